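# pigatria

An ionically detailed model of **pig atrial electrophysiology**: a
12-current Hodgkin–Huxley single-cell model with Luo–Rudy sarcoplasmic
Ca²⁺ handling, a monodomain (FTCS) cable/sheet solver, and the analysis
pipeline used to characterise reentry — S1–S2 cross-field spiral
initiation, spiral-tip tracking, signed-frequency trajectory spectra,
phase-singularity counting and alternans detection.

The pig atrium is a standard large-animal preparation for studying the
onset and surgical management of atrial fibrillation, but mechanistic
work has had to lean on models of other species. This package provides a
porcine-specific cell model for that gap. Its distinctive feature is the
transient outward current: in pig atria I_to is carried entirely by a
**Ca²⁺-activated chloride current (I_ClCa)** gated by the net myoplasmic
Ca²⁺ flux,

$$I_{ClCa} = g_{ClCa}\, q_{Ca}\,(V - E_{Cl}), \qquad
q_{Ca,\infty} = 1 - \frac{1}{1 + (F_n/1.1\times10^{-10})^3},\ \ \tau = 2\ \mathrm{ms},$$

which couples early repolarisation to sarcoplasmic Ca²⁺ release and
switches off at high pacing rates. The membrane equation is the standard
$dV/dt = -(I_{ion}+I_{stim})/C_m$ with twelve currents
(I_Na, I_K1, I_ClCa, I_Kur, I_Kr, I_Ks, I_CaL, I_pCa, I_NaK, I_NaCa,
I_bNa, I_bCa); tissue adds monodomain diffusion
($D = 0.00126\ \mathrm{cm^2/ms}$, $\Delta x = 0.022$ cm,
$\Delta t = 0.02$ ms). The formulation details, parameter table and all
design decisions are in the methods vignette
(`vignettes/pig-atrial-model.Rmd`).

## Worked example

```r
library(pigatria)

p  <- pig_params()                   # fitted pig parameter set
st <- paced_state(p)                 # cell adapted to 1 Hz pacing

# one paced beat and its clinical features
sim <- simulate_cell(p, duration = 900, stim_times = 10,
                     state = st, record_every = 0.05)
extract_ap_features(sim)
#>    rmp v_peak   apa dvdt_max apd_20 apd_50 apd_90
#> -76.5   61.6 138.2    276.4   10.2   98.4  187.1
```

Resting potential −76.5 mV, amplitude 138 mV, upstroke 276 V/s and
APD₉₀ = 187 ms at 1 Hz — an atrial AP with the pig's fast early
repolarisation (APD₂₀ only 10 ms). The chloride current behind that
early phase shows its hallmark bell-shaped IV curve under voltage clamp:

```r
iv <- run_voltage_clamp(clamp_protocol("i_clca"), p)
max(iv$current)                      # 1.33 pA/pF, peaking at +30 mV
autoplot(iv)
```

Tissue-level work chains the same way:

```r
cab <- simulate_cable(10, p, stim_times = stim_train(3, 1000, 0),
                      probe_pos_cm = c(4, 6), duration = 2800, state = st)
cv <- measure_cv(cab)                # cm/s from -35 mV front arrivals
measure_wavelength(cab, cv)          # (t_back(-40 mV) - t_front) x CV

spiral <- s1s2_crossfield(p, nx = 512, duration_after_s2 = 40000)  # long run
traj   <- tip_trajectory(spiral)
trajectory_spectrum(traj)            # signed rotation frequencies
count_phase_singularities(spiral)
```

A coarse desk-scale spiral for trying the analysis pipeline is one call:
`mini_spiral_sim()`. A thin command-line wrapper
(`inst/scripts/pigatria`) exposes the protocols as verbs
(`clamp`, `restitution`, `erp`, `tissue`, `s1s2`, `analyze`,
`fixtures`) driven by YAML configs via `run_experiment()`.

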