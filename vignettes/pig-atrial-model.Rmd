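---
title: "The pig atrial cell and tissue model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pig atrial cell and tissue model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`pigatria` implements an ionically detailed model of the porcine atrial
cardiomyocyte and its spatial extension to monodomain tissue. The membrane
obeys

$$\frac{dV}{dt} = -\frac{I_{ion} + I_{stim}}{C_m}, \qquad
I_{ion} = I_{Na} + I_{K1} + I_{ClCa} + I_{Kur} + I_{Kr} + I_{Ks} +
I_{Ca,L} + I_{p,Ca} + I_{NaK} + I_{NaCa} + I_{b,Na} + I_{b,Ca},$$

with twelve Hodgkin–Huxley-type membrane currents (densities in pA/pF,
conductances in nS/pF, $V$ in mV, $t$ in ms, concentrations in mM). In
tissue a diffusion term $D\nabla^2 V$ is added (monodomain,
$D = 0.00126\ \mathrm{cm^2/ms}$) and integrated by the explicit
forward-time centred-space (FTCS) scheme on a square grid
($\Delta x = \Delta y = 0.022$ cm, $\Delta t = 0.02$ ms, no-flux
boundaries via mirrored ghost nodes).

The formulations derive from the Courtemanche–Ramirez–Nattel (CRN) human
atrial model, with the sarcoplasmic-reticulum (SR) Ca²⁺ subsystem of the
Luo–Rudy dynamic model as embedded in CRN, and carry the following
pig-specific modifications:

* **I_Na** — Luo–Rudy kinetics with $g_{Na} = 13.99$ (1.8× the human
  value), activation time constant $\tau_m$ scaled ×1.7 and inactivation
  time constants $\tau_h, \tau_j$ scaled ×2.
* **I_K1** — reversal offset of +5 mV in the numerator
  ($V - E_K - 5$), conductance 0.08218 (−9% vs human), rectification
  slope 0.063/mV and half-rise at −70 mV:
  $I_{K1} = g_{K1}(V - E_K - 5) / (1 + e^{0.063 (V + 70)})$.
* **I_CaL** — $g_{Ca,L}\, d\, f\, f_{Ca} (V - 65)$ with the activation
  kinetics ($d_\infty$, $\tau_d$) shifted +5 mV rightward;
  $f_{Ca,\infty} = 1/(1 + [Ca^{2+}]_i / 0.00035)$, $\tau_{f_{Ca}} = 2$ ms.
* **I_Kur** — bi-exponential inactivation,
  $g_{Kur}(V)\,u_a^3 (a\,u_{i,f} + b\,u_{i,s}) (V - E_K)$ with
  $(a, b) = (0.25, 0.75)$ and
  $g_{Kur}(V) = g_{Kur,amp}\,[0.005 + 0.05/(1 + e^{-(V-15)/13})]$,
  $g_{Kur,amp} = 0.45539$.
* **I_Kr** — $g_{Kr}\, x_r (V - E_K) / (1 + e^{(V - 79.4825)/8.2217})$,
  with $x_{r,\infty} = 1/(1 + e^{-(V - 4.4451)/9.3305})$ (half-rise +20 mV
  vs human, shallower slope) and the human activation time constant.
* **I_Ks** — human formulation with $p_1 = 18.802$ mV, $p_2 = 12.6475$ mV:
  $x_{s,\infty} = [1 + e^{-(V-p_1)/p_2}]^{-1/2}$.
* **I_to ≡ I_ClCa** — uniquely in the pig atrium the transient outward
  current is entirely a Ca²⁺-activated Cl⁻ current (canine-type
  formulation): $g_{ClCa}\, q_{Ca} (V - E_{Cl})$ with
  $q_{Ca,\infty} = 1 - [1 + (F_n / 1.1\times10^{-10})^3]^{-1}$,
  $\tau_{q_{Ca}} = 2$ ms, where $F_n$ is the net Ca²⁺ flux into the
  myoplasm (CRN convention, dominated by SR release). The
  voltage-dependent inactivation of SR release (the $w$ gate) is shifted
  +40 mV and steepened, which produces the characteristic bell-shaped
  I_ClCa IV curve.
* **Pumps/exchangers** — CRN formulations with
  $I_{NaK,max} = 0.94935$ pA/pF and the Na⁺/Ca²⁺ exchanger scaling
  constant 2304.

Because the pig transient outward current carries Cl⁻ rather than K⁺, it
is excluded from the intracellular K⁺ balance (unlike the human model's
I_to).

# Parameters

`pig_params()` returns every constant with physical units; all entries are
overridable by name and `scale_params()` applies fractional channel block
(e.g. `g_kr = 0.25` for the repolarisation-reserve breakup regime,
`g_clca = 0.5` or `0.1` for the chloride-block alternans replay). The key
tunables:

| parameter | default | units | role |
|---|---|---|---|
| `g_na` … `g_cal` | fitted set | nS/pF | maximal conductances |
| `i_nak_max`, `i_naca_max`, `i_pca_max` | 0.94935, 2304, 0.275 | pA/pF (NaCa: scaling) | pump/exchanger maxima |
| `D` | 0.00126 | cm²/ms | tissue diffusion |
| `dx`, `dt` | 0.022 cm, 0.02 ms | — | FTCS grid |
| `stim_na`, `stim_duration` | 7 nA, 4 ms | — | tissue stimulus (÷ `cm` → 70 pA/pF) |
| `stim_cell_amp`, `stim_cell_duration` | 40 pA/pF, 1 ms | — | isolated-cell stimulus |
| `temperature` | 310.15 | K | body temperature |

# Numerical choices

* **Integration** — forward Euler for voltage and concentrations at
  $\Delta t = 0.02$ ms, matching the FTCS tissue scheme; a Rush–Larsen
  update for the Hodgkin–Huxley gates is available
  (`rush_larsen = TRUE`) and changes APD₉₀ and CV by under 2%, but the
  default remains plain Euler. Euler gate updates are projected back onto
  $[0,1]$; this only engages at electrode-artifact voltages where a time
  constant falls below $\Delta t$.
* **Rate tables** — all purely voltage-dependent quantities are tabulated
  on a 0.01 mV grid over $[-150, 400]$ mV and linearly interpolated inside
  the integration loops; the wide upper margin absorbs the transient
  excursion of stimulated nodes. The printed tissue stimulus
  (7 nA ÷ 100 pF for 4 ms) injects far more charge than any repolarising
  current can oppose, so electrode nodes transiently reach ∼+300 mV; the
  artifact is local and decays within milliseconds. For isolated cells the
  same pulse would depolarise the membrane by ∼+280 mV with no diffusive
  load, so cell-level protocols use an experimental-style 1 ms pulse at
  ∼30% above the 1 ms threshold (40 pA/pF) instead.
* **Stability** — the solver refuses to run when
  $D\,\Delta t/\Delta x^2 > 0.25$ (defaults: 0.052).
* **Grid resolution** — at $\Delta x = 0.022$ cm the model's fast upstroke
  (2–3 nodes wide) is only marginally resolved: halving $\Delta x$ raises
  CV by ≈7% and refining $\Delta t$ by ≈1.5%. The production grid is kept
  because it is the published discretisation; the $\sqrt{D}$ scaling of CV
  holds within 5% on the refined grid.
* **Thresholds** — wavefront arrival −35 mV (shared with tip tracking),
  waveback −40 mV (the wavelength definition
  $WL = (t|_{back,-40} - t|_{front})\times CV$), capture = APA > 60 mV,
  APD by linear interpolation at the repolarisation-level crossings,
  dV/dt by centred differences at the trace's native sampling.

# Initial conditions and the paced operating point

The state starts from the source model's resting values
(`pig_initial_state()`). The packaged quiescent state
(`pig_resting_state()`) is that state relaxed unstimulated for 300 s,
after which every Ca²⁺ compartment drifts by <1% per 10 s. Like its parent
models, the cell's ion concentrations creep on a minutes time scale, and
the quiescent equilibrium (Na⁺ᵢ ≈ 7.4 mM) is *not* the operating point of
a preparation under pacing. All pacing protocols therefore condition from
`paced_state()` — 200 s of 0D pacing at the protocol's cycle length —
mirroring experimental measurement "after reaching steady-state activity".
This matters: the effective refractory period is 213.5 ms from the paced
state versus 230 ms from the quiescent one.

# Protocols

* `run_voltage_clamp()` holds the membrane on a schedule while gates and
  Ca²⁺ evolve; each test pulse starts from the same conditioned holding
  state. The L-type characterisation clamps [Ca²⁺]ᵢ at 10⁻⁴ mM; defaults
  are hold −80 mV, steps −40…+60 mV in 5 mV, 300 ms.
* `run_restitution()` paces at 0.25–4 Hz, discards conditioning beats and
  averages features over the final 10 beats, recording per-beat peak
  I_ClCa and peak Ca²⁺ flux.
* `measure_erp()` bisects the S1–S2 coupling interval to 1 ms after ≥5
  conditioning beats; both 0D and cable modes exist because the source
  experiments do not state which was used.
* `simulate_cable()` + `measure_cv()`/`measure_wavelength()` implement the
  CV/WL measurements; `shortest_sustained_cl()` up-titrates the pacing
  rate to the fastest sustained 1:1 train (pacing at a cycle length below
  the refractory period — including the published 200 ms, which lies below
  the published 215 ms ERP — produces 2:1 block).
* `s1s2_crossfield()` launches S1 from the left edge and fires S2 over
  the lower half-plane when the S1 waveback (−40 mV) has cleared the
  domain midline; a run in which S2 fails to induce reentry is flagged
  (`spiral_formed = FALSE`), not an error.
* Analysis: `tip_trajectory()` intersects the V = −35 mV isoline with the
  zero contour of the inter-frame difference (the discrete dV/dt = 0 line,
  10 ms snapshots) and links tips by nearest neighbour within
  1 cm/10 ms; `trajectory_spectrum()` takes the DFT of $x + iy$
  (mean-removed, rectangular window) preserving rotation sign;
  `count_phase_singularities()` embeds phase as
  $\theta = \mathrm{atan2}(V(t) + 35, V(t - 2\,\mathrm{ms}) + 35)$ and counts
  ±2π plaquette windings; `apd_map()` samples every 8th node, excludes a
  1 cm radius around the tip, and flags alternans when consecutive-beat
  |ΔAPD₉₀| > 5 ms (no numeric threshold is given in the source, so 5 ms —
  comfortably above the 10 ms-snapshot APD uncertainty — was fixed once).

# Synthetic generators and what passing tests show

`synth_phasor_trajectory()` (closed-form counter-rotating orbits),
`synth_spiral_field()` (rigidly rotating Archimedean spiral whose core is
the exact intersection of the tracking contours) and
`synth_plane_wave_field()` provide analytic oracles for the spectrum sign
convention, tip localisation and the singularity census. They emulate the
*geometry* of reentry, not its electrophysiology: no restitution, no
meander, no noise. Tests passing on them certify the analysis pipeline,
not the tissue dynamics; the `mini_spiral_sim()` fixture (72×72 nodes at a
4×-coarsened 0.088 cm spacing, ∼1 s of reentry) certifies that the full
protocol→solver→analysis chain produces and tracks a rotating spiral, but
its tip metrics are not quantitatively comparable to the full-resolution
512×512 study, which takes hours of compute and is exposed through the
same functions (`s1s2_crossfield(params, nx = 512, ...)`).

# Reconstruction choices where the source is silent

The per-current supplementary material of the source publication is not
available, so the following were fixed once from the parent-model
literature and the main-text statements:

* **I_Kur inactivation kinetics** — shared steady state from the human
  model's inactivation rates; fast time constant from those rates, slow
  component 20× slower (reading the "reduced by a factor of 20" plot note
  as the fast/slow display scale). This gate barely moves on the AP time
  scale, so AP-level results are insensitive to the choice.
* **SR-release voltage inactivation ($w$)** — half-point shifted
  40 → 80 mV as stated; the unstated "increased slope" was fixed at
  2× (slope factor 17 → 8.5).
* **I_Ks time constant** — the printed expression is typographically
  garbled; the parent model's $\tau_s = [2(\alpha_s + \beta_s)]^{-1}$ with
  $p_1$ substituted for the human half-point is used, consistent with the
  statement that the slow rectifier was "retained".
* **E_Cl** — fixed by the Nernst relation from the canine-model chloride
  concentrations (132/29.26 mM, ≈ −40.3 mV); intracellular Cl⁻ is not a
  state variable.
* **I_Kr rectification** — implemented exactly as printed
  (half 79.4825 mV, slope 8.2217 mV), leaving the current essentially
  unrectified below +60 mV.

# Known limitations

* **Upstroke strength and its consequences.** Configured with the parent
  model's own constants the machinery reproduces that model's AP
  (peak +27.8 mV, dV/dt 201 V/s). With the printed pig modifications
  (1.8× g_Na, slowed inactivation) the reconstructed cell has a strong
  upstroke (peak ≈ +61 mV, dV/dt ≈ 275 V/s). Three measurable quantities
  inherit this: conduction velocity computes to ≈64 cm/s (published:
  58 ± 2), the 1 Hz wavelength to ≈9.3 cm (published: 8), and — because a
  peak near the +65 mV L-type reversal suppresses the early I_CaL spike —
  the Ca²⁺-release trigger is weakened, so I_ClCa is small during paced
  APs (its restitution *trend* still matches: both peak I_ClCa and peak
  Ca²⁺ flux fall steeply as the cycle length drops below 1 s, and early
  APD shows the pig-specific downward trend at long cycle lengths). The
  clamped L-type peak is 2.35 pA/pF against a measured constraint of
  3.25 ± 0.75; with the printed +5 mV activation shift and the fitted
  conductance, values above ≈2.44 are mathematically unreachable under
  this protocol, indicating the source's supplementary formulation
  differed in a way the main text does not record. No parameter was
  adjusted away from the printed values to compensate.
* **Wavelength near the capture limit** is ill-conditioned: one 10 ms
  titration step changes WL from 3.6 to 5.1 cm.
* The Ca²⁺ subsystem is a guinea-pig ventricular formulation two model
  generations old; it supports the qualitative chloride-current story but
  not quantitative Ca²⁺ prediction.
* Homogeneous, isotropic, 2D tissue only: no fibre anisotropy, no
  heterogeneity, no 3D anatomy.

# Problem sizes used by the tests and the acceptance script

Cables of 3–10 cm at the production grid; 0D conditioning of 200–300 s;
restitution at 12–20 beats per frequency; the coarse 72×72 spiral fixture
(~1 s of reentry). These sizes were chosen so that each protocol reaches
its quasi-steady regime while the whole suite stays comfortably
repeatable on a laptop-class single core.
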