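# Cached fixtures shared across test files (built once per test run).
.fix <- new.env(parent = emptyenv())

fix_cached <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

fix_params <- function() pig_params()

fix_resting <- function() fix_cached("resting", function() pig_resting_state())

# cell adapted to 1 Hz pacing: the conditioned operating point for protocols
fix_paced_1hz <- function() fix_cached("paced_1hz", function()
  paced_state(fix_params(), cl = 1000, state = fix_resting()))

fix_restitution <- function() fix_cached("restitution", function()
  run_restitution(fix_params(), frequencies = c(0.25, 0.5, 1, 2, 4),
                  n_beats = 12, last = 4, state = fix_paced_1hz()))

# 10 cm cable paced 3 beats at 1 Hz from the adapted state
fix_cable_1hz <- function() fix_cached("cable_1hz", function()
  simulate_cable(10, fix_params(), stim_times = stim_train(3, 1000, 0),
                 probe_pos_cm = c(4, 6), duration = 2800,
                 state = fix_paced_1hz()))

# coarse-grid S1-S2 spiral history (desk-scale analysis fixture)
fix_mini_spiral <- function() fix_cached("mini_spiral", function()
  mini_spiral_sim(fix_params(), duration_after_s2 = 700))
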