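#' Action-potential features per beat
#'
#' Extracts, for every stimulus in a voltage trace: resting membrane
#' potential (RMP, the pre-stimulus potential), action potential amplitude
#' (APA, peak minus RMP), maximum upstroke velocity (dV/dt max, centred
#' finite differences at the trace's native sampling) and the action
#' potential durations APD_X (time spent above the X%-repolarisation level,
#' with linear interpolation at the threshold crossings).
#'
#' A beat with APA below `capture_threshold` is flagged `captured = FALSE`
#' (no-capture), with its features set to `NA` rather than raising an error.
#'
#' @param trace a [simulate_cell()] result, or any data frame with `time` and
#'   `v` columns (ms, mV).
#' @param stim_times stimulus onset times; defaults to the attribute attached
#'   by [simulate_cell()].
#' @param apd_levels repolarisation percentages for APD (default 10..90).
#' @param capture_threshold minimum APA (mV) counted as a captured beat.
#' @return A tibble with one row per stimulus: `beat`, `t_stim`, `cl` (cycle
#'   length to the previous stimulus, NA for the first), `captured`, `rmp`,
#'   `v_peak`, `apa`, `dvdt_max`, and one `apd_X` column per level.
#' @export
extract_ap_features <- function(trace,
                                stim_times = attr(trace, "stim_times"),
                                apd_levels = seq(10, 90, 10),
                                capture_threshold = 60) {
  if (is.null(stim_times) || length(stim_times) == 0)
    abort("stim_times must be supplied (none attached to the trace)")
  stim_times <- sort(as.numeric(stim_times))
  t <- trace$time; v <- trace$v
  out <- purrr::map_dfr(seq_along(stim_times), function(b) {
    t0 <- stim_times[b]
    t1 <- if (b < length(stim_times)) stim_times[b + 1] else max(t) + 1
    cl <- if (b > 1) t0 - stim_times[b - 1] else NA_real_
    feats <- ap_features_one(t, v, t0, t1, apd_levels, capture_threshold)
    dplyr::bind_cols(tibble(beat = b, t_stim = t0, cl = cl), feats)
  })
  out
}

ap_features_one <- function(t, v, t0, t1, apd_levels, capture_threshold) {
  pre <- which(t <= t0)
  if (length(pre) == 0) abort("trace does not cover the stimulus onset")
  rmp <- v[max(pre)]
  win <- which(t >= t0 & t < t1)
  if (length(win) < 3) abort("trace window too short for feature extraction")
  tw <- t[win]; vw <- v[win]
  ipk <- which.max(vw)
  v_peak <- vw[ipk]
  apa <- v_peak - rmp

  na_row <- function() {
    apd <- setNames(as.list(rep(NA_real_, length(apd_levels))),
                    paste0("apd_", apd_levels))
    dplyr::bind_cols(tibble(captured = FALSE, rmp = rmp, v_peak = v_peak,
                            apa = apa, dvdt_max = NA_real_),
                     as_tibble(apd))
  }
  if (!is.finite(apa) || apa < capture_threshold) return(na_row())

  # centred differences on the upstroke (stimulus to peak)
  up <- win[1]:(win[1] + ipk - 1)
  if (length(up) >= 3) {
    i <- up[-c(1, length(up))]
    dvdt <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
    dvdt_max <- max(dvdt)
  } else dvdt_max <- NA_real_

  apd <- vapply(apd_levels, function(x) {
    level <- v_peak - (x / 100) * apa
    apd_at_level(tw, vw, ipk, level)
  }, numeric(1))
  names(apd) <- paste0("apd_", apd_levels)
  dplyr::bind_cols(tibble(captured = TRUE, rmp = rmp, v_peak = v_peak,
                          apa = apa, dvdt_max = dvdt_max),
                   as_tibble(as.list(apd)))
}

# time spent above `level` around the peak index, interpolated crossings
apd_at_level <- function(tw, vw, ipk, level) {
  cross_t <- function(i0, i1) { # crossing between samples i0, i1
    tw[i0] + (level - vw[i0]) * (tw[i1] - tw[i0]) / (vw[i1] - vw[i0])
  }
  # upstroke crossing: last sample below level before the peak
  below <- which(vw[1:ipk] < level)
  t_up <- if (length(below) == 0) tw[1] else cross_t(max(below), max(below) + 1)
  # repolarisation crossing: first sample below level after the peak
  after <- which(vw[ipk:length(vw)] < level)
  if (length(after) == 0) return(NA_real_)   # never repolarised in window
  idn <- ipk + min(after) - 1
  t_dn <- cross_t(idn - 1, idn)
  t_dn - t_up
}
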