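#' Spiral tip positions from a snapshot pair
#'
#' The spiral tip is located at the transversal intersection of the
#' isopotential line V = `level` with the zero contour of the inter-frame
#' voltage difference (the discrete dV/dt = 0 line), found to sub-grid
#' accuracy by intersecting the linearly interpolated contour segments
#' within grid cells.
#'
#' @param v,v_prev voltage matrices (nx x ny) at the current and previous
#'   snapshot.
#' @param dx grid spacing, cm.
#' @param level isopotential level, mV (-35 by default).
#' @return A tibble with columns `x`, `y` (cm); zero rows when no tip
#'   exists (e.g. a plane wave).
#' @export
track_tip <- function(v, v_prev, dx, level = -35) {
  stopifnot(all(dim(v) == dim(v_prev)))
  xs <- (seq_len(nrow(v)) - 1) * dx
  ys <- (seq_len(ncol(v)) - 1) * dx
  c_iso <- grDevices::contourLines(xs, ys, v, levels = level)
  c_dvdt <- grDevices::contourLines(xs, ys, v - v_prev, levels = 0)
  if (length(c_iso) == 0 || length(c_dvdt) == 0)
    return(tibble(x = numeric(0), y = numeric(0)))
  pts <- list()
  for (a in c_iso) for (b in c_dvdt) {
    # bounding-box prune
    if (max(a$x) < min(b$x) || max(b$x) < min(a$x) ||
        max(a$y) < min(b$y) || max(b$y) < min(a$y)) next
    pts[[length(pts) + 1]] <- polyline_intersections(a$x, a$y, b$x, b$y)
  }
  if (length(pts) == 0) return(tibble(x = numeric(0), y = numeric(0)))
  out <- dplyr::bind_rows(pts)
  if (nrow(out) > 1) { # merge near-duplicate intersections (< dx apart)
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out) - 1)) {
      if (!keep[i]) next
      d <- sqrt((out$x[-(1:i)] - out$x[i])^2 + (out$y[-(1:i)] - out$y[i])^2)
      keep[i + which(d < dx)] <- FALSE
    }
    out <- out[keep, ]
  }
  out
}

# all intersection points of two polylines
polyline_intersections <- function(ax, ay, bx, by) {
  out_x <- numeric(0); out_y <- numeric(0)
  na <- length(ax) - 1; nb <- length(bx) - 1
  for (i in seq_len(na)) {
    x1 <- ax[i]; y1 <- ay[i]; x2 <- ax[i + 1]; y2 <- ay[i + 1]
    lo_x <- min(x1, x2); hi_x <- max(x1, x2)
    lo_y <- min(y1, y2); hi_y <- max(y1, y2)
    for (j in seq_len(nb)) {
      x3 <- bx[j]; y3 <- by[j]; x4 <- bx[j + 1]; y4 <- by[j + 1]
      if (max(x3, x4) < lo_x || min(x3, x4) > hi_x ||
          max(y3, y4) < lo_y || min(y3, y4) > hi_y) next
      den <- (x2 - x1) * (y4 - y3) - (y2 - y1) * (x4 - x3)
      if (abs(den) < 1e-14) next
      s <- ((x3 - x1) * (y4 - y3) - (y3 - y1) * (x4 - x3)) / den
      u <- ((x3 - x1) * (y2 - y1) - (y3 - y1) * (x2 - x1)) / den
      if (s >= 0 && s <= 1 && u >= 0 && u <= 1) {
        out_x <- c(out_x, x1 + s * (x2 - x1))
        out_y <- c(out_y, y1 + s * (y2 - y1))
      }
    }
  }
  tibble(x = out_x, y = out_y)
}

#' Tip trajectory of a tissue simulation
#'
#' Detects spiral tips on every consecutive snapshot pair and links them
#' across frames by nearest-neighbour continuity with a displacement gate
#' (1 cm per 10 ms by default; a tip farther than the gate from every open
#' track starts a new track). Returns the positions of the longest track.
#'
#' @param sim a `pig_tissue_sim` with snapshots.
#' @param level isopotential level, mV.
#' @param gate_cm_per_10ms linking gate.
#' @param all_tracks if `TRUE`, return every track (column `track`).
#' @return A tibble of class `tip_trajectory` with `time` (ms), `x`, `y`
#'   (cm); sampling interval attached as attribute `interval`.
#' @export
tip_trajectory <- function(sim, level = -35, gate_cm_per_10ms = 1,
                           all_tracks = FALSE) {
  nt <- length(sim$snapshots)
  if (nt < 2) abort("need at least two snapshots")
  dt_snap <- diff(sim$snap_times)
  interval <- stats::median(dt_snap)
  gate <- gate_cm_per_10ms * interval / 10

  tracks <- list()   # each: list(times, xs, ys, open)
  for (k in 2:nt) {
    tips <- track_tip(sim$snapshots[[k]], sim$snapshots[[k - 1]], sim$dx,
                      level)
    tnow <- sim$snap_times[k]
    if (nrow(tips) == 0) next
    assigned <- rep(FALSE, nrow(tips))
    # open tracks = those updated at the previous frame (within one interval)
    for (ti in seq_along(tracks)) {
      tr <- tracks[[ti]]
      if (tnow - tr$times[length(tr$times)] > 1.5 * interval) next
      d <- sqrt((tips$x - tr$xs[length(tr$xs)])^2 +
                  (tips$y - tr$ys[length(tr$ys)])^2)
      d[assigned] <- Inf
      if (all(!is.finite(d)) || min(d) > gate) next
      i <- which.min(d)
      tracks[[ti]]$times <- c(tr$times, tnow)
      tracks[[ti]]$xs <- c(tr$xs, tips$x[i])
      tracks[[ti]]$ys <- c(tr$ys, tips$y[i])
      assigned[i] <- TRUE
    }
    for (i in which(!assigned))
      tracks[[length(tracks) + 1]] <- list(times = tnow, xs = tips$x[i],
                                           ys = tips$y[i])
  }
  if (length(tracks) == 0)
    return(structure(tibble(time = numeric(0), x = numeric(0),
                            y = numeric(0)),
                     interval = interval, class = c("tip_trajectory",
                                                    class(tibble()))))
  traj <- purrr::imap_dfr(tracks, function(tr, id)
    tibble(track = as.integer(id), time = tr$times, x = tr$xs, y = tr$ys))
  if (!all_tracks) {
    best <- traj %>% dplyr::count(.data$track) %>%
      dplyr::slice_max(.data$n, n = 1, with_ties = FALSE)
    traj <- traj %>% filter(.data$track == best$track) %>%
      select(-"track")
  }
  structure(traj, interval = interval,
            class = c("tip_trajectory", class(tibble())))
}

#' Signed-frequency spectrum of a tip trajectory
#'
#' Discrete Fourier transform of the complex tip signal
#' \eqn{z(t) = x(t) + i\,y(t)} (mean removed, rectangular window), keeping
#' the sign of frequency so that counter-rotating orbital components appear
#' at negative frequencies. The hypocycloidal ("flower") meander of a
#' spiral tip is the superposition of two counter-rotating circles, so its
#' spectrum shows one dominant positive and one dominant negative peak.
#'
#' @param traj a [tip_trajectory()] tibble (columns `time`, `x`, `y`).
#' @param fs sampling frequency, Hz; defaults to `1000 / interval`.
#' @param n_peaks number of dominant peaks to report (default 4).
#' @return A tibble of class `tip_spectrum` with `frequency` (Hz, signed)
#'   and `magnitude`; the `n_peaks` dominant peaks (local maxima, by
#'   magnitude) are attached as attribute `peaks`, and the rotation period
#'   (ms, from the strongest peak) as attribute `rotation_period`.
#' @export
trajectory_spectrum <- function(traj, fs = NULL, n_peaks = 4) {
  n <- nrow(traj)
  if (is.null(fs)) {
    interval <- attr(traj, "interval")
    if (is.null(interval)) interval <- stats::median(diff(traj$time))
    fs <- 1000 / interval
  }
  if (n < 8) abort("trajectory too short for a spectrum")
  z <- complex(real = traj$x - mean(traj$x),
               imaginary = traj$y - mean(traj$y))
  X <- fft(z) / n
  f <- (seq_len(n) - 1) / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  spec <- tibble(frequency = f, magnitude = Mod(X)) %>%
    arrange(.data$frequency)
  # dominant local maxima
  m <- spec$magnitude
  is_peak <- m > dplyr::lag(m, default = -Inf) &
    m >= dplyr::lead(m, default = -Inf)
  peaks <- spec[is_peak, ] %>% arrange(dplyr::desc(.data$magnitude)) %>%
    head(n_peaks)
  rot <- if (nrow(peaks) > 0 && abs(peaks$frequency[1]) > 0)
    1000 / abs(peaks$frequency[1]) else NA_real_
  structure(spec, peaks = peaks, rotation_period = rot, fs = fs,
            class = c("tip_spectrum", class(tibble())))
}

#' Phase-singularity census
#'
#' Embeds each snapshot as a phase field
#' \eqn{\theta = \mathrm{atan2}(V(t) - V^*,\ V(t-\tau) - V^*)} with
#' \eqn{V^* = -35} mV and \eqn{\tau = 2} ms (the lagged field stored with
#' each snapshot), and counts grid plaquettes around which the phase winds
#' by \eqn{\pm 2\pi} — one singularity sits at each spiral tip.
#'
#' @param sim a `pig_tissue_sim`, or a list with elements `snapshots`,
#'   `snapshots_lag`, `snap_times`.
#' @param v_star phase-embedding origin, mV.
#' @return A tibble with `time` (ms), `n_ps` (integer count per frame).
#' @export
count_phase_singularities <- function(sim, v_star = -35) {
  if (length(sim$snapshots) < 1) abort("need at least one snapshot frame")
  purrr::map2_dfr(sim$snapshots, seq_along(sim$snapshots), function(v, k) {
    vl <- sim$snapshots_lag[[k]]
    theta <- atan2(v - v_star, vl - v_star)
    tibble(time = sim$snap_times[k], n_ps = count_ps_frame(theta))
  })
}

# winding number per plaquette from a phase matrix
count_ps_frame <- function(theta) {
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  nx <- nrow(theta); ny <- ncol(theta)
  if (nx < 2 || ny < 2) return(0L)
  a <- theta[-nx, -ny]; b <- theta[-1, -ny]; c <- theta[-1, -1]; d <- theta[-nx, -1]
  w <- wrap(b - a) + wrap(c - b) + wrap(d - c) + wrap(a - d)
  sum(abs(w) > pi)
}

#' Per-site APD90 mapping, restitution pairs and alternans flags
#'
#' Samples every `stride`-th node of the snapshot history in x and y,
#' extracts per-beat APD90 (time above the 90%-repolarisation level, linear
#' interpolation at crossings) and the local cycle lengths and diastolic
#' intervals, excludes sites close to the spiral tip, and flags sites whose
#' consecutive-beat APD90 difference exceeds `alternans_threshold`.
#'
#' @param sim a `pig_tissue_sim` with snapshots.
#' @param stride site sampling stride in nodes (default 8).
#' @param traj optional [tip_trajectory()]; sites within `exclude_radius_cm`
#'   of any tip position are excluded.
#' @param exclude_radius_cm tip-exclusion radius, cm.
#' @param min_beats sites with fewer activations are dropped.
#' @param alternans_threshold |delta APD90| (ms) flagging alternans.
#' @return A tibble with one row per site and beat: `site_x`, `site_y` (cm),
#'   `beat`, `t_act` (activation time, ms), `cl`, `di`, `apd90` (ms), and a
#'   per-site logical `alternans`.
#' @export
apd_map <- function(sim, stride = 8, traj = NULL, exclude_radius_cm = 1,
                    min_beats = 4, alternans_threshold = 5) {
  nt <- length(sim$snapshots)
  if (nt < 10) abort("snapshot history too short for APD mapping")
  times <- sim$snap_times
  ixs <- seq(1, sim$nx, by = stride)
  iys <- seq(1, sim$ny, by = stride)
  rows <- list()
  for (ix in ixs) for (iy in iys) {
    sx <- (ix - 1) * sim$dx; sy <- (iy - 1) * sim$dx
    if (!is.null(traj) && nrow(traj) > 0) {
      dmin <- min(sqrt((traj$x - sx)^2 + (traj$y - sy)^2))
      if (dmin < exclude_radius_cm) next
    }
    v <- vapply(sim$snapshots, function(s) s[ix, iy], numeric(1))
    site <- site_apd_sequence(times, v)
    if (is.null(site) || nrow(site) < min_beats) next
    site$site_x <- sx; site$site_y <- sy
    rows[[length(rows) + 1]] <- site
  }
  if (length(rows) == 0)
    abort("no site produced enough activations for APD mapping")
  out <- dplyr::bind_rows(rows) %>%
    group_by(.data$site_x, .data$site_y) %>%
    mutate(alternans = any(abs(diff(.data$apd90)) > alternans_threshold)) %>%
    ungroup() %>%
    select("site_x", "site_y", "beat", "t_act", "cl", "di", "apd90",
           "alternans")
  out
}

# per-beat APD90 / CL / DI sequence at one site
site_apd_sequence <- function(t, v, upstroke_level = -35) {
  act <- upcross_times(t, v, upstroke_level)
  if (length(act) < 2) return(NULL)
  v_rest <- stats::quantile(v, 0.05, names = FALSE)
  v_peak <- max(v)
  level90 <- v_peak - 0.9 * (v_peak - v_rest)
  reps <- downcross_times(t, v, level90)
  rows <- purrr::map_dfr(seq_along(act), function(b) {
    t_act <- act[b]
    t_next <- if (b < length(act)) act[b + 1] else Inf
    r <- reps[reps > t_act & reps < t_next]
    tibble(beat = b, t_act = t_act,
           apd90 = if (length(r) > 0) r[1] - t_act else NA_real_)
  })
  rows %>%
    mutate(cl = t_act - lag(.data$t_act),
           di = .data$cl - lag(.data$apd90)) %>%
    filter(!is.na(.data$apd90))
}
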