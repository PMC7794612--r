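#' Differentiate an estimated position track into velocity
#'
#' Central-difference velocity at the analysis tick rate, followed by a
#' zero-phase low-pass filter that suppresses tick-to-tick jitter from the
#' position estimator (the time differential amplifies high-frequency
#' noise).
#'
#' @param track a `position_track` (from [smooth_track()]) or any data frame
#'   with columns `t`, `x`, `y` on a uniform time grid.
#' @param f_cut2 low-pass cutoff, Hz.
#' @param order Butterworth order.
#' @return A `velocity_track` data frame: `t`, `vx`, `vy` (mm/s), `speed`.
#' @export
differentiate_positions <- function(track, f_cut2 = 0.5, order = 4) {
  if (nrow(track) < 3) stop("need at least 3 ticks to differentiate")
  t <- track$t
  dt <- median(diff(t))
  fs <- 1 / dt
  if (f_cut2 >= fs / 2) stop("f_cut2 must be below the tick Nyquist rate")
  cdiff <- function(p) {
    n <- length(p)
    v <- c(p[2] - p[1], (p[3:n] - p[1:(n - 2)]) / 2, p[n] - p[n - 1]) / dt
    v
  }
  vx <- cdiff(track$x)
  vy <- cdiff(track$y)
  bf <- signal::butter(order, f_cut2 / (fs / 2), type = "low")
  vx <- zerophase_filter(bf, vx)
  vy <- zerophase_filter(bf, vy)
  out <- data.frame(t = t, vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
  class(out) <- c("velocity_track", "data.frame")
  out
}

#' Stopping probability of a window
#'
#' Percentage of an analysis window during which the swimming speed is below
#' the threshold `v_stop`: `100 * T(|v| < v_stop) / T_index`, evaluated on
#' the tick grid (the shared tick spacing cancels from numerator and
#' denominator).
#'
#' @param speeds tick speeds over one window, mm/s.
#' @param v_stop threshold speed, mm/s.
#' @return Stopping probability in percent, in \[0, 100\].
#' @export
stopping_probability <- function(speeds, v_stop = 3) {
  if (length(speeds) == 0) stop("empty window")
  100 * sum(speeds < v_stop) / length(speeds)
}

#' Ventilatory frequency at the estimated position
#'
#' Reads, for every analysis tick, the spectral peak frequency of the
#' electrode nearest the estimated fish position. Ticks where that electrode
#' has a degenerate (zero-power) spectrum carry the last valid frequency
#' forward and are flagged.
#'
#' @param track a `position_track` (columns `t`, `x`, `y`).
#' @param maps a `peak_maps` object from [compute_peak_maps()] on the same
#'   tick grid.
#' @return Numeric vector of per-tick frequencies (Hz) with a logical
#'   `carried` attribute marking carried-forward ticks.
#' @export
ventilatory_frequency_at <- function(track, maps) {
  if (nrow(track) != length(maps$t)) {
    stop("track and peak maps must share the tick grid")
  }
  exy <- maps$arena$electrode_xy
  nearest <- vapply(seq_len(nrow(track)), function(i) {
    which.min((exy[, 1] - track$x[i])^2 + (exy[, 2] - track$y[i])^2)
  }, integer(1))
  fv <- maps$freq[cbind(seq_len(nrow(track)), nearest)]
  carried <- !is.finite(fv)
  if (all(carried)) stop("no valid spectral peaks along the track")
  if (any(carried)) {
    # carry last finite value forward (and first finite value backward)
    idx <- which(is.finite(fv))
    filled <- approx(idx, fv[idx], xout = seq_along(fv),
                     method = "constant", rule = 2, f = 0)$y
    fv <- filled
  }
  attr(fv, "carried") <- carried
  fv
}

#' Six evaluation indices per analysis window
#'
#' Aggregates tick-level speed and ventilatory frequency into the six
#' evaluation indices on consecutive windows (default 5 s): (i) mean speed,
#' (ii) stopping probability, (iii) mean ventilatory frequency, (iv) SD of
#' speed, (v) SD of stopping probability over sub-windows (default 1 s),
#' and (vi) SD of ventilatory frequency. A trailing partial window is
#' dropped.
#'
#' @param velocity a `velocity_track` or data frame with `t` and `speed`.
#' @param fv per-tick ventilatory frequency, Hz (same length as `velocity`).
#' @param window window length, s.
#' @param v_stop stopping-speed threshold, mm/s.
#' @param sub_window sub-window length for the SD of the stopping
#'   probability, s.
#' @param fish_id,state labels stored with each window.
#' @return An `index_windows` data frame with columns `fish_id`, `state`,
#'   `t0`, `v_mean`, `p_stop`, `fv_mean`, `v_sd`, `p_stop_sd`, `fv_sd`,
#'   `standardised`.
#' @export
windowed_indices <- function(velocity, fv, window = 5, v_stop = 3,
                             sub_window = 1, fish_id = 1L,
                             state = "normal") {
  t <- velocity$t
  speed <- velocity$speed
  if (length(fv) != length(speed)) stop("fv and velocity lengths differ")
  dt <- median(diff(t))
  if (window / dt < 3) stop("window must contain at least 3 ticks")
  rel <- t - t[1]
  duration <- rel[length(rel)] + dt
  nw <- floor(duration / window + 1e-9)
  if (nw < 1) stop("series shorter than one window")
  widx <- floor(rel / window + 1e-9)
  keep <- widx < nw
  widx <- widx[keep]
  speed <- speed[keep]
  fvk <- fv[keep]
  relk <- rel[keep]

  rows <- lapply(seq_len(nw) - 1L, function(k) {
    sel <- widx == k
    sp <- speed[sel]
    f <- fvk[sel]
    sub <- floor((relk[sel] - k * window) / sub_window + 1e-9)
    psub <- vapply(
      split(sp, sub),
      function(s) stopping_probability(s, v_stop), numeric(1)
    )
    data.frame(
      fish_id = fish_id, state = state, t0 = t[1] + k * window,
      v_mean = mean(sp),
      p_stop = stopping_probability(sp, v_stop),
      fv_mean = mean(f),
      v_sd = sd(sp),
      p_stop_sd = if (length(psub) > 1) sd(psub) else 0,
      fv_sd = sd(f),
      standardised = FALSE,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("index_windows", "data.frame")
  out
}

#' Standardise index windows against a per-fish baseline
#'
#' Per fish and per index, maps values to z-scores using the mean and SD of
#' that fish's baseline windows (by default its `"normal"`-state windows,
#' the 5 min collected before treatment). Applying the transform to the
#' baseline itself therefore yields mean 0 and SD 1, and re-standardising an
#' already-standardised table is a no-op.
#'
#' @param windows an `index_windows` data frame.
#' @param baseline_state state label defining the baseline segment.
#' @return The table with the six index columns standardised and
#'   `standardised = TRUE`.
#' @export
standardise_windows <- function(windows, baseline_state = "normal") {
  cols <- index_columns()
  out <- windows
  for (fish in unique(windows$fish_id)) {
    frows <- windows$fish_id == fish
    base <- frows & windows$state == baseline_state
    if (sum(base) < 2) {
      stop(sprintf("fish %s: baseline needs at least 2 windows", fish))
    }
    for (cl in cols) {
      mu <- mean(windows[[cl]][base])
      sg <- sd(windows[[cl]][base])
      if (!is.finite(sg) || sg <= 0) {
        stop(sprintf("fish %s: zero baseline SD for index '%s'", fish, cl))
      }
      out[[cl]][frows] <- (windows[[cl]][frows] - mu) / sg
    }
  }
  out$standardised <- TRUE
  out
}
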