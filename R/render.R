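#' Render a trajectory into electrode-array signals
#'
#' Forward model of the ventilatory signal seen by the electrode array.
#' Channel \eqn{c} at time \eqn{t} carries
#' \deqn{A \, K(\lVert e_c - p(t) \rVert) \, \sin\phi(t) + \epsilon_c(t),}
#' where \eqn{p(t)} is the fish position, \eqn{K(d) = \exp(-d^2 / 2\ell^2)}
#' is a Gaussian spatial kernel with length-scale \eqn{\ell} equal to one
#' electrode pitch, \eqn{\phi(t)} is the running phase of the instantaneous
#' ventilation frequency, and \eqn{\epsilon} is white Gaussian noise scaled
#' so the signal-to-noise *power* ratio on the strongest channel is
#' approximately `snr`. Ground truth is resampled from the simulation rate
#' to the output sampling rate by linear interpolation.
#'
#' @param traj a [simulate_trajectory()] result.
#' @param arena the arena the trajectory was simulated in.
#' @param snr peak-channel signal-to-noise power ratio (> 0); `Inf` gives a
#'   noiseless rendering.
#' @param seed integer seed for the noise draw.
#' @param fs output sampling rate, Hz (default 1000).
#' @param amplitude source amplitude at zero distance (arbitrary units).
#' @param length_scale kernel length-scale, mm; defaults to the electrode
#'   pitch.
#' @return An `electrode_recording`: list with `samples` (channels x time
#'   matrix), `fs`, `arena` and the `truth` trajectory.
#' @export
render_signals <- function(traj, arena = attr(traj, "arena"), snr = Inf,
                           seed = 1, fs = 1000, amplitude = 1,
                           length_scale = NULL) {
  if (!inherits(traj, "ground_truth_trajectory")) {
    stop("traj must be a ground_truth_trajectory")
  }
  if (!inherits(arena, "arena_geometry")) stop("arena must be arena_geometry")
  if (!same_arena(arena, attr(traj, "arena"))) {
    stop("trajectory and arena geometry do not match")
  }
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive")
  ell <- length_scale %||% arena$pitch

  dur <- traj$t[nrow(traj)] + 1 / attr(traj, "rate")
  nt <- round(dur * fs)
  th <- (seq_len(nt) - 1) / fs
  x <- approx(traj$t, traj$x, th, rule = 2)$y
  y <- approx(traj$t, traj$y, th, rule = 2)$y
  fv <- approx(traj$t, traj$fv, th, rule = 2)$y
  phase <- 2 * pi * cumsum(fv) / fs

  exy <- arena$electrode_xy
  d2 <- outer(exy[, 1], x, "-")^2 + outer(exy[, 2], y, "-")^2
  gain <- amplitude * exp(-d2 / (2 * ell^2))
  s <- gain * matrix(sin(phase), nrow(exy), nt, byrow = TRUE)

  if (is.finite(snr)) {
    peak_pow <- max(rowMeans(s^2))
    noise_sd <- sqrt(peak_pow / snr)
    s <- s + with_seed(seed, matrix(rnorm(length(s), sd = noise_sd),
      nrow(s), ncol(s)
    ))
  }

  structure(
    list(samples = s, fs = fs, arena = arena, truth = traj),
    class = "electrode_recording"
  )
}

#' @export
print.electrode_recording <- function(x, ...) {
  cat(sprintf(
    "<electrode_recording> %d channels x %d samples (%.1f s at %g Hz)\n",
    nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$fs, x$fs
  ))
  invisible(x)
}
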