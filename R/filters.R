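#' Band-pass / low-pass filter specification
#'
#' @param f_low,f_high pass-band edges in Hz. For `kind = "low-pass"` only
#'   `f_high` is used.
#' @param order Butterworth order (the filter is applied forward-backward,
#'   doubling the effective order and cancelling group delay).
#' @param kind `"band-pass"` or `"low-pass"`.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(f_low = 1, f_high = 10, order = 4,
                        kind = c("band-pass", "low-pass")) {
  kind <- match.arg(kind)
  if (order < 1) stop("order must be >= 1")
  if (kind == "band-pass" && !(0 < f_low && f_low < f_high)) {
    stop("need 0 < f_low < f_high")
  }
  if (kind == "low-pass" && f_high <= 0) stop("f_high must be positive")
  structure(list(f_low = f_low, f_high = f_high, order = order, kind = kind),
    class = "filter_spec"
  )
}

.design_filter <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$f_high >= nyq) stop("cutoff frequency at or above Nyquist")
  if (spec$kind == "band-pass") {
    signal::butter(spec$order, c(spec$f_low, spec$f_high) / nyq, type = "pass")
  } else {
    signal::butter(spec$order, spec$f_high / nyq, type = "low")
  }
}

# Zero-phase filtering with odd-reflection edge padding: filtfilt run on
# the bare series starts from zero initial conditions, which leaves a
# large transient on signals with non-zero mean or trend (e.g. position
# tracks). Reflecting the series about its end points before filtering
# and stripping the pads afterwards removes it.
zerophase_filter <- function(bf, x, dc_gain = 1) {
  n <- length(x)
  m <- mean(x)
  x <- x - m # keep the pad transient small for any DC level
  np <- min(n - 1, 300)
  y <- if (np < 3) {
    signal::filtfilt(bf, x)
  } else {
    head_pad <- 2 * x[1] - x[(np + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
    yy <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    yy[(np + 1):(np + n)]
  }
  y + dc_gain * m
}

# zero-phase filtering of the rows of a channels x time matrix
.filtfilt_rows <- function(bf, x) {
  out <- x
  for (i in seq_len(nrow(x))) out[i, ] <- zerophase_filter(bf, x[i, ], dc_gain = 0)
  out
}

#' Extract band-limited ventilatory signals
#'
#' Applies the ventilatory band-pass (default 1-10 Hz Butterworth) to every
#' channel of a recording, forward and backward so the output is zero-phase
#' (no group delay; a pulse's envelope peak stays put). Length is preserved.
#'
#' @param rec an `electrode_recording`.
#' @param spec a [filter_spec()]; must be valid for the recording's
#'   sampling rate.
#' @return The recording with filtered samples (`band` attribute records the
#'   pass band).
#' @export
bandpass_extract <- function(rec, spec = filter_spec()) {
  if (!inherits(rec, "electrode_recording")) stop("rec must be an electrode_recording")
  bf <- .design_filter(spec, rec$fs)
  rec$samples <- .filtfilt_rows(bf, rec$samples)
  rec$band <- c(spec$f_low, spec$f_high)
  rec
}
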