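# Burg autoregressive estimation, vectorised across the rows of a
# channels x samples matrix. Returns coefficients for the model
#   x[t] = sum_k a[k] x[t-k] + e[t]
# (same sign convention as stats::ar.burg$ar) plus the residual variance.
# The hand-vectorised recursion exists because the peak-map stage fits an
# AR model on every channel at every 33.33 Hz tick; per-channel ar.burg
# calls are kept as the independent oracle in the tests.
burg_ar <- function(x, order) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n <= order) stop("window length must exceed the AR order")
  C <- nrow(x)
  a <- matrix(0, C, order)
  E <- rowSums(x^2) / n
  fwd <- x[, 2:n, drop = FALSE]
  bwd <- x[, 1:(n - 1), drop = FALSE]
  for (m in seq_len(order)) {
    den <- rowSums(fwd^2) + rowSums(bwd^2)
    k <- ifelse(den > 0, 2 * rowSums(fwd * bwd) / den, 0)
    if (m > 1) {
      prev <- a[, 1:(m - 1), drop = FALSE]
      a[, 1:(m - 1)] <- prev - k * prev[, (m - 1):1, drop = FALSE]
    }
    a[, m] <- k
    E <- E * (1 - k^2)
    if (m < order) {
      fnew <- fwd - k * bwd
      bnew <- bwd - k * fwd
      nc <- ncol(fnew)
      fwd <- fnew[, 2:nc, drop = FALSE]
      bwd <- bnew[, 1:(nc - 1), drop = FALSE]
    }
  }
  list(ar = a, var = E)
}

# AR(p) power spectral density of each row at the given frequencies.
# psd(f) = var / (fs * |1 - sum_k a_k exp(-2 pi i f k / fs)|^2)
burg_psd <- function(fit, freqs, fs) {
  p <- ncol(fit$ar)
  basis <- exp(-2i * pi * outer(seq_len(p), freqs) / fs) # p x F
  denom <- 1 - fit$ar %*% basis # C x F complex
  sweep(1 / (Mod(denom)^2 * fs), 1, fit$var, "*")
}

#' Autoregressive power spectral density of one signal segment
#'
#' Estimates the spectrum of a single-channel window with a Burg AR model,
#' the estimator used to find the ventilatory peak: AR spectra resolve a
#' single 1-10 Hz peak from windows only a couple of cycles long, where the
#' periodogram is coarse. The peak location is invariant to amplitude
#' scaling of the segment. A constant (zero-variance) segment is flagged
#' degenerate and returns zero power rather than erroring.
#'
#' @param segment numeric vector of samples.
#' @param ar_order AR model order (default 10).
#' @param f_s sampling rate of the segment, Hz.
#' @param freqs frequencies (Hz) at which to evaluate the PSD; default is a
#'   0.01 Hz grid over \[0, f_s/2\].
#' @return List with `freq`, `psd` and logical `degenerate`.
#' @export
ar_psd <- function(segment, ar_order = 10, f_s,
                   freqs = seq(0, f_s / 2, by = 0.01)) {
  if (length(segment) <= ar_order) stop("window length must exceed ar_order")
  seg <- segment - mean(segment)
  if (var(seg) < .Machine$double.eps) {
    return(list(freq = freqs, psd = rep(0, length(freqs)), degenerate = TRUE))
  }
  fit <- burg_ar(seg, ar_order)
  list(
    freq = freqs,
    psd = as.numeric(burg_psd(fit, freqs, f_s)),
    degenerate = FALSE
  )
}
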