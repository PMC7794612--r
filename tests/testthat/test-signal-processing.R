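# Band-pass extraction, Burg AR spectra and peak maps

make_rec <- function(x, fs = 1000, arena = arena_geometry()) {
  # single-channel matrix replicated onto the first electrode; the rest zero
  s <- matrix(0, n_electrodes(arena), length(x))
  s[1, ] <- x
  structure(list(samples = s, fs = fs, arena = arena),
    class = "electrode_recording"
  )
}

test_that("filter specification is validated against the sampling rate", {
  expect_error(filter_spec(f_low = 5, f_high = 2), "f_low")
  expect_error(filter_spec(order = 0), "order")
  rec <- make_rec(sin(2 * pi * 3 * seq(0, 2, by = 1e-3)))
  expect_error(bandpass_extract(rec, filter_spec(1, 600)), "Nyquist")
})

test_that("the ventilatory band-pass removes DC and mains, keeps the band", {
  t <- seq(0, 6, by = 1e-3)[-1]
  # DC-only channels -> essentially zero output
  out <- bandpass_extract(make_rec(rep(2, length(t))))
  expect_lt(sqrt(mean(out$samples[1, ]^2)), 1e-6 * 2)

  # 5 Hz tone passes with < 5% amplitude error (interior, past edge ripple)
  out5 <- bandpass_extract(make_rec(sin(2 * pi * 5 * t)))
  core <- 1000:5000
  expect_lt(abs(sqrt(mean(out5$samples[1, core]^2)) - sqrt(0.5)) / sqrt(0.5),
            0.05)

  # 50 Hz attenuated by at least 20 dB
  out50 <- bandpass_extract(make_rec(sin(2 * pi * 50 * t)))
  expect_lt(sqrt(mean(out50$samples[1, core]^2)) / sqrt(0.5), 10^(-20 / 20))
})

test_that("zero-phase filtering preserves a burst envelope peak", {
  t <- seq(0, 6, by = 1e-3)[-1]
  env <- exp(-((t - 3)^2) / (2 * 0.4^2))
  x <- env * sin(2 * pi * 5 * t)
  out <- bandpass_extract(make_rec(x))
  smooth_env <- function(v) {
    as.numeric(stats::filter(abs(v), rep(1 / 201, 201), sides = 2))
  }
  # envelope centroid (argmax of the flat-topped envelope is dominated by
  # carrier ripple; the centroid pins the envelope's timing robustly)
  centroid <- function(e) {
    e[is.na(e)] <- 0
    w <- pmax(e - 0.5 * max(e), 0)
    sum(w * seq_along(e)) / sum(w)
  }
  e_in <- smooth_env(x)
  e_out <- smooth_env(out$samples[1, ])
  expect_lte(abs(centroid(e_out) - centroid(e_in)), 1)
})

test_that("burg recursion matches stats::ar.burg", {
  set.seed(42)
  x <- as.numeric(arima.sim(list(ar = c(0.6, -0.4, 0.2)), 400))
  ours <- burg_ar(x - mean(x), 3)
  ref <- ar.burg(x, aic = FALSE, order.max = 3, demean = TRUE)
  expect_equal(as.numeric(ours$ar), as.numeric(ref$ar), tolerance = 1e-10)
})

test_that("AR spectrum finds a tone where the periodogram does", {
  fs <- 50
  t <- seq(0, 2, by = 1 / fs)[-1]
  for (trial in 1:50) {
    f0 <- runif(1, 1.5, 9)
    seg <- with_seed(trial, sin(2 * pi * f0 * t) + rnorm(length(t), sd = 0.05))
    p <- ar_psd(seg, ar_order = 10, f_s = fs)
    f_ar <- p$freq[which.max(p$psd)]
    sp <- spec.pgram(ts(seg, frequency = fs), plot = FALSE, taper = 0,
                     pad = 7) # pad for a fine periodogram grid
    f_pg <- sp$freq[which.max(sp$spec)]
    expect_lt(abs(f_ar - f_pg), 0.5)
    if (trial == 1) {
      expect_lt(abs(f_ar - f0), 0.25)
      # amplitude scaling does not move the peak
      p10 <- ar_psd(10 * seg, ar_order = 10, f_s = fs)
      expect_equal(p$freq[which.max(p$psd)], p10$freq[which.max(p10$psd)])
    }
  }
})

test_that("constant segments flag a degenerate spectrum instead of erroring", {
  p <- ar_psd(rep(1.5, 100), ar_order = 10, f_s = 50)
  expect_true(p$degenerate)
  expect_true(all(p$psd == 0))
  expect_error(ar_psd(1:5, ar_order = 10, f_s = 50), "exceed")
})

test_that("a low-order AR fit of white noise rarely fakes an in-band peak", {
  fs <- 50
  fake <- vapply(1:100, function(i) {
    x <- with_seed(1000 + i, rnorm(2 * fs))
    p <- ar_psd(x, ar_order = 2, f_s = fs,
                freqs = seq(1, 10, by = 0.05))
    max(p$psd) > 3 * median(p$psd)
  }, logical(1))
  expect_lte(mean(fake), 0.10)
})

test_that("peak maps follow the documented tick policy", {
  rec <- stationary_recording(f0 = 3, duration = 10, snr = Inf)
  filt <- bandpass_extract(rec)
  maps <- compute_peak_maps(filt)
  # floor((N - window) / hop) + 1 ticks for a 10 s recording, 1 s window
  expect_equal(length(maps$t), floor((10000 - 1000) / 30) + 1)
  expect_true(all(maps$power >= 0 & is.finite(maps$power)))
  # window longer than the recording is rejected
  expect_error(compute_peak_maps(filt, window_s = 20), "longer")
})

test_that("peak maps recover a stationary ventilation tone on the near electrode", {
  a <- arena_geometry()
  rec <- stationary_recording(f0 = 3, x0 = 100, y0 = 70, duration = 8,
                              snr = Inf)
  maps <- compute_peak_maps(bandpass_extract(rec))
  el <- which.min((a$electrode_xy[, 1] - 100)^2 + (a$electrode_xy[, 2] - 70)^2)
  expect_true(all(abs(maps$freq[, el] - 3) <= 0.25))
  expect_true(all(maps$freq[is.finite(maps$freq)] >= 1 &
                    maps$freq[is.finite(maps$freq)] <= 10))
})

test_that("an all-zero recording yields zero peak power everywhere", {
  a <- arena_geometry()
  rec <- structure(
    list(samples = matrix(0, n_electrodes(a), 3000), fs = 1000, arena = a,
         band = c(1, 10)),
    class = "electrode_recording"
  )
  maps <- compute_peak_maps(rec)
  expect_true(all(maps$power == 0))
})
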