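# Velocity differentiation, stopping probability, window indices and
# baseline standardisation

tick_track <- function(x, y, dt = 0.03) {
  data.frame(t = (seq_along(x) - 1) * dt, x = x, y = y)
}

test_that("velocity differentiation is exact on ramps and antisymmetric", {
  n <- 400
  cst <- tick_track(rep(10, n), rep(20, n))
  v <- differentiate_positions(cst)
  expect_true(all(abs(v$speed) < 1e-9))

  ramp <- tick_track(10 + 10 * (seq_len(n) - 1) * 0.03, rep(0, n))
  vr <- differentiate_positions(ramp)
  core <- 100:300
  expect_true(all(abs(vr$vx[core] - 10) / 10 < 0.02))

  # reversing the trajectory negates the velocity (interior ticks; the
  # zero-phase filter's edge padding is not exactly time-symmetric)
  rev_ramp <- tick_track(rev(ramp$x), rep(0, n))
  vrev <- differentiate_positions(rev_ramp)
  expect_equal(vrev$vx[core], -rev(vr$vx)[core], tolerance = 1e-6)

  expect_error(differentiate_positions(ramp[1:2, ]), "3 ticks")
})

test_that("stopping probability counts sub-threshold ticks", {
  expect_equal(stopping_probability(rep(1, 50), v_stop = 3), 100)
  expect_equal(stopping_probability(rep(9, 50), v_stop = 3), 0)
  sp <- c(rep(1, 33), rep(10, 132)) # 33 of 165 ticks below threshold
  expect_equal(stopping_probability(sp, v_stop = 3), 20)
  expect_error(stopping_probability(numeric(0)), "empty")
})

test_that("vectorised stopping probability equals a per-tick loop exactly", {
  for (i in 1:100) {
    speeds <- with_seed(i, runif(165, 0, 40))
    v_stop <- with_seed(1000 + i, runif(1, 1, 20))
    brute <- 0
    for (s in speeds) if (s < v_stop) brute <- brute + 1
    expect_identical(
      stopping_probability(speeds, v_stop),
      100 * brute / length(speeds)
    )
  }
})

test_that("ventilatory frequency reads the nearest electrode's peak", {
  a <- arena_geometry(30, 10, nx = 2, ny = 2) # electrodes at x = 7.5, 22.5
  nt <- 5
  maps <- structure(
    list(
      t = (0:(nt - 1)) * 0.03,
      freq = matrix(rep(c(2, 8, 2, 8), each = nt), nt, 4),
      power = matrix(1, nt, 4),
      arena = a, band = c(1, 10)
    ),
    class = "peak_maps"
  )
  on_first <- data.frame(t = maps$t, x = rep(7.5, nt), y = rep(2.5, nt))
  expect_equal(ventilatory_frequency_at(on_first, maps),
               rep(2, nt), ignore_attr = TRUE)

  # crossing the midpoint switches the assigned electrode exactly once
  crossing <- data.frame(t = maps$t, x = seq(10, 20, length.out = nt),
                         y = rep(2.5, nt))
  fv <- ventilatory_frequency_at(crossing, maps)
  expect_equal(sum(diff(fv) != 0), 1)

  # degenerate (NA) ticks carry the last valid value forward
  maps$freq[3, ] <- NA
  fv2 <- ventilatory_frequency_at(on_first, maps)
  expect_equal(fv2[3], 2, ignore_attr = TRUE)
  expect_true(attr(fv2, "carried")[3])
})

test_that("windowed indices aggregate 5 s windows correctly", {
  fm <- 1000 / 30
  nt <- round(300 * fm)
  vel <- data.frame(t = (seq_len(nt) - 1) / fm, speed = rep(12, nt))
  win <- windowed_indices(vel, fv = rep(3.2, nt))
  expect_equal(nrow(win), 60)
  expect_true(all(win$v_sd == 0))
  expect_true(all(win$fv_sd == 0))
  expect_true(all(win$p_stop == 0))

  # alternating 0 / 20 mm/s, v_stop = 5: P_stop 50 %, mean 10 mm/s
  nt2 <- round(5 * fm)
  vel2 <- data.frame(t = (seq_len(nt2) - 1) / fm,
                     speed = rep(c(0, 20), length.out = nt2))
  win2 <- windowed_indices(vel2, fv = rep(3, nt2), v_stop = 5)
  expect_equal(nrow(win2), 1)
  expect_equal(win2$p_stop, 50, tolerance = 1)
  expect_equal(win2$v_mean, 10, tolerance = 0.2)

  expect_error(windowed_indices(vel2, fv = rep(3, nt2), window = 0.05),
               "3 ticks")
})

test_that("standardisation maps the baseline to mean 0, SD 1 and is idempotent", {
  win <- small_cohort(seed = 5, duration = 60, fear_fish = 1:2,
                      ethanol_fish = integer(0))
  std <- standardise_windows(win)
  for (fish in unique(std$fish_id)) {
    base <- std[std$fish_id == fish & std$state == "normal", ]
    for (cl in ventrack:::index_columns()) {
      expect_equal(mean(base[[cl]]), 0, tolerance = 1e-12)
      expect_equal(sd(base[[cl]]), 1, tolerance = 1e-12)
    }
  }
  expect_equal(standardise_windows(std), std, tolerance = 1e-12)
})

test_that("standardisation arithmetic and degenerate baselines", {
  win <- data.frame(
    fish_id = 1, state = rep(c("normal", "fear"), each = 3),
    t0 = seq(0, 25, by = 5),
    v_mean = c(8, 10, 12, 14, 14, 14), p_stop = c(1, 2, 3, 3, 3, 3),
    fv_mean = c(2.9, 3, 3.1, 3, 3, 3), v_sd = c(1, 2, 3, 2, 2, 2),
    p_stop_sd = c(1, 2, 3, 2, 2, 2), fv_sd = c(.1, .2, .3, .2, .2, .2),
    standardised = FALSE
  )
  std <- standardise_windows(win)
  # baseline mean 10, sd 2 -> value 14 maps to z = 2
  expect_equal(std$v_mean[4], 2)
  # all values at the baseline mean map to zero
  expect_true(all(abs(std$p_stop[4:6] - (3 - 2) / 1) < 1e-12))

  win$fv_sd <- 0.2 # constant baseline
  expect_error(standardise_windows(win), "fv_sd")
})
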