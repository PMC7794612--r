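# Virtual aquarium: arena geometry, behavioural simulation, signal rendering

test_that("default arena matches the measurement aquarium layout", {
  a <- arena_geometry()
  expect_equal(nrow(a$electrode_xy), 126)
  expect_equal(c(a$nx, a$ny), c(14, 9))
  expect_true(all(a$electrode_xy[, 1] >= 0 & a$electrode_xy[, 1] <= 210))
  expect_true(all(a$electrode_xy[, 2] >= 0 & a$electrode_xy[, 2] <= 140))
  expect_equal(a$pitch_x, 15)
})

test_that("behaviour parameters are validated", {
  expect_error(behaviour_params("fear", mean_speed = -1), "non-negative")
  expect_error(behaviour_params("normal", vent_base = 0.5), "pass band")
  expect_error(behaviour_params("normal", vent_base = 12), "pass band")
  expect_error(behaviour_params("normal", heading_persistence = 1), "persistence")
})

test_that("a permanently frozen fish does not move", {
  p <- behaviour_params("fear",
    freeze_rate = Inf, freeze_duration = 60, hold_speed = 0,
    decay_floor = 1, decay_tau = Inf
  )
  traj <- simulate_trajectory(p, 60, seed = 4)
  expect_true(all(traj$speed == 0))
  expect_true(all(traj$vx == 0 & traj$vy == 0))
  expect_equal(length(unique(traj$x)), 1)
})

test_that("trajectories stay inside the arena for every state", {
  for (state in c("normal", "fear", "appetitive")) {
    traj <- simulate_trajectory(behaviour_params(state), 60, seed = 11)
    expect_true(all(traj$x >= 0 & traj$x <= 210), info = state)
    expect_true(all(traj$y >= 0 & traj$y <= 140), info = state)
    expect_true(all(traj$fv > 0))
    # velocity is the discrete derivative of position
    dt <- 1 / attr(traj, "rate")
    expect_equal(traj$vx[-1], diff(traj$x) / dt, tolerance = 1e-12)
  }
})

test_that("identical seeds give bit-identical trajectories and signals", {
  p <- behaviour_params("appetitive")
  t1 <- simulate_trajectory(p, 20, seed = 7)
  t2 <- simulate_trajectory(p, 20, seed = 7)
  expect_identical(t1, t2)
  r1 <- render_signals(t1, snr = 8, seed = 3)
  r2 <- render_signals(t2, snr = 8, seed = 3)
  expect_identical(r1$samples, r2$samples)
  t3 <- simulate_trajectory(p, 20, seed = 8)
  expect_false(identical(t1$x, t3$x))
})

test_that("fear lowers swimming speed and raises ventilation frequency", {
  trn <- simulate_trajectory(behaviour_params("normal"), 300, seed = 1)
  trf <- simulate_trajectory(behaviour_params("fear"), 300, seed = 1)
  expect_lt(mean(trf$speed), mean(trn$speed))
  expect_gt(mean(trf$fv), mean(trn$fv))
})

test_that("a stationary fish on an electrode dominates that channel", {
  a <- arena_geometry()
  el <- 40
  rec <- stationary_recording(
    f0 = 3, x0 = a$electrode_xy[el, 1], y0 = a$electrode_xy[el, 2],
    duration = 4, snr = Inf
  )
  rms <- sqrt(rowMeans(rec$samples^2))
  expect_equal(which.max(rms), el)
})

test_that("rendered ventilation carrier sits at the programmed frequency", {
  rec <- stationary_recording(f0 = 3, duration = 8, snr = Inf)
  ch <- which.max(sqrt(rowMeans(rec$samples^2)))
  sp <- spec.pgram(ts(rec$samples[ch, ], frequency = rec$fs), plot = FALSE,
                   taper = 0)
  fpk <- sp$freq[which.max(sp$spec)]
  expect_lt(abs(fpk - 3), 1 / 8 + 1e-9) # within one FFT bin of an 8 s record
})

test_that("increasing snr raises the measured in-band to out-of-band ratio", {
  band_ratio <- function(snr) {
    rec <- stationary_recording(f0 = 3, duration = 6, snr = snr, seed = 5)
    ch <- which.max(sqrt(rowMeans(rec$samples^2)))
    sp <- spec.pgram(ts(rec$samples[ch, ], frequency = rec$fs), plot = FALSE,
                     taper = 0)
    inband <- sp$freq > 2.5 & sp$freq < 3.5
    sum(sp$spec[inband]) / sum(sp$spec[!inband])
  }
  expect_gt(band_ratio(10), band_ratio(5))
})

test_that("noiseless channel power decays with distance from the fish", {
  a <- arena_geometry()
  rec <- stationary_recording(f0 = 3, x0 = 100, y0 = 70, duration = 4,
                              snr = Inf)
  rms <- sqrt(rowMeans(rec$samples^2))
  d <- sqrt((a$electrode_xy[, 1] - 100)^2 + (a$electrode_xy[, 2] - 70)^2)
  ord <- order(d)
  expect_true(all(diff(rms[ord]) <= 1e-9))
})

test_that("rendering rejects mismatched geometry and bad snr", {
  traj <- simulate_trajectory(behaviour_params("normal"), 5, seed = 1)
  other <- arena_geometry(100, 80)
  expect_error(render_signals(traj, other), "do not match")
  expect_error(render_signals(traj, snr = 0), "snr")
})

test_that("cohort generation respects the plan arithmetic", {
  # one fish, one state, 300 s -> 60 windows
  cfg <- cohort_config(seed = 2, duration = 300, fear_fish = 1,
                       ethanol_fish = integer(0))
  cfg$plan <- cfg$plan[cfg$plan$state == "normal", ]
  win <- generate_cohort(cfg)
  expect_equal(nrow(win), 60)

  # empty plan -> empty collection
  cfg0 <- cohort_config(fear_fish = integer(0), ethanol_fish = integer(0))
  expect_equal(nrow(generate_cohort(cfg0)), 0)

  # duplicate fish ids rejected
  expect_error(cohort_config(fear_fish = c(1, 1)), "duplicate")
  expect_error(cohort_config(fear_fish = 1:3, ethanol_fish = 3:4), "duplicate")

  # small two-experiment cohort: windows per fish-state and labelling
  win2 <- small_cohort(seed = 3, duration = 50)
  expect_equal(nrow(win2), (4 + 3) * 2 * 10)
  expect_setequal(unique(win2$state), c("normal", "fear", "appetitive"))
})
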