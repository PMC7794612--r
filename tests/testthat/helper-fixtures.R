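# Shared fixture builders. Everything is generated in code at test time;
# recordings are kept short so the whole suite stays fast.

# a trajectory with fully prescribed position/ventilation, bypassing the
# behavioural model (for rendering and tracking oracles)
scripted_trajectory <- function(x, y, fv, rate = 100,
                                arena = arena_geometry(), state = "normal") {
  n <- max(length(x), length(y), length(fv))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  fv <- rep_len(fv, n)
  dt <- 1 / rate
  vx <- c(0, diff(x)) / dt
  vy <- c(0, diff(y)) / dt
  if (n > 1) {
    vx[1] <- vx[2]
    vy[1] <- vy[2]
  }
  traj <- data.frame(
    t = (seq_len(n) - 1) * dt, x = x, y = y, vx = vx, vy = vy,
    speed = sqrt(vx^2 + vy^2), fv = fv, holding = FALSE, state = state,
    stringsAsFactors = FALSE
  )
  attr(traj, "arena") <- arena
  attr(traj, "rate") <- rate
  attr(traj, "fish_id") <- 1L
  attr(traj, "params") <- behaviour_params(state)
  class(traj) <- c("ground_truth_trajectory", "data.frame")
  traj
}

stationary_recording <- function(f0 = 3, x0 = 100, y0 = 70, duration = 8,
                                 snr = Inf, seed = 1,
                                 arena = arena_geometry()) {
  n <- duration * 100
  traj <- scripted_trajectory(rep(x0, n), rep(y0, n), rep(f0, n),
                              arena = arena)
  render_signals(traj, arena, snr = snr, seed = seed)
}

# small labelled Gaussian clouds for classifier tests
gaussian_classes <- function(n, means, sd = 1, seed = 1, labels = NULL) {
  with_seed(seed, {
    d <- ncol(means)
    x <- do.call(rbind, lapply(seq_len(nrow(means)), function(k) {
      matrix(rnorm(n * d, sd = sd), n, d) +
        matrix(means[k, ], n, d, byrow = TRUE)
    }))
    list(
      x = x,
      labels = labels %||% rep(paste0("class", seq_len(nrow(means))), each = n)
    )
  })
}

with_seed <- ventrack:::with_seed
`%||%` <- ventrack:::`%||%`

# a small index cohort (fewer fish, shorter recordings) for structural tests
small_cohort <- function(seed = 1, duration = 100, fear_fish = 1:4,
                         ethanol_fish = 5:7) {
  generate_cohort(cohort_config(
    seed = seed, duration = duration,
    fear_fish = fear_fish, ethanol_fish = ethanol_fish
  ))
}

# Index table with a designed correlation structure for the PC-count
# experiments. The six indices form three correlated pairs (rho = 0.8,
# 0.6, 0.5). Class 2 shifts along the sum axis of pair two; class 3
# shifts along the *difference* axis of pair three, whose eigenvalue sits
# fourth in the correlation spectrum -- so class 3 is separable only once
# the fourth principal component is included.
latent_cohort <- function(n_per = 30, fish_per = 4, shift3 = 1.6,
                          shift4 = 1.5, seed = 21) {
  with_seed(seed, {
    states <- c("normal", "fear", "appetitive")
    rho <- c(0.8, 0.6, 0.5)
    rows <- list()
    fid <- 0
    for (s in seq_along(states)) {
      for (f in seq_len(fish_per)) {
        fid <- fid + 1
        x <- matrix(0, n_per, 6)
        for (p in 1:3) {
          u <- rnorm(n_per)
          x[, 2 * p - 1] <- sqrt(rho[p]) * u + sqrt(1 - rho[p]) * rnorm(n_per)
          x[, 2 * p] <- sqrt(rho[p]) * u + sqrt(1 - rho[p]) * rnorm(n_per)
        }
        if (s == 2) x[, 3:4] <- x[, 3:4] + shift3 / sqrt(2)
        if (s == 3) {
          x[, 5] <- x[, 5] + shift4 / sqrt(2)
          x[, 6] <- x[, 6] - shift4 / sqrt(2)
        }
        df <- as.data.frame(x)
        names(df) <- ventrack:::index_columns()
        df$fish_id <- fid
        df$state <- states[s]
        df$t0 <- (seq_len(n_per) - 1) * 5
        df$standardised <- TRUE
        rows[[fid]] <- df
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("index_windows", "data.frame")
    out
  })
}

# shared cache for the acceptance cohort (built once per test run)
.acc_cache <- new.env(parent = emptyenv())
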