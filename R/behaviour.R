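#' Behavioural parameters for one emotional state
#'
#' Parameterises the state-dependent movement and ventilation programme used
#' by the virtual aquarium. Movement is a two-mode semi-Markov process: the
#' fish alternates between a *move* mode (correlated random walk whose speed
#' follows an Ornstein-Uhlenbeck (OU) process around `mean_speed`, with
#' occasional short darts at `dart_speed`) and a *hold* mode (freezing or
#' station-holding at the constant `hold_speed`). Instantaneous ventilation
#' frequency follows an OU process with mean `vent_base` and stationary SD
#' `vent_sd`.
#'
#' The three state presets are calibrated so that a simulated cohort
#' reproduces the qualitative index fingerprint reported for zebrafish:
#' fear/anxiety shows low speed, frequent freezing with elevated ventilation
#' frequency and a stabilised short-term speed/frequency variability;
#' appetitive behaviour shows normal-level ventilation frequency with a
#' *more* stable respiratory rhythm but highly variable locomotion (bouts of
#' cruising alternating with station-holding).
#'
#' @param state one of `"normal"`, `"fear"`, `"appetitive"`; selects the
#'   preset that unspecified arguments default to.
#' @param mean_speed mean cruising speed in move mode, mm/s.
#' @param speed_sd stationary SD of the OU speed fluctuation, mm/s.
#' @param speed_tau OU relaxation time of the speed process, s.
#' @param freeze_rate rate of initiating hold bouts, 1/s (hazard while moving).
#' @param freeze_duration mean hold-bout duration, s (exponential).
#' @param dart_rate rate of darting events while moving, 1/s.
#' @param dart_speed speed during a dart, mm/s.
#' @param dart_duration dart duration, s.
#' @param hold_speed residual speed in hold mode, mm/s (drift/fin motion).
#' @param vent_base mean ventilation frequency, Hz; must lie in (1, 10) so
#'   the rendered signal survives the 1-10 Hz band-pass.
#' @param vent_sd stationary SD of the ventilation-frequency OU process, Hz.
#' @param vent_tau OU relaxation time of the ventilation frequency, s.
#' @param heading_persistence dimensionless in \[0, 1); 1 means straight
#'   swimming. Heading diffuses at `(1 - heading_persistence) * 2 * pi`
#'   rad per sqrt(s) while moving.
#' @param wall_margin distance (mm) from a wall at which avoidance steering
#'   begins.
#' @param wall_gain avoidance steering gain, 1/s (heading relaxation rate
#'   toward the inward normal inside the margin).
#' @param decay_floor,decay_tau within-session decay of the *motion*
#'   response: the deviation from the resting programme relaxes from full
#'   strength at stimulus onset toward `decay_floor` (fraction) with time
#'   constant `decay_tau` seconds. `decay_floor = 1` disables decay.
#' @param vent_decay_floor,vent_decay_tau decay of the *ventilatory*
#'   response; defaults to the motion decay. The fear preset decays on both
#'   channels, the ventilatory one faster (acutely elevated ventilation
#'   fades within a couple of minutes of alarm-pheromone exposure, while
#'   freezing lingers).
#' @param rest_mean_speed,rest_vent_base,rest_vent_sd the resting-programme
#'   values the response decays toward (default: the normal-state preset).
#' @return An object of class `behaviour_params` (named list).
#' @export
behaviour_params <- function(state = c("normal", "fear", "appetitive"),
                             mean_speed = NULL, speed_sd = NULL,
                             speed_tau = NULL,
                             freeze_rate = NULL, freeze_duration = NULL,
                             dart_rate = NULL, dart_speed = NULL,
                             dart_duration = NULL, hold_speed = NULL,
                             vent_base = NULL, vent_sd = NULL,
                             vent_tau = NULL,
                             heading_persistence = NULL,
                             wall_margin = NULL, wall_gain = NULL,
                             decay_floor = NULL, decay_tau = NULL,
                             vent_decay_floor = NULL, vent_decay_tau = NULL,
                             rest_mean_speed = NULL, rest_vent_base = NULL,
                             rest_vent_sd = NULL) {
  state <- match.arg(state)
  preset <- .state_presets[[state]]
  p <- list(
    state = state,
    mean_speed = mean_speed %||% preset$mean_speed,
    speed_sd = speed_sd %||% preset$speed_sd,
    speed_tau = speed_tau %||% preset$speed_tau,
    freeze_rate = freeze_rate %||% preset$freeze_rate,
    freeze_duration = freeze_duration %||% preset$freeze_duration,
    dart_rate = dart_rate %||% preset$dart_rate,
    dart_speed = dart_speed %||% preset$dart_speed,
    dart_duration = dart_duration %||% preset$dart_duration,
    hold_speed = hold_speed %||% preset$hold_speed,
    vent_base = vent_base %||% preset$vent_base,
    vent_sd = vent_sd %||% preset$vent_sd,
    vent_tau = vent_tau %||% preset$vent_tau,
    heading_persistence = heading_persistence %||% preset$heading_persistence,
    wall_margin = wall_margin %||% preset$wall_margin,
    wall_gain = wall_gain %||% preset$wall_gain,
    decay_floor = decay_floor %||% preset$decay_floor %||% 1,
    decay_tau = decay_tau %||% preset$decay_tau %||% Inf,
    vent_decay_floor = vent_decay_floor %||% preset$vent_decay_floor %||%
      decay_floor %||% preset$decay_floor %||% 1,
    vent_decay_tau = vent_decay_tau %||% preset$vent_decay_tau %||%
      decay_tau %||% preset$decay_tau %||% Inf,
    rest_mean_speed = rest_mean_speed %||% .state_presets$normal$mean_speed,
    rest_vent_base = rest_vent_base %||% .state_presets$normal$vent_base,
    rest_vent_sd = rest_vent_sd %||% .state_presets$normal$vent_sd
  )
  num <- p[setdiff(names(p), "state")]
  if (any(!vapply(num, function(v) is.numeric(v) && length(v) == 1, TRUE))) {
    stop("behaviour parameters must be numeric scalars")
  }
  nonneg <- c(
    "mean_speed", "speed_sd", "speed_tau", "freeze_rate", "freeze_duration",
    "dart_rate", "dart_speed", "dart_duration", "hold_speed",
    "vent_sd", "vent_tau", "wall_margin", "wall_gain"
  )
  if (any(unlist(p[nonneg]) < 0)) {
    stop("rates, speeds and durations must be non-negative")
  }
  if (p$vent_base <= 1 || p$vent_base >= 10) {
    stop("vent_base must lie strictly inside the (1, 10) Hz pass band")
  }
  if (p$heading_persistence < 0 || p$heading_persistence >= 1) {
    stop("heading_persistence must lie in [0, 1)")
  }
  if (p$decay_floor < 0 || p$decay_floor > 1 ||
      p$vent_decay_floor < 0 || p$vent_decay_floor > 1) {
    stop("decay floors must lie in [0, 1]")
  }
  structure(p, class = "behaviour_params")
}

# Calibrated state presets (see the methods vignette for the rationale and
# the qualitative directions each one is meant to reproduce).
.state_presets <- list(
  normal = list(
    mean_speed = 28, speed_sd = 10, speed_tau = 4,
    freeze_rate = 0.04, freeze_duration = 1.3,
    dart_rate = 0.02, dart_speed = 90, dart_duration = 0.3,
    hold_speed = 0.5,
    vent_base = 3.0, vent_sd = 0.35, vent_tau = 2,
    heading_persistence = 0.98,
    wall_margin = 40, wall_gain = 2
  ),
  fear = list(
    mean_speed = 10, speed_sd = 5, speed_tau = 1.5,
    freeze_rate = 0.28, freeze_duration = 4,
    dart_rate = 0.02, dart_speed = 110, dart_duration = 0.3,
    hold_speed = 0.3,
    vent_base = 4.8, vent_sd = 0.12, vent_tau = 2,
    heading_persistence = 0.55,
    wall_margin = 30, wall_gain = 3,
    decay_floor = 0.5, decay_tau = 200,
    vent_decay_floor = 0.05, vent_decay_tau = 55
  ),
  appetitive = list(
    mean_speed = 29, speed_sd = 12, speed_tau = 2,
    freeze_rate = 0.07, freeze_duration = 5,
    dart_rate = 0.04, dart_speed = 100, dart_duration = 0.3,
    hold_speed = 0.4,
    vent_base = 3.0, vent_sd = 0.2, vent_tau = 2,
    heading_persistence = 0.8,
    wall_margin = 30, wall_gain = 3
  )
)

#' @export
print.behaviour_params <- function(x, ...) {
  cat(sprintf(
    "<behaviour_params> state=%s, mean speed %.1f mm/s, ventilation %.1f +/- %.2f Hz\n",
    x$state, x$mean_speed, x$vent_base, x$vent_sd
  ))
  invisible(x)
}

# Ornstein-Uhlenbeck sample path of length n around 0 (stationary start).
.ou_path <- function(n, sd, tau, dt) {
  if (sd <= 0 || n == 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov <- rnorm(n, sd = sd * sqrt(1 - a^2))
  innov[1] <- rnorm(1, sd = sd)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# Alternating move/hold bout labels, TRUE where holding.
.hold_mask <- function(n, dt, rate, mean_dur) {
  if (n == 0) return(logical(0))
  if (!is.finite(rate) && rate > 0) { # degenerate: permanently holding
    return(rep(TRUE, n))
  }
  if (rate <= 0 || mean_dur <= 0) return(rep(FALSE, n))
  total <- n * dt
  durs <- numeric(0)
  holds <- logical(0)
  acc <- 0
  moving <- TRUE
  while (acc < total) {
    d <- if (moving) rexp(1, rate) else rexp(1, 1 / mean_dur)
    durs <- c(durs, d)
    holds <- c(holds, !moving)
    acc <- acc + d
    moving <- !moving
  }
  counts <- pmax(0, round(durs / dt))
  mask <- rep(holds, counts)
  length(mask) <- n # pad/truncate
  mask[is.na(mask)] <- holds[length(holds)]
  mask
}

#' Simulate one ground-truth fish trajectory
#'
#' Generates a seeded, state-dependent trajectory (position, velocity,
#' instantaneous ventilation frequency) inside a rectangular arena.
#' Movement is a correlated random walk with semi-Markov hold (freezing /
#' station-holding) bouts and Poisson darts; boundaries are reflective, so
#' the fish never leaves the arena. Velocity is defined as the discrete
#' backward difference of position, so it is exactly consistent with the
#' returned positions (including wall reflections).
#'
#' @param params a [behaviour_params()] object.
#' @param duration simulated duration, s (> 0).
#' @param arena an [arena_geometry()].
#' @param seed integer; fixes all randomness (identical seed, identical
#'   trajectory).
#' @param rate simulation rate, Hz. The default 100 Hz is an integer
#'   multiple of the 33.33 Hz analysis tick rate.
#' @param fish_id identifier stored with the trajectory.
#' @return A `ground_truth_trajectory`: a data frame with columns
#'   `t` (s), `x`, `y` (mm), `vx`, `vy`, `speed` (mm/s), `fv` (Hz),
#'   `holding` (logical) and `state`, with the arena, rate, fish id and
#'   parameters attached as attributes.
#' @export
simulate_trajectory <- function(params, duration, arena = arena_geometry(),
                                seed = 1, rate = 100, fish_id = 1L) {
  if (!inherits(params, "behaviour_params")) stop("params must be behaviour_params")
  if (!inherits(arena, "arena_geometry") || n_electrodes(arena) < 1) {
    stop("arena must be a non-empty arena_geometry")
  }
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  dt <- 1 / rate
  n <- round(duration * rate)
  if (n < 2) stop("duration too short for the simulation rate")

  with_seed(seed, {
    # within-session response decay profiles (1 at onset -> floor)
    profile <- function(floor, tau) {
      if (is.finite(tau) && floor < 1) {
        floor + (1 - floor) * exp(-(seq_len(n) - 1) * dt / tau)
      } else {
        rep(1, n)
      }
    }
    r_t <- profile(params$decay_floor, params$decay_tau)
    r_vent <- profile(params$vent_decay_floor, params$vent_decay_tau)

    hold <- .hold_mask(n, dt, params$freeze_rate, params$freeze_duration)
    if (any(r_t < 1) && any(hold)) {
      # thin hold bouts as the response fades: each bout survives with the
      # probability given by the decay profile at its onset
      runs <- rle(hold)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (j in which(runs$values)) {
        if (runif(1) > r_t[starts[j]]) hold[starts[j]:ends[j]] <- FALSE
      }
    }

    # darts: Poisson starts, active for dart_duration, only while moving
    dart <- rep(FALSE, n)
    if (params$dart_rate > 0 && params$dart_duration > 0) {
      k <- rpois(1, params$dart_rate * duration)
      if (k > 0) {
        starts <- sort(ceiling(runif(k) * n))
        len <- max(1L, round(params$dart_duration / dt))
        for (s in starts) dart[s:min(n, s + len - 1L)] <- TRUE
      }
      dart <- dart & !hold
    }

    mean_t <- params$rest_mean_speed +
      (params$mean_speed - params$rest_mean_speed) * r_t
    speed <- pmax(0, mean_t + .ou_path(n, params$speed_sd, params$speed_tau, dt))
    speed[dart] <- params$dart_speed
    speed[hold] <- params$hold_speed

    sigma_theta <- (1 - params$heading_persistence) * 2 * pi
    dtheta <- rnorm(n, sd = sigma_theta * sqrt(dt))
    dtheta[hold] <- 0
    theta0 <- runif(1, 0, 2 * pi)
    x0 <- runif(1, 0.1, 0.9) * arena$width_x
    y0 <- runif(1, 0.1, 0.9) * arena$width_y
    pos <- .integrate_walk(x0, y0, theta0, speed, dtheta, dt,
                           arena$width_x, arena$width_y,
                           margin = params$wall_margin,
                           steer_gain = params$wall_gain)
    x <- pos$x
    y <- pos$y

    vx <- c(0, diff(x)) / dt
    vy <- c(0, diff(y)) / dt
    vx[1] <- vx[2]
    vy[1] <- vy[2]

    vb_t <- params$rest_vent_base +
      (params$vent_base - params$rest_vent_base) * r_vent
    vsd_t <- params$rest_vent_sd +
      (params$vent_sd - params$rest_vent_sd) * r_vent
    ou_v <- .ou_path(n, params$vent_sd, params$vent_tau, dt)
    if (params$vent_sd > 0) ou_v <- ou_v * (vsd_t / params$vent_sd)
    fv <- pmin(pmax(vb_t + ou_v, 1.05), 9.5)

    traj <- data.frame(
      t = (seq_len(n) - 1) * dt,
      x = x, y = y, vx = vx, vy = vy,
      speed = sqrt(vx^2 + vy^2),
      fv = fv, holding = hold,
      state = params$state,
      stringsAsFactors = FALSE
    )
    attr(traj, "arena") <- arena
    attr(traj, "rate") <- rate
    attr(traj, "fish_id") <- fish_id
    attr(traj, "params") <- params
    class(traj) <- c("ground_truth_trajectory", "data.frame")
    traj
  })
}

# Fold an unbounded coordinate into [0, w] by specular reflection.
.reflect_fold <- function(x, w) {
  p <- x %% (2 * w)
  ifelse(p > w, 2 * w - p, p)
}

# Stepwise integration of the correlated walk with specular wall
# reflection and mild wall-avoidance steering: inside `margin` of a wall
# the heading relaxes toward the inward normal at rate `steer_gain`
# (1/s), mimicking collision avoidance, so the fish does not spend long
# stretches pressed against the boundary.
.integrate_walk <- function(x0, y0, theta0, speed, dtheta, dt, wx, wy,
                            margin, steer_gain) {
  n <- length(speed)
  x <- numeric(n)
  y <- numeric(n)
  xi <- x0
  yi <- y0
  th <- theta0
  for (i in seq_len(n)) {
    rx <- max(0, 1 - xi / margin) - max(0, 1 - (wx - xi) / margin)
    ry <- max(0, 1 - yi / margin) - max(0, 1 - (wy - yi) / margin)
    if ((rx != 0 || ry != 0) && speed[i] > 0) {
      th <- th + steer_gain * sin(atan2(ry, rx) - th) * dt
    }
    th <- th + dtheta[i]
    xi <- xi + speed[i] * cos(th) * dt
    yi <- yi + speed[i] * sin(th) * dt
    if (xi < 0 || xi > wx) {
      xi <- .reflect_fold(xi, wx)
      th <- pi - th
    }
    if (yi < 0 || yi > wy) {
      yi <- .reflect_fold(yi, wy)
      th <- -th
    }
    x[i] <- xi
    y[i] <- yi
  }
  list(x = x, y = y)
}
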