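#' Cohort configuration mirroring the study's sample structure
#'
#' The default plan reproduces the study's two experiments: fifteen fish
#' (ids 1-15) each observed 5 min in the normal state and 5 min after alarm
#' pheromone exposure (fear/anxiety), and eight fish (ids 16-23) observed
#' 5 min on the pre-conditioning day (normal) and 5 min after ethanol place
#' preference conditioning (appetitive). At 60 windows of 5 s per
#' fish-state this yields 2760 index windows.
#'
#' @param seed base seed; per-recording seeds are derived from it.
#' @param duration seconds of data per fish-state.
#' @param fear_fish,ethanol_fish fish ids in each experiment (disjoint).
#' @param window,sub_window,v_stop index-window parameters, see
#'   [windowed_indices()].
#' @param rate trajectory simulation rate, Hz.
#' @param tick_hz analysis tick rate, Hz; `rate` must be an integer
#'   multiple.
#' @param fish_variability log-SD of the per-fish response-strength
#'   multiplier: each fish's treatment-state parameters are pulled toward /
#'   pushed past the preset by a lognormal factor, so some fish respond
#'   weakly and overlap the normal state (as real cohorts do). 0 disables.
#' @param baseline_vent_sd SD (Hz) of the per-fish offset on resting
#'   ventilation frequency (shared by both of that fish's recordings).
#' @param baseline_speed_sd log-SD of the per-fish cruising-speed
#'   multiplier (shared across states).
#' @return An `experiment_cohort_config` list with a `plan` data frame
#'   (fish_id, state, phase, duration, seed).
#' @export
cohort_config <- function(seed = 1, duration = 300,
                          fear_fish = 1:15, ethanol_fish = 16:23,
                          window = 5, sub_window = 1, v_stop = 3,
                          rate = 100, tick_hz = 1000 / 30,
                          fish_variability = 0,
                          baseline_vent_sd = 0.08,
                          baseline_speed_sd = 0.08) {
  if (length(intersect(fear_fish, ethanol_fish)) > 0) {
    stop("duplicate fish ids across experiments")
  }
  if (anyDuplicated(fear_fish) || anyDuplicated(ethanol_fish)) {
    stop("duplicate fish ids")
  }
  plan <- rbind(
    do.call(rbind, lapply(fear_fish, function(f) {
      data.frame(
        fish_id = f, state = c("normal", "fear"),
        phase = c("before", "after"), experiment = "alarm_pheromone",
        duration = duration, stringsAsFactors = FALSE
      )
    })),
    do.call(rbind, lapply(ethanol_fish, function(f) {
      data.frame(
        fish_id = f, state = c("normal", "appetitive"),
        phase = c("before", "after"), experiment = "ethanol",
        duration = duration, stringsAsFactors = FALSE
      )
    }))
  )
  if (!is.null(plan)) {
    plan$seed <- (seed %% 20000L) * 100000L + plan$fish_id * 10L +
      as.integer(factor(plan$state, c("normal", "fear", "appetitive")))
  }
  structure(
    list(
      seed = seed, plan = plan, window = window, sub_window = sub_window,
      v_stop = v_stop, rate = rate, tick_hz = tick_hz,
      fish_variability = fish_variability,
      baseline_vent_sd = baseline_vent_sd,
      baseline_speed_sd = baseline_speed_sd,
      arena = arena_geometry()
    ),
    class = "experiment_cohort_config"
  )
}

# Per-fish behavioural parameters: a fish-level baseline (resting
# ventilation offset, cruising-speed multiplier, shared by both of the
# fish's recordings) plus, for treatment states, a response-strength
# multiplier m that scales the deviation of every response parameter from
# the normal preset: p = p_normal + m * (p_state - p_normal).
.fish_params <- function(state, fish_id, config) {
  normal <- .state_presets$normal
  preset <- .state_presets[[state]]
  base_seed <- (config$seed %% 20000L) * 50000L + fish_id
  eff <- with_seed(base_seed, list(
    vent_off = rnorm(1, 0, config$baseline_vent_sd),
    speed_mult = exp(rnorm(1, 0, config$baseline_speed_sd)),
    resp_mult = exp(rnorm(1, 0, config$fish_variability))
  ))
  m <- if (state == "normal") 0 else eff$resp_mult
  mix <- function(field) {
    normal[[field]] + m * (preset[[field]] - normal[[field]])
  }
  p <- behaviour_params(
    state,
    mean_speed = max(1, mix("mean_speed") * eff$speed_mult),
    speed_sd = max(0.5, mix("speed_sd")),
    speed_tau = max(0.3, mix("speed_tau")),
    freeze_rate = max(0, mix("freeze_rate")),
    freeze_duration = max(0.1, mix("freeze_duration")),
    dart_rate = max(0, mix("dart_rate")),
    dart_speed = preset$dart_speed,
    hold_speed = preset$hold_speed,
    vent_base = min(9, max(1.2, mix("vent_base") + eff$vent_off)),
    vent_sd = max(0.03, mix("vent_sd")),
    heading_persistence = preset$heading_persistence,
    rest_mean_speed = max(1, normal$mean_speed * eff$speed_mult),
    rest_vent_base = min(9, max(1.2, normal$vent_base + eff$vent_off)),
    rest_vent_sd = normal$vent_sd
  )
  p
}

#' Generate a simulated cohort
#'
#' Runs the virtual aquarium over a cohort plan. In `"indices"` mode (the
#' default) each fish-state trajectory is reduced directly to ground-truth
#' index windows on the 33.33 Hz tick grid -- the representation consumed by
#' the statistics and classification stages. In `"signals"` mode full
#' electrode-array recordings are rendered instead (intended for small
#' validation subsets; a full cohort of 300 s, 126-channel recordings is
#' deliberately out of desk scale).
#'
#' @param config an [cohort_config()] object.
#' @param mode `"indices"` or `"signals"`.
#' @param snr signal-to-noise ratio for `"signals"` mode.
#' @return In `"indices"` mode an `index_windows` data frame (unstandardised)
#'   covering the whole plan; in `"signals"` mode a list of
#'   `electrode_recording`s named `fish<id>_<state>`.
#' @export
generate_cohort <- function(config = cohort_config(), mode = c("indices", "signals"),
                            snr = 10) {
  mode <- match.arg(mode)
  plan <- config$plan
  if (is.null(plan) || nrow(plan) == 0) {
    return(if (mode == "indices") {
      structure(
        data.frame(
          fish_id = integer(0), state = character(0), t0 = numeric(0),
          v_mean = numeric(0), p_stop = numeric(0), fv_mean = numeric(0),
          v_sd = numeric(0), p_stop_sd = numeric(0), fv_sd = numeric(0),
          standardised = logical(0)
        ),
        class = c("index_windows", "data.frame")
      )
    } else {
      list()
    })
  }
  if (anyDuplicated(plan[, c("fish_id", "state")])) {
    stop("duplicate fish ids in cohort plan")
  }
  step <- config$rate / config$tick_hz
  if (abs(step - round(step)) > 1e-9) {
    stop("simulation rate must be an integer multiple of the tick rate")
  }
  step <- as.integer(round(step))

  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    traj <- simulate_trajectory(
      .fish_params(row$state, row$fish_id, config), row$duration,
      arena = config$arena, seed = row$seed, rate = config$rate,
      fish_id = row$fish_id
    )
    if (mode == "signals") {
      out[[i]] <- render_signals(traj, config$arena, snr = snr,
                                 seed = row$seed + 1L)
      names(out)[i] <- sprintf("fish%d_%s", row$fish_id, row$state)
    } else {
      ticks <- seq(1, nrow(traj), by = step)
      vel <- data.frame(t = traj$t[ticks], speed = traj$speed[ticks])
      out[[i]] <- windowed_indices(
        vel, traj$fv[ticks],
        window = config$window, v_stop = config$v_stop,
        sub_window = config$sub_window,
        fish_id = row$fish_id, state = row$state
      )
    }
  }
  if (mode == "signals") return(out)
  windows <- do.call(rbind, out)
  class(windows) <- c("index_windows", "data.frame")
  windows
}

#' Simulated study cohort, standardised and ready for analysis
#'
#' Convenience wrapper: generates the default 23-fish cohort in index mode
#' and standardises every fish against its own normal-state baseline.
#'
#' @param seed base seed.
#' @param ... passed to [cohort_config()].
#' @return A standardised `index_windows` data frame (2760 rows with the
#'   default plan).
#' @export
simulate_index_cohort <- function(seed = 1, ...) {
  standardise_windows(generate_cohort(cohort_config(seed = seed, ...)))
}
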