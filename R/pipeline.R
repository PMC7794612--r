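#' Experiment configuration for the full pipeline
#'
#' Gathers every tunable of the analysis chain in one validated, fully
#' serialisable object: arena geometry, filter specifications, AR order,
#' window lengths, stopping threshold, the cohort plan, classifier settings
#' and the PC-count range. A short content hash of the configuration is
#' stamped into every artefact the pipeline writes.
#'
#' @param cohort a [cohort_config()].
#' @param bandpass ventilatory band-pass [filter_spec()].
#' @param ar_order Burg AR order for the peak maps.
#' @param window_s spectral analysis window, s.
#' @param f_cut1,f_cut2 low-pass cutoffs (Hz) for position and velocity
#'   smoothing.
#' @param lp_order order of both low-pass filters.
#' @param subdivisions spline refinement factor.
#' @param classifier default classifier for the classification stage.
#' @param n_pcs PC counts evaluated in the classification stage.
#' @param llgmn_m LLGMN components per class.
#' @param validation_fish,validation_duration,validation_snr small rendered
#'   subset used for the tracking-fidelity stage.
#' @param out_dir artefact directory.
#' @return An `experiment_config` list with a `hash` field.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              bandpass = filter_spec(),
                              ar_order = 10, window_s = 1,
                              f_cut1 = 1, f_cut2 = 0.5, lp_order = 4,
                              subdivisions = 5,
                              classifier = "llgmn", n_pcs = c(3, 4),
                              llgmn_m = 2,
                              validation_fish = 2, validation_duration = 30,
                              validation_snr = Inf,
                              out_dir = "results") {
  stopifnot(inherits(cohort, "experiment_cohort_config"),
            inherits(bandpass, "filter_spec"), ar_order >= 1,
            window_s > 0, f_cut1 > 0, f_cut2 > 0, subdivisions >= 1)
  cfg <- list(
    cohort = cohort, bandpass = bandpass, ar_order = ar_order,
    window_s = window_s, f_cut1 = f_cut1, f_cut2 = f_cut2,
    lp_order = lp_order, subdivisions = subdivisions,
    classifier = classifier, n_pcs = n_pcs, llgmn_m = llgmn_m,
    validation_fish = validation_fish,
    validation_duration = validation_duration,
    validation_snr = validation_snr,
    out_dir = out_dir
  )
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "experiment_config")
}

#' Short polynomial content hash of an R object (via its serialised bytes)
#' @param x any serialisable object.
#' @return 12-hex-digit character hash.
#' @export
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  .poly_hash(as.integer(bytes))
}

# 48-bit rolling polynomial hash, exact in double precision
.poly_hash <- function(ints) {
  h <- 0
  for (b in ints) h <- (h * 131 + b + 1) %% 281474976710656
  sprintf("%06x%06x", h %/% 16777216, h %% 16777216)
}

.file_hash <- function(path) {
  .poly_hash(as.integer(readBin(path, "raw", file.info(path)$size)))
}

#' Run one pipeline stage
#'
#' Stages: `"simulate"` (cohort index windows), `"standardise"`,
#' `"extract"`, `"track"`, `"indices"` (signal-path validation on the
#' rendered subset), `"stats"`, `"classify"`. Each stage is runnable
#' standalone from prior artefacts passed via `inputs`.
#'
#' @param name stage name.
#' @param inputs named list of upstream artefacts (stage-dependent).
#' @param config an [experiment_config()].
#' @return The stage artefact (stage-dependent).
#' @export
run_stage <- function(name, inputs = list(), config = experiment_config()) {
  need <- function(key) {
    if (is.null(inputs[[key]])) {
      stop(sprintf("stage '%s': missing upstream artefact '%s'", name, key))
    }
    inputs[[key]]
  }
  switch(name,
    simulate = generate_cohort(config$cohort),
    standardise = standardise_windows(need("windows")),
    extract = bandpass_extract(need("recording"), config$bandpass),
    track = {
      rec <- need("recording")
      maps <- compute_peak_maps(rec, window_s = config$window_s,
                                ar_order = config$ar_order)
      raw <- track_positions(maps, subdivisions = config$subdivisions)
      list(track = smooth_track(raw, f_cut1 = config$f_cut1,
                                order = config$lp_order, arena = rec$arena),
           maps = maps)
    },
    indices = {
      track <- need("track")
      maps <- need("maps")
      vel <- differentiate_positions(track, f_cut2 = config$f_cut2,
                                     order = config$lp_order)
      fv <- ventilatory_frequency_at(track, maps)
      windowed_indices(vel, fv,
        window = config$cohort$window, v_stop = config$cohort$v_stop,
        sub_window = config$cohort$sub_window,
        fish_id = inputs$fish_id %||% 1L, state = inputs$state %||% "normal"
      )
    },
    stats = {
      windows <- need("windows")
      cols <- index_columns()
      by_state <- split(windows[cols], windows$state)
      anova <- lapply(cols, function(cl) {
        one_way_anova(lapply(by_state, function(d) d[[cl]]))
      })
      names(anova) <- cols
      pca <- pca_fit(windows)
      sc <- pca_scores(pca, windows)
      anova_pc <- lapply(seq_len(ncol(sc)), function(j) {
        one_way_anova(split(sc[, j], windows$state))
      })
      names(anova_pc) <- colnames(sc)
      list(anova_indices = anova, pca = pca, anova_pcs = anova_pc)
    },
    classify = {
      windows <- need("windows")
      compare_pc_counts(windows, classifier = config$classifier,
                        n_pcs_range = config$n_pcs, M = config$llgmn_m)
    },
    stop(sprintf("unknown stage '%s'", name))
  )
}

#' Run the full offline pipeline
#'
#' Executes the stages in order -- cohort simulation, standardisation,
#' signal-path validation on a small rendered subset (render, extract,
#' track, indices), index statistics, classification -- writing CSV/JSON
#' artefacts under `config$out_dir` and returning a manifest of paths and
#' content hashes. Identical configuration and seeds give identical
#' artefacts.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return A manifest list: per-artefact-group file paths and hashes, plus
#'   the config hash.
#' @export
run_pipeline <- function(config = experiment_config(), quiet = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  art <- function(file) file.path(config$out_dir, file)
  manifest <- list(config = list(hash = config$hash))
  stamp <- function(group, paths) {
    manifest[[group]] <<- list(
      files = paths,
      hashes = vapply(paths, .file_hash, character(1))
    )
  }

  tryCatch({
    say("stage simulate: cohort index windows")
    windows <- run_stage("simulate", config = config)
    raw_path <- art("index_windows_raw.csv")
    write_index_windows(windows, raw_path)
    stamp("cohort_raw", raw_path)

    say("stage standardise")
    std <- run_stage("standardise", list(windows = windows), config)
    std_path <- art("index_windows_standardised.csv")
    write_index_windows(std, std_path)
    stamp("cohort_standardised", std_path)

    say("stage track: signal-path validation subset (%d fish x %g s)",
        config$validation_fish, config$validation_duration)
    val_paths <- character(0)
    for (i in seq_len(config$validation_fish)) {
      traj <- simulate_trajectory(
        behaviour_params("normal"), config$validation_duration,
        arena = config$cohort$arena,
        seed = config$cohort$seed + 5000L + i,
        rate = config$cohort$rate, fish_id = 1000L + i
      )
      rec <- render_signals(traj, config$cohort$arena,
                            snr = config$validation_snr,
                            seed = config$cohort$seed + 6000L + i)
      filt <- run_stage("extract", list(recording = rec), config)
      tr <- run_stage("track", list(recording = filt), config)
      p <- art(sprintf("validation_track_fish%d.csv", i))
      write_position_track(tr$track, p)
      val_paths <- c(val_paths, p)
    }
    stamp("validation_tracks", val_paths)

    say("stage stats")
    st <- run_stage("stats", list(windows = std), config)
    stats_path <- art("stats_summary.json")
    jsonlite::write_json(
      list(
        config_hash = config$hash,
        anova_indices = lapply(st$anova_indices, function(a) {
          list(F = a$statistic, df = a$df, p = a$p)
        }),
        explained_variance = st$pca$explained,
        loadings = as.data.frame(st$pca$loadings),
        anova_pcs = lapply(st$anova_pcs, function(a) {
          list(F = a$statistic, df = a$df, p = a$p)
        })
      ),
      stats_path, auto_unbox = TRUE, digits = NA
    )
    loadings_path <- art("pc_loadings.csv")
    write.csv(data.frame(index = index_columns(), st$pca$loadings),
              loadings_path, row.names = FALSE)
    stamp("stats", c(stats_path, loadings_path))

    say("stage classify (%s, N = %s)", config$classifier,
        paste(config$n_pcs, collapse = ","))
    cls <- run_stage("classify", list(windows = std), config)
    cls_paths <- character(0)
    for (nm in names(cls$reports)) {
      cp <- art(sprintf("classifier_report_%s.csv", nm))
      jp <- art(sprintf("classifier_report_%s.json", nm))
      write_classifier_report(cls$reports[[nm]], cp, jp)
      cls_paths <- c(cls_paths, cp, jp)
    }
    stamp("classification", cls_paths)
  }, error = function(e) {
    stop(sprintf("pipeline aborted: %s", conditionMessage(e)), call. = FALSE)
  })

  manifest_path <- art("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  manifest$manifest_path <- manifest_path
  invisible(manifest)
}
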