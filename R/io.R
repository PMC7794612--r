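#' Write / read index-window tables
#'
#' The index-window CSV (header `fish_id, state, t0, v_mean, p_stop,
#' fv_mean, v_sd, p_stop_sd, fv_sd, standardised`) is the contract between
#' the signal-processing and statistics/classification stages.
#'
#' @param windows an `index_windows` data frame.
#' @param path file path.
#' @return `write_index_windows` returns `path` invisibly;
#'   `read_index_windows` returns an `index_windows` data frame.
#' @export
write_index_windows <- function(windows, path) {
  write.csv(as.data.frame(windows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_index_windows
#' @export
read_index_windows <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "state", "t0", index_columns(), "standardised")
  if (!all(need %in% names(df))) {
    stop("not an index-window table: missing columns")
  }
  class(df) <- c("index_windows", "data.frame")
  df
}

#' Write a position track to CSV
#'
#' Columns `t, x_raw, y_raw, x, y, degenerate`.
#' @param track a `position_track`.
#' @param path file path.
#' @export
write_position_track <- function(track, path) {
  write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_position_track
#' @export
read_position_track <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("position_track", "data.frame")
  df
}

#' Export ground truth to CSV
#' @param traj a `ground_truth_trajectory`.
#' @param path file path.
#' @export
write_ground_truth <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Serialise peak maps to CSV (long format: t, electrode, freq, power)
#' @param maps a `peak_maps`.
#' @param path file path.
#' @export
write_peak_maps <- function(maps, path) {
  nt <- length(maps$t)
  L <- ncol(maps$freq)
  df <- data.frame(
    t = rep(maps$t, L),
    electrode = rep(seq_len(L), each = nt),
    freq = as.vector(maps$freq),
    power = as.vector(maps$power)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a classifier model to JSON
#'
#' Documented schema: `type`, `classes`, and the numeric weight matrix
#' (`W`, stored column-major with its dimensions); LLGMN models add `M`,
#' `N`, `H`; LDA models add `dim`.
#'
#' @param model an `llgmn_model` or `lda_model`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "llgmn_model")) {
    list(
      type = "llgmn", classes = model$classes, M = model$M, N = model$N,
      H = model$H, W = list(dim = dim(model$W), values = as.vector(model$W))
    )
  } else if (inherits(model, "lda_model")) {
    list(
      type = "lda", classes = model$classes, dim = model$dim,
      W = list(dim = dim(model$W), values = as.vector(model$W))
    )
  } else {
    stop("unsupported model class")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(obj$W$values, obj$W$dim[1], obj$W$dim[2])
  if (obj$type == "llgmn") {
    colnamesW <- NULL
    structure(
      list(W = W, classes = obj$classes, M = obj$M, N = obj$N, H = obj$H,
           trace = numeric(0), loglik = NA_real_),
      class = "llgmn_model"
    )
  } else {
    colnames(W) <- obj$classes
    structure(
      list(W = W, classes = obj$classes, dim = obj$dim),
      class = "lda_model"
    )
  }
}

#' Write a classifier report (per-window predictions CSV + summary JSON)
#' @param report a `classifier_report`.
#' @param csv_path,json_path output paths (either may be NULL).
#' @export
write_classifier_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    write.csv(report$predictions, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        classifier = report$classifier, n_pcs = report$n_pcs,
        classes = report$classes,
        confusion = as.vector(report$confusion),
        precision = as.list(report$scores$precision),
        recall = as.list(report$scores$recall),
        f = as.list(report$scores$f),
        macro_f = report$scores$macro_f,
        n_folds = report$n_folds
      ),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(report)
}
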