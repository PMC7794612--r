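#' Per-class and macro F-scores from confusion counts
#'
#' F-score per class is the harmonic mean of precision and recall,
#' `2PR / (P + R)`, defined as 0 when `P + R = 0` (degenerate cells). The
#' macro F is the unweighted mean over classes, which balances the unequal
#' numbers of fish across the two experiments.
#'
#' @param confusion K x K matrix of counts, rows = true class,
#'   columns = predicted class (dimnames give class names).
#' @return List with `precision`, `recall`, `f` (per class) and `macro_f`.
#' @export
f_scores <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop("confusion counts must be non-negative")
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  cls <- rownames(confusion) %||% paste0("class", seq_along(tp))
  list(
    precision = setNames(prec, cls), recall = setNames(rec, cls),
    f = setNames(f, cls), macro_f = mean(f)
  )
}

.confusion <- function(truth, pred, classes) {
  table(
    factor(truth, levels = classes),
    factor(pred, levels = classes)
  )
}

#' Leave-one-fish-out cross-validated emotion discrimination
#'
#' For each fish in turn, fits the PCA and the classifier on every *other*
#' fish's windows and evaluates on the held-out fish, so no within-animal
#' information leaks into training (by default the PCA itself is refit per
#' fold; `refit_pca = FALSE` switches to a single global PCA for
#' comparison experiments). Predictions are pooled over folds into one
#' confusion matrix and per-class F-scores; per-fold F-scores are kept for
#' distributional comparisons across PC counts.
#'
#' @param windows a standardised `index_windows` table (columns `fish_id`,
#'   `state` and the six indices).
#' @param classifier `"llgmn"` or `"lda"`.
#' @param n_pcs number of leading PC scores fed to the classifier (1..6).
#' @param M LLGMN components per class.
#' @param seed seed for classifier initialisation.
#' @param refit_pca refit the PCA inside each training fold (default TRUE).
#' @param ... further arguments passed to the classifier's fit function.
#' @return A `classifier_report`: `predictions` (per-window data frame with
#'   posteriors), `confusion`, `scores` (output of [f_scores()]),
#'   `fold_f` (per-fold macro and per-class F; the macro averages over the
#'   classes actually present in the held-out fish's windows and a
#'   per-class F is `NA` for folds whose fish has no windows of that
#'   class), `classifier`, `n_pcs`.
#' @export
loo_fish_cv <- function(windows, classifier = c("llgmn", "lda"), n_pcs = 4,
                        M = 2, seed = 1, refit_pca = TRUE, ...) {
  classifier <- match.arg(classifier)
  if (n_pcs < 1 || n_pcs > length(index_columns())) {
    stop("n_pcs must lie in 1..6")
  }
  states <- levels(.state_factor(windows$state))
  per_class_fish <- vapply(states, function(s) {
    length(unique(windows$fish_id[windows$state == s]))
  }, 1L)
  if (any(per_class_fish < 2)) stop("need at least 2 fish per class")

  fish <- sort(unique(windows$fish_id))
  global_pca <- if (!refit_pca) pca_fit(windows) else NULL
  preds <- vector("list", length(fish))
  fold_f <- vector("list", length(fish))

  for (i in seq_along(fish)) {
    f <- fish[i]
    tr <- windows[windows$fish_id != f, , drop = FALSE]
    te <- windows[windows$fish_id == f, , drop = FALSE]
    if (length(unique(tr$state)) < length(states)) {
      warning(sprintf("fold for fish %s skipped: training set misses a class", f))
      next
    }
    pca <- if (refit_pca) pca_fit(tr) else global_pca
    str <- pca_scores(pca, tr)[, seq_len(n_pcs), drop = FALSE]
    ste <- pca_scores(pca, te)[, seq_len(n_pcs), drop = FALSE]
    if (classifier == "llgmn") {
      mod <- fit_llgmn(str, tr$state, M = M, seed = seed, ...)
      pr <- predict_llgmn(mod, ste)
    } else {
      mod <- fit_lda(str, tr$state, ...)
      pr <- predict_lda(mod, ste)
      colnames(pr$posterior) <- mod$classes
    }
    post <- pr$posterior[, states, drop = FALSE]
    colnames(post) <- paste0("p_", states)
    preds[[i]] <- cbind(
      data.frame(
        fish_id = te$fish_id, t0 = te$t0, truth = te$state,
        prediction = pr$label, stringsAsFactors = FALSE
      ),
      as.data.frame(post)
    )
    fs <- f_scores(.confusion(te$state, pr$label, states))
    present <- states %in% te$state
    ff <- ifelse(present, fs$f, NA_real_)
    fold_f[[i]] <- data.frame(
      fish_id = f, macro_f = mean(fs$f[present]),
      t(setNames(ff, paste0("f_", states)))
    )
  }
  predictions <- do.call(rbind, preds)
  conf <- .confusion(predictions$truth, predictions$prediction, states)
  structure(
    list(
      predictions = predictions,
      confusion = conf,
      scores = f_scores(conf),
      fold_f = do.call(rbind, fold_f),
      classifier = classifier, n_pcs = n_pcs, classes = states,
      n_folds = sum(!vapply(preds, is.null, TRUE))
    ),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> %s, %d PCs, %d folds, %d windows; macro F = %.3f\n",
    x$classifier, x$n_pcs, x$n_folds, nrow(x$predictions), x$scores$macro_f
  ))
  print(round(x$scores$f, 3))
  invisible(x)
}

#' Discrimination performance as PCs are added one by one
#'
#' Runs leave-one-fish-out cross-validation for each PC count in
#' `n_pcs_range` and compares the per-fold F-score distributions between PC
#' counts with the Tukey-Kramer test (macro F and, separately, the
#' appetitive-state F when that state is present).
#'
#' @param windows standardised `index_windows`.
#' @param classifier `"llgmn"` or `"lda"`.
#' @param n_pcs_range PC counts to evaluate (within 1..6).
#' @param ... passed to [loo_fish_cv()].
#' @return List with `reports` (one per PC count), `macro_f` (named vector),
#'   `tukey_macro` and (if applicable) `tukey_appetitive` comparison tables.
#' @export
compare_pc_counts <- function(windows, classifier = "llgmn",
                              n_pcs_range = 1:6, ...) {
  if (any(n_pcs_range < 1 | n_pcs_range > length(index_columns()))) {
    stop("PC counts must lie in 1..6")
  }
  reports <- lapply(n_pcs_range, function(np) {
    loo_fish_cv(windows, classifier = classifier, n_pcs = np, ...)
  })
  names(reports) <- paste0("PC1_", n_pcs_range)
  macro_groups <- lapply(reports, function(r) r$fold_f$macro_f)
  out <- list(
    reports = reports,
    macro_f = vapply(reports, function(r) r$scores$macro_f, numeric(1)),
    tukey_macro = tukey_kramer(macro_groups)
  )
  if ("appetitive" %in% reports[[1]]$classes) {
    app_groups <- lapply(reports, function(r) {
      v <- r$fold_f$f_appetitive
      v[!is.na(v)]
    })
    out$tukey_appetitive <- tukey_kramer(app_groups)
  }
  out
}

#' Posterior-probability shift before vs after a treatment
#'
#' For the fish exposed to a given treatment, compares each state's
#' posterior probability between the pre-treatment (normal) windows and the
#' post-treatment windows with Welch's t-test and Cohen's d, ordered by
#' effect magnitude. In a well-calibrated system the largest effect lands
#' on the treatment-matched state's posterior.
#'
#' @param report a `classifier_report` from [loo_fish_cv()].
#' @param treatment_state `"fear"` or `"appetitive"`; selects the fish that
#'   have post-treatment windows of that state.
#' @param baseline_state the pre-treatment state label.
#' @return Data frame (one row per posterior state): `state`, `t`, `df`,
#'   `p`, `d`, ordered by decreasing `|d|`.
#' @export
posterior_shift_analysis <- function(report, treatment_state,
                                     baseline_state = "normal") {
  pr <- report$predictions
  fish <- unique(pr$fish_id[pr$truth == treatment_state])
  if (length(fish) == 0) stop(sprintf("no windows with state '%s'", treatment_state))
  sub <- pr[pr$fish_id %in% fish, , drop = FALSE]
  before <- sub[sub$truth == baseline_state, , drop = FALSE]
  after <- sub[sub$truth == treatment_state, , drop = FALSE]
  if (nrow(before) < 2 || nrow(after) < 2) stop("missing before/after group")
  rows <- lapply(report$classes, function(s) {
    col <- paste0("p_", s)
    a <- after[[col]]
    b <- before[[col]]
    if (var(a) + var(b) <= 0) { # degenerate: posterior never moved
      return(data.frame(state = s, t = 0, df = NA_real_, p = 1, d = 0,
                        stringsAsFactors = FALSE))
    }
    wt <- welch_t(a, b)
    data.frame(
      state = s, t = wt$statistic, df = wt$df, p = wt$p, d = wt$d,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res[order(-abs(res$d)), , drop = FALSE]
}
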