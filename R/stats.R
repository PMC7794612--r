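#' Welch's t-test between two groups
#'
#' Two-sided Welch t (unequal variances, Welch-Satterthwaite degrees of
#' freedom), the test used to compare each index before and after a
#' treatment. Cohen's d is attached as the effect size.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return A `ventrack_test` list: `statistic`, `df`, `p`, `d`, `method`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  ht <- t.test(a, b, var.equal = FALSE)
  structure(
    list(
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p = ht$p.value, d = cohens_d(a, b), method = "welch_t"
    ),
    class = "ventrack_test"
  )
}

#' One-way ANOVA across k groups
#'
#' F statistic with (k - 1, N - k) degrees of freedom. Perfect separation
#' (zero within-group variance but distinct means) is returned as an
#' infinite F flagged `degenerate`, with p = 0.
#'
#' @param groups list of numeric vectors (>= 2 groups of >= 2 values).
#' @return A `ventrack_test` list: `statistic`, `df` (length 2), `p`,
#'   `degenerate`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- length(groups)
  n <- length(y)
  means <- tapply(y, g, mean)
  ss_w <- sum((y - means[g])^2)
  ss_b <- sum(tabulate(g) * (means - mean(y))^2)
  df <- c(k - 1, n - k)
  if (ss_w < .Machine$double.eps * max(1, ss_b)) {
    f <- if (ss_b > 0) Inf else 0
    return(structure(
      list(
        statistic = f, df = df, p = if (is.infinite(f)) 0 else 1,
        degenerate = is.infinite(f), method = "one_way_anova"
      ),
      class = "ventrack_test"
    ))
  }
  f <- (ss_b / df[1]) / (ss_w / df[2])
  structure(
    list(
      statistic = f, df = df, p = pf(f, df[1], df[2], lower.tail = FALSE),
      degenerate = FALSE, method = "one_way_anova"
    ),
    class = "ventrack_test"
  )
}

#' Cohen's d effect size
#'
#' Standardised mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled (n-1 weighted) SD.
#'
#' @param a,b numeric vectors.
#' @return Cohen's d (signed).
#' @export
cohens_d <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values")
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled SD")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' @export
print.ventrack_test <- function(x, ...) {
  cat(sprintf(
    "<%s> statistic=%.4g, df=%s, p=%.3g%s\n",
    x$method, x$statistic, paste(signif(x$df, 6), collapse = ","), x$p,
    if (!is.null(x$d)) sprintf(", d=%.3g", x$d) else ""
  ))
  invisible(x)
}

#' Principal component model of the six indices
#'
#' Eigendecomposition of the correlation matrix of the pooled index table
#' (equivalently, PCA of the per-column standardised data): the indices mix
#' units (mm/s, %, Hz), so correlation scaling puts them on an equal
#' footing. The sign of each loading column is fixed so that its
#' largest-magnitude entry is positive, making loadings and scores
#' reproducible.
#'
#' @param table a data frame containing the six index columns.
#' @param columns index column names (defaults to the six evaluation
#'   indices).
#' @return A `pc_model`: `center`, `scale` (per-index mean/SD), `loadings`
#'   (6 x 6, orthonormal columns), `explained` (variance fractions, sum 1).
#' @export
pca_fit <- function(table, columns = index_columns()) {
  x <- as.matrix(table[, columns, drop = FALSE])
  if (nrow(x) < length(columns) + 1) stop("need more rows than indices")
  sds <- apply(x, 2, sd)
  if (any(sds <= 0 | !is.finite(sds))) {
    stop(sprintf(
      "constant index column: %s",
      paste(columns[sds <= 0 | !is.finite(sds)], collapse = ", ")
    ))
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, "*")
  structure(
    list(
      center = pc$center, scale = pc$scale, loadings = rot,
      explained = pc$sdev^2 / sum(pc$sdev^2), columns = columns
    ),
    class = "pc_model"
  )
}

#' Project an index table into PC-score space
#'
#' @param model a [pca_fit()] model.
#' @param table data frame with the model's index columns.
#' @return Matrix of scores (rows x 6), columns `PC1..PC6`.
#' @export
pca_scores <- function(model, table) {
  x <- as.matrix(table[, model$columns, drop = FALSE])
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  s <- xs %*% model$loadings
  colnames(s) <- paste0("PC", seq_len(ncol(s)))
  s
}

#' @export
print.pc_model <- function(x, ...) {
  cat("<pc_model> explained variance fractions:",
      paste(sprintf("%.3f", x$explained), collapse = " "), "\n")
  invisible(x)
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentised-range pairwise comparisons of k group means with the
#' Tukey-Kramer standard errors for unequal group sizes.
#'
#' @param groups named list of numeric vectors (k >= 2).
#' @return Data frame: `group1`, `group2`, `diff`, `p`.
#' @export
tukey_kramer <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs >= 2 values")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
    levels = names(groups)
  )
  tk <- TukeyHSD(aov(y ~ g))$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  data.frame(
    group1 = pairs[, 1], group2 = pairs[, 2],
    diff = unname(tk[, "diff"]), p = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
}
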