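#' Multi-class Fisher linear discriminant classifier
#'
#' Linear discriminant functions `y_k(x) = w_k' [1, x]` with the decision
#' rule "assign x to class k when y_k(x) > y_j(x) for all j != k". The
#' weights are the equal-covariance Gaussian discriminant
#' `w_k = Sigma^-1 mu_k` with intercept `-mu_k' Sigma^-1 mu_k / 2 +
#' log pi_k`, where `Sigma` is the pooled within-class covariance -- the
#' classifier form of Fisher's criterion (for two classes the implied
#' projection `Sigma^-1 (mu_1 - mu_2)` is exactly the direction maximising
#' the between- to within-class variance ratio). A singular within-class
#' scatter is ridge-regularised with a warning. Ties go to the lowest class
#' index.
#'
#' @param x numeric matrix (n x N) of PC scores.
#' @param labels class labels; level order fixes the class indices
#'   (`normal < fear < appetitive` when those states are present).
#' @param ridge regularisation added to Sigma when it is numerically
#'   singular.
#' @return An `lda_model`: `W` ((N+1) x K weight matrix, bias row first),
#'   `classes`, `means`, `cov`.
#' @export
fit_lda <- function(x, labels, ridge = 1e-8) {
  x <- as.matrix(x)
  labels <- .state_factor(labels)
  K <- nlevels(labels)
  if (K < 2) stop("need at least 2 classes")
  N <- ncol(x)
  if (any(table(labels) <= N)) {
    stop("each class needs more samples than input dimensions")
  }
  mus <- matrix(0, K, N, dimnames = list(levels(labels), colnames(x)))
  for (cl in levels(labels)) {
    mus[cl, ] <- colMeans(x[labels == cl, , drop = FALSE])
  }
  n <- nrow(x)
  Sw <- matrix(0, N, N)
  for (cl in levels(labels)) {
    xc <- sweep(x[labels == cl, , drop = FALSE], 2, mus[cl, ], "-")
    Sw <- Sw + crossprod(xc)
  }
  Sigma <- Sw / (n - K)
  if (rcond(Sigma) < 1e-12) {
    warning("singular within-class scatter; applying ridge regularisation")
    Sigma <- Sigma + diag(max(ridge, 1e-6 * mean(diag(Sigma))), N)
  }
  Sinv <- solve(Sigma)
  pri <- as.numeric(table(labels)) / n
  W <- vapply(seq_len(K), function(k) {
    wk <- Sinv %*% mus[k, ]
    c(-0.5 * drop(mus[k, ] %*% wk) + log(pri[k]), wk)
  }, numeric(N + 1))
  colnames(W) <- levels(labels)
  structure(
    list(W = W, classes = levels(labels), means = mus, cov = Sigma,
         priors = pri, dim = N),
    class = "lda_model"
  )
}

# order emotion-state labels canonically; other label sets keep their order
.state_factor <- function(labels) {
  if (is.factor(labels)) return(droplevels(labels))
  states <- c("normal", "fear", "appetitive")
  u <- unique(labels)
  if (all(u %in% states)) {
    factor(labels, levels = states[states %in% u])
  } else {
    factor(labels, levels = u)
  }
}

#' Discriminant values and class prediction from a fitted LDA
#'
#' @param model an `lda_model`.
#' @param x matrix (or vector) of inputs with the model's dimensionality.
#' @param posterior return softmax posteriors as well.
#' @return List with `y` (discriminant values), `label` (predicted class),
#'   and `posterior` when requested.
#' @export
predict_lda <- function(model, x, posterior = TRUE) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != model$dim) stop("input dimension mismatch")
  y <- cbind(1, x) %*% model$W
  lab <- model$classes[max.col(y, ties.method = "first")]
  out <- list(y = y, label = lab)
  if (posterior) {
    z <- y - apply(y, 1, max)
    e <- exp(z)
    out$posterior <- e / rowSums(e)
  }
  out
}

#' Fisher projection direction for a two-class problem
#'
#' The direction maximising the ratio of between-class to within-class
#' variance, `Sigma_w^-1 (mu_1 - mu_2)`, returned as a unit vector. Used to
#' validate the classifier against brute-force maximisation of the Fisher
#' ratio.
#'
#' @param x numeric matrix (n x N).
#' @param labels two-class labels.
#' @return Unit-length numeric vector of length N.
#' @export
fisher_direction <- function(x, labels) {
  labels <- .state_factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes required")
  x <- as.matrix(x)
  m1 <- colMeans(x[labels == levels(labels)[1], , drop = FALSE])
  m2 <- colMeans(x[labels == levels(labels)[2], , drop = FALSE])
  Sw <- matrix(0, ncol(x), ncol(x))
  for (cl in levels(labels)) {
    xc <- sweep(x[labels == cl, , drop = FALSE], 2,
                colMeans(x[labels == cl, , drop = FALSE]), "-")
    Sw <- Sw + crossprod(xc)
  }
  w <- solve(Sw, m1 - m2)
  as.numeric(w / sqrt(sum(w^2)))
}
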