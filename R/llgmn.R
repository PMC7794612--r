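# nonlinear input expansion of the log-linearised Gaussian mixture network:
# (1, x_i, x_i x_j for i <= j), dimension H = 1 + N + N(N+1)/2
llgmn_expand <- function(x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  n <- nrow(x)
  N <- ncol(x)
  quad <- matrix(0, n, N * (N + 1) / 2)
  c0 <- 0L
  for (i in seq_len(N)) {
    for (j in i:N) {
      c0 <- c0 + 1L
      quad[, c0] <- x[, i] * x[, j]
    }
  }
  cbind(1, x, quad)
}

.llgmn_forward <- function(X, W, K, M) {
  Z <- X %*% W # n x (K*M)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  O <- E / rowSums(E)
  # per-class posterior: sum over that class's M component units
  Y <- vapply(seq_len(K), function(k) {
    rowSums(O[, ((k - 1) * M + 1):(k * M), drop = FALSE])
  }, numeric(nrow(X)))
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  list(O = O, Y = Y)
}

#' Fit a log-linearised Gaussian mixture network (LLGMN)
#'
#' A feed-forward probabilistic classifier whose architecture realises a
#' Gaussian mixture model per class: the input is expanded nonlinearly as
#' `(1, x_i, x_i x_j)` (so each linear unit is a log-quadratic, i.e. a
#' log-Gaussian-times-prior, function of x), a linear map feeds `K x M`
#' units, a normalised exponential couples all units, and each class
#' posterior is the sum of its `M` component units. Training maximises the
#' log-likelihood of the class labels by full-batch gradient ascent with
#' backtracking step halving, which makes the training log-likelihood
#' monotone non-decreasing.
#'
#' @param x numeric matrix (n x N) of inputs (e.g. PC scores).
#' @param labels class labels (see [fit_lda()] for level ordering).
#' @param M mixture components per class (default 2: the appetitive state is
#'   bimodal in PC space).
#' @param lr initial learning rate.
#' @param max_epochs maximum training epochs.
#' @param tol stop when the relative log-likelihood change drops below this.
#' @param seed seed for the near-zero random initialisation.
#' @return An `llgmn_model`: weights `W` (H x K*M), `classes`, `M`, `N`,
#'   and `trace` (training log-likelihood per epoch).
#' @export
fit_llgmn <- function(x, labels, M = 2, lr = 0.01, max_epochs = 2000,
                      tol = 1e-6, seed = 0) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite inputs")
  labels <- .state_factor(labels)
  K <- nlevels(labels)
  if (K < 2) stop("need at least 2 classes")
  N <- ncol(x)
  X <- llgmn_expand(x)
  H <- ncol(X)
  n <- nrow(X)
  ci <- as.integer(labels)

  W <- with_seed(seed, matrix(rnorm(H * K * M, sd = 0.01), H, K * M))
  eps <- 1e-300
  fw <- .llgmn_forward(X, W, K, M)
  ll <- sum(log(pmax(fw$Y[cbind(seq_len(n), ci)], eps)))
  if (!is.finite(ll)) stop("non-finite loss at initialisation")
  trace <- numeric(max_epochs)
  step <- lr
  unit_class <- rep(seq_len(K), each = M)
  memb <- outer(ci, unit_class, "==") * 1 # n x K*M unit-in-true-class mask

  for (epoch in seq_len(max_epochs)) {
    yc <- pmax(fw$Y[cbind(seq_len(n), ci)], eps)
    G <- crossprod(X, fw$O * (memb / yc - 1)) / n

    accepted <- FALSE
    for (try in 1:25) {
      Wn <- W + step * G
      fwn <- .llgmn_forward(X, Wn, K, M)
      lln <- sum(log(pmax(fwn$Y[cbind(seq_len(n), ci)], eps)))
      if (is.finite(lln) && lln >= ll - 1e-12 * abs(ll)) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      trace <- trace[seq_len(epoch - 1)]
      break
    }
    improved <- lln - ll
    W <- Wn
    fw <- fwn
    ll <- lln
    trace[epoch] <- ll
    step <- min(step * 1.3, 2000 * lr)
    if (epoch > 1 && improved / (abs(ll) + 1) < tol) {
      trace <- trace[seq_len(epoch)]
      break
    }
  }
  structure(
    list(W = W, classes = levels(labels), M = M, N = N, H = H,
         trace = trace, loglik = ll),
    class = "llgmn_model"
  )
}

#' Posterior probabilities and labels from a fitted LLGMN
#'
#' Posteriors are non-negative and sum to one by construction (normalised
#' exponential); the label is the posterior argmax, ties to the lowest
#' class index.
#'
#' @param model an `llgmn_model`.
#' @param x input matrix or single vector with `model$N` columns.
#' @return List with `posterior` (n x K matrix, columns named by class) and
#'   `label`.
#' @export
predict_llgmn <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != model$N) stop("input dimension mismatch")
  fw <- .llgmn_forward(llgmn_expand(x), model$W, length(model$classes), model$M)
  colnames(fw$Y) <- model$classes
  list(
    posterior = fw$Y,
    label = model$classes[max.col(fw$Y, ties.method = "first")]
  )
}

#' @export
print.llgmn_model <- function(x, ...) {
  cat(sprintf(
    "<llgmn_model> %d classes x %d components, H=%d, trained %d epochs (logLik %.3f)\n",
    length(x$classes), x$M, x$H, length(x$trace), x$loglik
  ))
  invisible(x)
}
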