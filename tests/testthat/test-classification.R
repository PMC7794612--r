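# Fisher LDA, LLGMN and leave-one-fish-out cross-validation

test_that("F-scores follow the harmonic-mean definition", {
  diagm <- diag(c(5, 7, 9))
  rownames(diagm) <- colnames(diagm) <- c("normal", "fear", "appetitive")
  fs <- f_scores(diagm)
  expect_equal(unname(fs$f), c(1, 1, 1))
  expect_equal(fs$macro_f, 1)

  conf <- matrix(c(8, 2, 0, 1, 7, 2, 1, 1, 8), 3, 3, byrow = TRUE)
  fs2 <- f_scores(conf)
  expect_equal(unname(fs2$f[1]), 0.8) # P = R = 0.8 for class 1

  half <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(unname(f_scores(half)$f), c(0.5, 0.5))

  none <- matrix(c(0, 2, 0, 2), 2, 2) # class 1 never predicted correctly
  expect_equal(unname(f_scores(none)$f[1]), 0)
  expect_error(f_scores(matrix(c(-1, 0, 0, 1), 2)), "non-negative")
})

test_that("LDA separates separable classes and is honest at chance", {
  g <- gaussian_classes(200, matrix(c(-5, 5), 2, 1), seed = 2)
  m <- fit_lda(g$x, g$labels)
  acc <- mean(predict_lda(m, g$x)$label == g$labels)
  expect_gte(acc, 0.99)

  g3 <- gaussian_classes(400, matrix(0, 3, 2), seed = 3)
  m3 <- fit_lda(g3$x, g3$labels)
  acc3 <- mean(predict_lda(m3, g3$x)$label == g3$labels)
  expect_lt(abs(acc3 - 1 / 3), 0.05)
})

test_that("LDA projection matches brute-force Fisher-ratio maximisation", {
  g <- gaussian_classes(300, matrix(c(0, 3, 0, 1.5), 2, 2), sd = 1, seed = 4)
  w <- fisher_direction(g$x, g$labels)

  fisher_ratio <- function(theta) {
    v <- c(cos(theta), sin(theta))
    p <- g$x %*% v
    m1 <- mean(p[g$labels == "class1"])
    m2 <- mean(p[g$labels == "class2"])
    sw <- sum((p[g$labels == "class1"] - m1)^2) +
      sum((p[g$labels == "class2"] - m2)^2)
    (m1 - m2)^2 / sw
  }
  grid <- seq(0, pi, length.out = 3601)[-3601]
  best <- grid[which.max(vapply(grid, fisher_ratio, 1))]
  ang <- atan2(w[2], w[1]) %% pi
  diff <- min(abs(ang - best), pi - abs(ang - best))
  expect_lt(diff * 180 / pi, 1)
})

test_that("LDA decision rule: argmax, shift invariance, ties, validation", {
  g <- gaussian_classes(100, matrix(c(-4, 4, 0, 0), 2, 2), seed = 5)
  m <- fit_lda(g$x, g$labels)
  pr <- predict_lda(m, c(-4, 0))
  expect_equal(pr$label, "class1")

  # adding a constant to every discriminant leaves decisions unchanged
  m2 <- m
  m2$W[1, ] <- m2$W[1, ] + 7
  expect_equal(predict_lda(m2, g$x)$label, predict_lda(m, g$x)$label)

  # exact ties go to the lowest class index
  mt <- m
  mt$W[] <- 0
  expect_equal(predict_lda(mt, c(1, 1))$label, m$classes[1])

  expect_error(predict_lda(m, c(1, 2, 3)), "dimension")
  expect_error(fit_lda(g$x[1:3, ], g$labels[1:3]), "class")
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  g <- gaussian_classes(150, matrix(c(0, 2.5, -1, 0, 1, 2), 3, 2), seed = 6)
  ours <- predict_lda(fit_lda(g$x, g$labels), g$x)$label
  ref <- as.character(predict(MASS::lda(g$x, grouping = g$labels))$class)
  expect_gte(mean(ours == ref), 0.99)
})

test_that("LLGMN posteriors are proper and training is monotone", {
  g <- gaussian_classes(150, matrix(c(-2, 2, 0, 1), 2, 2), seed = 7)
  m <- fit_llgmn(g$x, g$labels, M = 2, seed = 1, max_epochs = 300)
  expect_true(all(diff(m$trace) >= -1e-8))
  pr <- predict_llgmn(m, g$x)
  expect_true(all(abs(rowSums(pr$posterior) - 1) < 1e-9))
  expect_true(all(pr$posterior >= 0))
  expect_error(predict_llgmn(m, c(1, 2, 3)), "dimension")
  expect_error(fit_llgmn(matrix(c(1, NA), 2, 1), c("a", "b")), "finite")
})

test_that("LLGMN approximates the Bayes posterior of a Gaussian mixture", {
  g <- gaussian_classes(2000, matrix(c(-2, 2), 2, 1), sd = 1, seed = 8)
  m <- fit_llgmn(g$x, g$labels, M = 1, seed = 2)
  probe <- matrix(seq(-4, 4, by = 0.05), ncol = 1)
  bayes1 <- 1 / (1 + exp(4 * probe[, 1])) # P(class1 | x), class1 at -2
  est1 <- predict_llgmn(m, probe)$posterior[, "class1"]
  expect_lte(mean(abs(est1 - bayes1)), 0.05)
  # a probe at a class centroid is confidently assigned
  expect_gt(predict_llgmn(m, matrix(-2))$posterior[, "class1"], 0.5)
})

test_that("a hand-mirrored LLGMN is exactly symmetric at the midpoint", {
  m <- structure(
    list(
      W = matrix(c(0.3, 1.2, 0.4, 0.3, -1.2, 0.4), 3, 2), # mirrored in x
      classes = c("class1", "class2"), M = 1, N = 1, H = 3,
      trace = numeric(0), loglik = NA_real_
    ),
    class = "llgmn_model"
  )
  pr <- predict_llgmn(m, matrix(0))
  expect_equal(as.numeric(pr$posterior), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("LLGMN solves a linearly inseparable mixture where LDA cannot", {
  with_seed(9, {
    n <- 100
    corners <- rbind(c(3, 3), c(-3, -3), c(3, -3), c(-3, 3))
    x <- do.call(rbind, lapply(1:4, function(k) {
      matrix(rnorm(2 * n), n, 2) + matrix(corners[k, ], n, 2, byrow = TRUE)
    }))
    labels <- rep(c("A", "A", "B", "B"), each = n)
  })
  gm <- fit_llgmn(x, labels, M = 2, seed = 3)
  acc_gm <- mean(predict_llgmn(gm, x)$label == labels)
  ld <- fit_lda(x, labels)
  acc_ld <- mean(predict_lda(ld, x)$label == labels)
  expect_gte(acc_gm, 0.9)
  expect_lte(acc_ld, 0.65)
})

test_that("leave-one-fish-out reporting: folds, counts, perfect separation", {
  tab <- latent_cohort(n_per = 20, fish_per = 2, shift3 = 8, shift4 = 8)
  rep <- loo_fish_cv(tab, classifier = "lda", n_pcs = 4)
  expect_equal(rep$n_folds, 6)
  expect_equal(nrow(rep$predictions), nrow(tab))
  expect_equal(sum(rep$confusion), nrow(tab))
  expect_equal(rep$scores$macro_f, 1)
  expect_error(loo_fish_cv(tab, n_pcs = 9), "1..6")
})

test_that("a label-shuffled cohort classifies at chance", {
  tab <- latent_cohort(n_per = 40, fish_per = 4, seed = 31)
  tab$state <- with_seed(32, sample(tab$state)) # break label-feature link
  rep <- loo_fish_cv(tab, classifier = "lda", n_pcs = 4)
  expect_lt(abs(rep$scores$macro_f - 1 / 3), 0.05)
})

test_that("held-out labels cannot leak into predictions", {
  tab <- latent_cohort(n_per = 20, fish_per = 2)
  rep1 <- loo_fish_cv(tab, classifier = "lda", n_pcs = 4)
  flipped <- tab
  rows <- flipped$fish_id == 1
  flipped$state[rows] <- rev(flipped$state[rows])
  flipped$state[rows][1:10] <- "appetitive"
  rep2 <- loo_fish_cv(flipped, classifier = "lda", n_pcs = 4)
  expect_equal(
    rep1$predictions$prediction[rep1$predictions$fish_id == 1],
    rep2$predictions$prediction[rep2$predictions$fish_id == 1]
  )
})

test_that("a class separable only in PC4 needs the fourth PC", {
  tab <- latent_cohort(n_per = 50, fish_per = 5)
  cmp <- compare_pc_counts(tab, classifier = "lda", n_pcs_range = 3:4)
  r3 <- cmp$reports[[1]]
  r4 <- cmp$reports[[2]]
  expect_lt(r3$scores$f["appetitive"], 0.5)
  expect_gt(r4$scores$f["appetitive"], 0.7)
  expect_gt(r4$scores$macro_f, r3$scores$macro_f)
  tk <- cmp$tukey_macro
  row <- tk[(tk$group1 == "PC1_4" & tk$group2 == "PC1_3") |
              (tk$group1 == "PC1_3" & tk$group2 == "PC1_4"), ]
  expect_lt(row$p, 0.001)
})

test_that("posterior shifts report effects per state ordered by magnitude", {
  # fabricated report: after treatment the fear posterior rises sharply
  n <- 60
  mk <- function(fish, state, p) {
    data.frame(fish_id = fish, t0 = seq_len(n), truth = state,
               prediction = state, p_normal = p[1], p_fear = p[2],
               p_appetitive = p[3])
  }
  pred <- rbind(
    mk(1, "normal", c(0.8, 0.1, 0.1)), mk(1, "fear", c(0.2, 0.7, 0.1)),
    mk(2, "normal", c(0.75, 0.15, 0.1)), mk(2, "fear", c(0.25, 0.65, 0.1))
  )
  pred$p_normal <- pred$p_normal + with_seed(5, rnorm(nrow(pred), sd = 0.02))
  pred$p_fear <- pred$p_fear + with_seed(6, rnorm(nrow(pred), sd = 0.02))
  rep <- structure(
    list(predictions = pred, classes = c("normal", "fear", "appetitive")),
    class = "classifier_report"
  )
  res <- posterior_shift_analysis(rep, "fear")
  expect_equal(res$state[1:2], c("fear", "normal")) # largest |d| first
  expect_gt(res$d[res$state == "fear"], 0)
  expect_lt(res$d[res$state == "normal"], 0)
  expect_error(posterior_shift_analysis(rep, "appetitive"), "no windows")
})
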