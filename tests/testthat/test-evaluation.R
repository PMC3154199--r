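test_that("discretization uses floor bins with a closed upper edge", {
  cfg <- evaluation_config(window = 0.05, range = c(0, 3))
  expect_equal(discretize(0.049, cfg), 0L)
  expect_equal(discretize(0.05, cfg), 1L)
  expect_equal(discretize(3.0, cfg), 59L)
  expect_equal(discretize(c(-1, 4), cfg), c(0L, 59L))  # clipped to range
})

test_that("CCF counts same-bin agreement", {
  cfg <- evaluation_config(window = 0.05, range = c(0, 3))
  v <- c(0.3, 1.2, 2.7)
  expect_equal(ccf(v, v, cfg), 1.0)
  # bin-aligned values at least two windows apart never agree
  expect_equal(ccf(c(0.0, 0.5, 1.0), c(0.2, 0.7, 1.2), cfg), 0.0)
  # hand binning: bins (0,1,2) vs (0,2,2) agree at positions 1 and 3
  expect_equal(ccf(c(0.02, 0.06, 0.11), c(0.03, 0.12, 0.11), cfg), 2 / 3,
               tolerance = 1e-12)
  expect_error(ccf(1:3, 1:2, cfg), "lengths differ")

  band <- evaluation_config(window = 0.05, match = "band")
  expect_equal(ccf(c(0.02, 0.10), c(0.06, 0.30), band), 0.5)
})

test_that("AUCCF is the span-normalized trapezoid", {
  expect_equal(auccf(rep(0.8, 7)), 0.8, tolerance = 1e-12)
  expect_equal(auccf(seq(0, 1, length.out = 11)), 0.5, tolerance = 1e-12)
  expect_equal(auccf(c(0.5, 0.7, 0.9)), 0.7, tolerance = 1e-12)
  expect_error(auccf(0.5), "at least 2")
})

test_that("ROC handles separation, ties, and the hand-counted toy", {
  perfect <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auroc, 1.0)
  expect_equal(perfect$points$fpf[1], 0)
  expect_equal(perfect$points$tpf[nrow(perfect$points)], 1)

  tied <- roc_curve(rep(2, 8), rep(c(0, 1), 4))
  expect_equal(tied$auroc, 0.5)

  toy <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(toy$auroc, 0.75, tolerance = 1e-12)

  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
})

test_that("trapezoidal AUROC equals exhaustive tie-corrected pair counting", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    r <- roc_curve(scores, labels)
    expect_equal(r$auroc, brute_auroc(scores, labels), tolerance = 1e-12)
    # label inversion maps area a to 1 - a
    expect_equal(roc_curve(scores, 1 - labels)$auroc, 1 - r$auroc,
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  scores <- c(rnorm(40, 1), rnorm(40, 1.8))
  labels <- rep(c(0, 1), each = 40)
  ours <- roc_curve(scores, labels)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                        levels = c(0, 1), quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the half-angle operating point sits on the sensitivity = specificity locus", {
  chance <- roc_curve(rep(1, 10), rep(c(0, 1), 5))
  p <- optimal_point(chance)
  expect_equal(p$sensitivity, 0.5)
  expect_equal(p$specificity, 0.5)

  step <- roc_curve(c(1, 1, 2, 2), c(0, 0, 1, 1))
  ps <- optimal_point(step)
  expect_equal(ps$sensitivity, 1.0)
  expect_equal(ps$specificity, 1.0)

  set.seed(16)
  scores <- c(rnorm(300, 0), rnorm(300, 1.2))
  labels <- rep(c(0, 1), each = 300)
  pe <- optimal_point(roc_curve(scores, labels))
  expect_equal(pe$sensitivity, pe$specificity, tolerance = 1e-9)
})

test_that("cluster-adjusted correlation matches hand and library sandwiches", {
  # exact linear relation
  pred <- seq(0.1, 2, length.out = 40)
  res <- cluster_adjusted_correlation(pred, 2 * pred, rep(1:4, each = 10))
  expect_equal(res$r, 1.0, tolerance = 1e-12)
  expect_equal(res$slope, 2, tolerance = 1e-9)
  expect_lt(res$p, 1e-12)

  # under the null, correlation stays near zero
  set.seed(17)
  x <- rnorm(1000); y <- rnorm(1000)
  null <- cluster_adjusted_correlation(x, y, rep(1:10, each = 100))
  expect_lt(abs(null$r), 0.1)
  expect_gt(null$p, 0.01)

  # two clusters, three points each: hand-computed CR0 sandwich
  px <- c(0.2, 0.5, 0.9, 1.1, 1.6, 2.0)
  gy <- c(0.5, 0.4, 1.1, 0.9, 1.8, 1.7)
  cl <- c("a", "a", "a", "b", "b", "b")
  got <- cluster_adjusted_correlation(px, gy, cl)
  X <- cbind(1, px)
  beta <- solve(crossprod(X), crossprod(X, gy))
  e <- gy - X %*% beta
  meat <- matrix(0, 2, 2)
  for (g in c("a", "b")) {
    s <- crossprod(X[cl == g, ], e[cl == g])
    meat <- meat + s %*% t(s)
  }
  V <- solve(crossprod(X)) %*% meat %*% solve(crossprod(X))
  expect_equal(got$slope, beta[2], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(got$se, sqrt(V[2, 2]), tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(beta[2] / sqrt(V[2, 2])), df = 1),
               tolerance = 1e-12, ignore_attr = TRUE)

  skip_if_not_installed("sandwich")
  fit <- lm(gy ~ px)
  Vref <- sandwich::vcovCL(fit, cluster = cl, type = "HC0", cadjust = FALSE)
  expect_equal(got$se, sqrt(Vref[2, 2]), tolerance = 1e-10)

  expect_error(cluster_adjusted_correlation(px, gy, rep("a", 6)), "2 clusters")
})

test_that("confusion fractions match direct counting", {
  scores <- c(0.2, 0.3, 0.4, 1.2, 1.4, 1.6)
  labels <- c(0, 0, 1, 0, 1, 1)
  lo <- confusion_fractions(scores, labels, 0.1)
  expect_equal(lo$tpf, 1); expect_equal(lo$fpf, 1)
  hi <- confusion_fractions(scores, labels, 2)
  expect_equal(hi$tpf, 0); expect_equal(hi$fpf, 0)
  mid <- confusion_fractions(scores, labels, 1.0)
  expect_equal(mid$tpf, 2 / 3)   # scores 1.4, 1.6 of the three lesions
  expect_equal(mid$fpf, 1 / 3)   # score 1.2 of the three normals
  expect_equal(mid$tnf, 2 / 3)
  expect_error(confusion_fractions(scores, rep(1, 6), 1), "both classes")
})
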