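test_that("LDA boundary sits at the Bayes point for 1-D Gaussians", {
  set.seed(1)
  n <- 5000
  X <- matrix(c(rnorm(n, 0), rnorm(n, 2)), ncol = 1)
  y <- rep(c("A", "B"), each = n)
  m <- lda_fit(X, y, positive = "B")
  # decision boundary: delta_B = delta_A  =>  x* = (mu_A + mu_B) / 2
  xstar <- mean(m$mu %*% m$Sinv) / as.numeric(m$Sinv)
  expect_lt(abs(xstar - 1.0), 0.05)
})

test_that("LDA model is invariant to duplicating the training set", {
  tb <- sample_feature_table(c(HC = 30, AD = 30), 3, informative = 1,
                             effect_size_d = 1, seed = 2)
  m1 <- lda_fit(tb$X, tb$y, positive = "AD")
  m2 <- lda_fit(rbind(tb$X, tb$X), c(tb$y, tb$y), positive = "AD")
  expect_equal(m1$mu, m2$mu, tolerance = 1e-12)
  # covariance denominators differ (n-2), directions do not
  expect_equal(lda_predict(m1, tb$X), lda_predict(m2, tb$X))
})

test_that("LDA predictions match brute-force discriminant evaluation", {
  tb <- sample_feature_table(c(HC = 100, AD = 100), 2, informative = 1:2,
                             effect_size_d = 1, seed = 3)
  m <- lda_fit(tb$X, tb$y, positive = "AD")
  grid <- as.matrix(expand.grid(seq(-3, 4, length.out = 100),
                                seq(-3, 4, length.out = 100)))
  pred <- lda_predict(m, grid)
  # independent plug-in evaluation of the two discriminants
  delta <- function(x, mu, Sinv, pk)
    x %*% (Sinv %*% mu) - 0.5 * as.numeric(t(mu) %*% Sinv %*% mu) +
      log(pk)
  d1 <- delta(grid, m$mu[1, ], m$Sinv, 0.5)
  d2 <- delta(grid, m$mu[2, ], m$Sinv, 0.5)
  brute <- as.vector(ifelse(d2 >= d1, m$classes[2], m$classes[1]))
  expect_identical(pred, brute)
  # exact tie goes to the positive class
  mm <- suppressMessages(
    lda_fit(matrix(c(-1.5, -0.5, 0.5, 1.5), 4, 1), c("A", "A", "B", "B"),
            positive = "B"))
  expect_equal(lda_predict(mm, matrix(0, 1, 1)), "B")
})

test_that("feature order is irrelevant when consistent", {
  tb <- sample_feature_table(c(HC = 50, AD = 50), 4, informative = 1,
                             effect_size_d = 2, seed = 4)
  m1 <- lda_fit(tb$X, tb$y, positive = "AD")
  m2 <- lda_fit(tb$X[, 4:1], tb$y, positive = "AD")
  expect_identical(lda_predict(m1, tb$X), lda_predict(m2, tb$X[, 4:1]))
})

test_that("SVM dual solution matches the closed-form two-point QP", {
  X <- rbind(c(0, 0), c(1, 1))
  y <- c("neg", "pos")
  gamma <- 0.5; C <- 10
  m <- svm_fit(X, y, C = C, gamma = gamma, tol = 1e-8, positive = "pos")
  K <- exp(-gamma * as.matrix(dist(X))^2)
  # equality-constrained dual: alpha* = 2 / (K11 + K22 - 2 K12), capped
  astar <- min(2 / (K[1, 1] + K[2, 2] - 2 * K[1, 2]), C)
  dual_obj <- 2 * astar - 0.5 * astar^2 * (K[1, 1] + K[2, 2] - 2 * K[1, 2])
  a <- abs(m$fit$coefs)
  expect_equal(as.vector(a), rep(astar, 2), tolerance = 1e-6)
  obj <- sum(a) - 0.5 * sum((m$fit$coefs %*% t(m$fit$coefs)) *
                              K[m$fit$index, m$fit$index])
  expect_equal(obj, dual_obj, tolerance = 1e-6)
  expect_identical(svm_predict(m, X), y)
})

test_that("label flip negates the SVM decision function", {
  tb <- sample_feature_table(c(HC = 30, AD = 30), 2, informative = 1,
                             effect_size_d = 1.5, seed = 5)
  m1 <- svm_fit(tb$X, tb$y, positive = "AD")
  flipped <- factor(ifelse(tb$y == "AD", "HC", "AD"),
                    levels = c("HC", "AD"))
  m2 <- svm_fit(tb$X, flipped, positive = "AD")
  d1 <- attr(predict(m1$fit, tb$X, decision.values = TRUE),
             "decision.values")
  d2 <- attr(predict(m2$fit, tb$X, decision.values = TRUE),
             "decision.values")
  expect_equal(abs(as.vector(d1)), abs(as.vector(d2)), tolerance = 1e-3)
})

test_that("RBF kernel solves the XOR pattern", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c("a", "a", "b", "b")
  m <- svm_fit(X, y, C = 100, gamma = 1, positive = "b")
  expect_identical(svm_predict(m, X), y)
})

test_that("metrics follow the stated hand counts", {
  expect_equal(unname(evaluate(c("P", "P", "N", "N"),
                               c("P", "P", "N", "N"), "P")),
               c(100, 100, 100))
  expect_equal(unname(evaluate(c("P", "N", "N", "N"),
                               c("P", "P", "N", "N"), "P")),
               c(75, 50, 100))
  # majority-class predictor on a 60/40 split
  truth <- rep(c("maj", "min"), c(60, 40))
  expect_equal(unname(evaluate(rep("maj", 100), truth, "maj")),
               c(60, 100, 0))
  expect_error(evaluate(c("X", "P"), c("P", "P"), "P"), "unknown")
})

test_that("run-distribution CI uses linear-interpolation percentiles", {
  expect_equal(unname(ci_from_runs(rep(80, 5))), c(80, 80))
  expect_equal(unname(ci_from_runs(c(60, 70, 80, 90, 100))), c(61, 99))
  # CI width shrinks with test-set size
  set.seed(6)
  width <- vapply(c(10, 40, 160), function(nt) {
    ccrs <- replicate(200, 100 * mean(rbinom(nt, 1, 0.8)))
    diff(ci_from_runs(ccrs))
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

test_that("run comparison: t statistic, significance and normality", {
  r <- compare_runs(c(70, 72, 74), c(70, 72, 74))
  expect_equal(r$t, 0)
  expect_false(r$significant)
  # scalar oracle on two 3-element samples
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  r2 <- compare_runs(a, b)
  tt <- t.test(a, b)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  # power at the stringent level for well-separated distributions
  set.seed(7)
  r3 <- compare_runs(rnorm(300, 70, 1), rnorm(300, 80, 1))
  expect_true(r3$significant)
  expect_true(r3$ks_normality_pass)
})

test_that("LDA approaches the closed-form Bayes rate", {
  for (d in c(1, 2)) {
    tb <- sample_feature_table(c(HC = 2000, AD = 2000), 1,
                               informative = 1, effect_size_d = d,
                               seed = 100 + d)
    m <- lda_fit(tb$X, tb$y, positive = "AD")
    ccr <- 100 * mean(lda_predict(m, tb$X) == tb$y)
    expect_lt(abs(ccr - 100 * pnorm(d / 2)), 2)
  }
})
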