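# Classifiers and evaluation metrics. LDA with a pooled within-class
# covariance and uninformative priors (0.5/0.5) is written out
# explicitly from its discriminant form; the RBF-kernel SVM wraps
# libSVM (e1071). Metrics follow the CCR / SEN / SPE convention on the
# percent scale, with run-distribution confidence intervals.

#' Linear discriminant analysis with uninformative priors
#'
#' Class means and pooled within-class covariance; the discriminant of
#' class k is `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`. When
#' the covariance is ill-conditioned (e.g. more features than
#' subjects) a ridge `1e-6 trace(S)/p I` is added (logged via
#' message).
#'
#' @param X numeric matrix (subjects x features).
#' @param y binary labels; `positive` names the disease-ward class.
#' @param priors class priors, default uninformative c(0.5, 0.5)
#'   regardless of group sizes.
#' @param positive positive class label (default: second level).
#' @return an `lda_model`: means, pooled covariance (inverse), priors,
#'   class labels.
#' @export
lda_fit <- function(X, y, priors = c(0.5, 0.5), positive = NULL) {
  X <- as.matrix(X)
  lev <- if (is.factor(y)) levels(droplevels(y)) else sort(unique(y))
  if (length(lev) != 2) stop("lda_fit: need exactly two classes")
  if (is.null(positive)) positive <- lev[2]
  lev <- c(setdiff(lev, positive), positive)   # negative first
  n <- nrow(X); p <- ncol(X)
  mu <- rbind(colMeans(X[y == lev[1], , drop = FALSE]),
              colMeans(X[y == lev[2], , drop = FALSE]))
  S <- matrix(0, p, p)
  for (k in 1:2) {
    Xk <- X[y == lev[k], , drop = FALSE]
    S <- S + crossprod(sweep(Xk, 2L, mu[k, ]))
  }
  S <- S / max(n - 2, 1)
  S[!is.finite(S)] <- 0
  ridge_needed <- n <= p + 2 ||
    inherits(try(chol(S), silent = TRUE), "try-error") ||
    rcond(S) < 1e-12
  if (ridge_needed) {
    eps <- max(1e-6 * sum(diag(S)) / p, 1e-8)
    S <- S + diag(eps, p)
    message("lda_fit: covariance conditioned with ridge ", signif(eps, 3))
  }
  Sinv <- chol2inv(chol(S))
  structure(list(mu = mu, Sinv = Sinv, Sigma = S, priors = priors,
                 classes = lev, positive = positive),
            class = "lda_model")
}

#' @rdname lda_fit
#' @param model fitted `lda_model`.
#' @param newdata matrix with matching feature dimension.
#' @return `lda_predict` returns the predicted labels; ties go to the
#'   positive class.
#' @export
lda_predict <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(model$mu))
    stop("lda_predict: feature dimension mismatch (",
         ncol(newdata), " vs ", ncol(model$mu), ")")
  d <- vapply(1:2, function(k) {
    mk <- model$mu[k, ]
    as.numeric(newdata %*% (model$Sinv %*% mk)) -
      0.5 * sum(mk * (model$Sinv %*% mk)) + log(model$priors[k])
  }, numeric(nrow(newdata)))
  d <- matrix(d, ncol = 2)
  # tie -> positive class (class 2)
  model$classes[ifelse(d[, 2] >= d[, 1], 2L, 1L)]
}

#' RBF-kernel support vector machine (libSVM)
#'
#' Soft-margin SVM with kernel `exp(-gamma ||x - x'||^2)` solved by
#' libSVM via e1071. The default bandwidth is
#' `1 / (n_features * var(X))` and C = 1; an optional inner-CV grid
#' search follows the usual libSVM guidelines.
#'
#' @param X,y training data (binary labels).
#' @param C soft-margin penalty.
#' @param gamma kernel bandwidth; NULL for the variance default.
#' @param tol termination tolerance of the dual solver.
#' @param positive positive class label (default: second level).
#' @param tune if TRUE, grid-search C in 2^(-2..6), gamma in
#'   gamma0 * 2^(-3..3) by 5-fold inner CV.
#' @return an `svm_model` wrapping the libSVM fit.
#' @export
svm_fit <- function(X, y, C = 1, gamma = NULL, tol = 1e-3,
                    positive = NULL, tune = FALSE) {
  X <- as.matrix(X)
  lev <- if (is.factor(y)) levels(droplevels(y)) else sort(unique(y))
  if (length(lev) != 2) stop("svm_fit: need exactly two classes")
  if (is.null(positive)) positive <- lev[2]
  lev <- c(setdiff(lev, positive), positive)
  yf <- factor(as.character(y), levels = lev)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- 1 / (ncol(X) * if (v > 0) v else 1)
  }
  if (tune) {
    grid <- expand.grid(C = 2^seq(-2, 6, 2), gamma = gamma * 2^seq(-3, 3, 2))
    errs <- vapply(seq_len(nrow(grid)), function(i) {
      f <- e1071::svm(X, yf, kernel = "radial", cost = grid$C[i],
                      gamma = grid$gamma[i], scale = FALSE, cross = 5,
                      tolerance = tol)
      100 - f$tot.accuracy
    }, numeric(1))
    C <- grid$C[which.min(errs)]
    gamma <- grid$gamma[which.min(errs)]
  }
  fit <- e1071::svm(X, yf, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE, tolerance = tol)
  structure(list(fit = fit, C = C, gamma = gamma, classes = lev,
                 positive = positive),
            class = "svm_model")
}

#' @rdname svm_fit
#' @param model fitted `svm_model`.
#' @param newdata matrix of test rows.
#' @export
svm_predict <- function(model, newdata) {
  as.character(stats::predict(model$fit, as.matrix(newdata)))
}

#' Classification metrics: CCR, sensitivity, specificity
#'
#' CCR = correct / total, SEN = true-positive rate on the declared
#' disease-ward class, SPE = true-negative rate; all on the percent
#' scale.
#'
#' @param pred,truth equal-length label vectors.
#' @param positive the disease-ward class.
#' @param classes the admissible labels (default: those in `truth`
#'   plus `positive`); predictions outside this set are an error.
#' @return named numeric vector c(ccr, sen, spe); sen/spe are NaN when
#'   the corresponding class is absent from `truth`.
#' @export
evaluate <- function(pred, truth, positive,
                     classes = union(unique(truth), positive)) {
  if (length(pred) != length(truth))
    stop("evaluate: length mismatch")
  if (!positive %in% classes)
    stop("evaluate: positive class unknown")
  if (any(!pred %in% classes))
    stop("evaluate: prediction contains unknown labels")
  pos <- truth == positive
  c(ccr = 100 * mean(pred == truth),
    sen = 100 * mean(pred[pos] == truth[pos]),
    spe = 100 * mean(pred[!pos] == truth[!pos]))
}

#' 95% confidence interval from classification runs
#'
#' Empirical 2.5th/97.5th linear-interpolation percentiles of the
#' run-level CCR distribution; a normal-approximation mode
#' (mean +- 1.96 sd) is available.
#'
#' @param run_ccrs numeric vector of per-run CCRs (>= 2).
#' @param method "percentile" or "normal".
#' @return c(low, high).
#' @export
ci_from_runs <- function(run_ccrs, method = c("percentile", "normal")) {
  method <- match.arg(method)
  if (length(run_ccrs) < 2) stop("ci_from_runs: need >= 2 runs")
  if (method == "percentile") {
    q <- stats::quantile(run_ccrs, c(0.025, 0.975), names = FALSE, type = 7)
  } else {
    m <- mean(run_ccrs); s <- stats::sd(run_ccrs)
    q <- c(m - 1.96 * s, m + 1.96 * s)
  }
  stats::setNames(q, c("low", "high"))
}

#' Compare two run distributions
#'
#' Kolmogorov-Smirnov normality check of each sample against a fitted
#' normal, then Welch's unpaired two-sample t-test; significance at
#' the stringent level used for combined-vs-single comparisons
#' (default 1e-4).
#'
#' @param runs_A,runs_B numeric vectors of per-run CCRs (>= 2 each).
#' @param alpha significance level (default 1e-4).
#' @return list(t, p, significant, ks_normality_pass, ks_p).
#' @export
compare_runs <- function(runs_A, runs_B, alpha = 1e-4) {
  stopifnot(length(runs_A) >= 2, length(runs_B) >= 2)
  ksp <- vapply(list(runs_A, runs_B), function(r) {
    if (stats::sd(r) < 1e-12) return(1)   # degenerate: trivially "normal"
    suppressWarnings(stats::ks.test(r, "pnorm", mean(r),
                                    stats::sd(r))$p.value)
  }, numeric(1))
  if (stats::sd(runs_A) < 1e-12 && stats::sd(runs_B) < 1e-12) {
    tt <- list(statistic = 0, p.value = 1)
    if (!isTRUE(all.equal(mean(runs_A), mean(runs_B))))
      tt$p.value <- 0
  } else {
    tt <- stats::t.test(runs_A, runs_B, var.equal = FALSE)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha,
       ks_normality_pass = all(ksp > 0.05), ks_p = ksp)
}
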