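# Bridge from raw features to classifier input: per-feature linear
# age/sex correction fitted on healthy controls only and applied to
# everyone, explicit missing-value handling, and forward-backward
# stepwise selection on a linear model of the binary label. Every
# fitted object records the subject ids it touched (attribute
# "touched_ids") so the cross-validation layer can audit leakage.

covar_design <- function(covariates) {
  cbind(intercept = 1, age = covariates$age,
        male = as.numeric(covariates$sex == "M"))
}

#' Fit the age/sex correction model on controls
#'
#' Ordinary least squares per feature, controls only; missing cells
#' are excluded from each feature's fit. Requires both sexes among the
#' controls (the design is rank-deficient otherwise) and at least 3
#' controls with observed values per feature.
#'
#' @param features matrix (subjects x features), NA = missing;
#'   rownames are subject ids.
#' @param covariates data frame with `age` and `sex` ("M"/"F"), rows
#'   matching `features`.
#' @param control_ids ids of the control (HC) subjects to fit on.
#' @return a `correction_model`: coefficient matrix (intercept, age,
#'   male) x features, with `touched_ids` attribute.
#' @export
fit_correction <- function(features, covariates, control_ids) {
  rows <- match(control_ids, rownames(features))
  if (anyNA(rows)) stop("fit_correction: unknown control ids")
  Xc <- features[rows, , drop = FALSE]
  Z <- covar_design(covariates[rows, , drop = FALSE])
  if (qr(Z)$rank < 3)
    stop("fit_correction: rank-deficient covariate design on controls ",
         "(single sex or constant age)")
  coefs <- vapply(seq_len(ncol(Xc)), function(j) {
    ok <- !is.na(Xc[, j])
    if (sum(ok) < 3)
      stop("fit_correction: fewer than 3 controls observed for feature ",
           colnames(Xc)[j])
    stats::lm.fit(Z[ok, , drop = FALSE], Xc[ok, j])$coefficients
  }, numeric(3))
  colnames(coefs) <- colnames(features)
  structure(list(coef = coefs),
            class = "correction_model",
            touched_ids = control_ids)
}

#' Apply the correction model to all subjects
#'
#' Subtracts the control-fitted prediction (intercept + age and sex
#' terms) from every subject's features, patients included; missing
#' cells stay missing.
#'
#' @param features matrix (subjects x features).
#' @param model a `correction_model`.
#' @param covariates data frame matching `features` rows.
#' @return corrected feature matrix.
#' @export
apply_correction <- function(features, model, covariates) {
  Z <- covar_design(covariates)
  features - Z %*% model$coef
}

#' Handle missing feature values
#'
#' `train-mean` fills each missing cell with the mean over non-missing
#' *training* subjects (test subjects never enter the statistics);
#' `drop-subject` removes rows with any missing value; `drop-feature`
#' removes columns with any missing value.
#'
#' @param features matrix with NA for missing.
#' @param strategy one of "train-mean", "drop-subject", "drop-feature".
#' @param training_ids ids whose values may inform the fill statistics.
#' @return completed matrix (possibly with fewer rows/columns).
#' @export
impute_missing <- function(features,
                           strategy = c("train-mean", "drop-subject",
                                        "drop-feature"),
                           training_ids = rownames(features)) {
  strategy <- match.arg(strategy)
  out <- switch(strategy,
    "train-mean" = {
      tr <- match(training_ids, rownames(features))
      for (j in seq_len(ncol(features))) {
        mj <- mean(features[tr, j], na.rm = TRUE)
        if (is.nan(mj))
          stop("impute_missing: feature ", colnames(features)[j],
               " missing for all training subjects")
        features[is.na(features[, j]), j] <- mj
      }
      features
    },
    "drop-subject" = features[stats::complete.cases(features), ,
                              drop = FALSE],
    "drop-feature" = features[, colSums(is.na(features)) == 0,
                              drop = FALSE])
  attr(out, "touched_ids") <- training_ids
  out
}

# residualize x against the columns of Q (orthonormal basis)
resid_q <- function(Q, x) x - Q %*% crossprod(Q, x)

#' Forward-backward stepwise feature selection
#'
#' Stepwise regression of the binary class label on the features:
#' repeatedly add the candidate with the smallest partial-F p-value if
#' below `p_enter`, then remove any included feature whose p-value
#' exceeds `p_remove`. Ties break deterministically by feature name.
#' `p_enter <= p_remove` (required) plus the iteration cap guarantee
#' termination.
#'
#' @param features complete numeric matrix (impute first).
#' @param labels binary factor/character/numeric of length nrow.
#' @param p_enter,p_remove entry and removal p-value thresholds
#'   (defaults 0.05 / 0.10).
#' @param max_iter cap on add/remove sweeps.
#' @return integer vector of selected column indices (named), with a
#'   step log in attribute "log" and `touched_ids`.
#' @export
stepwise_select <- function(features, labels, p_enter = 0.05,
                            p_remove = 0.10, max_iter = 50) {
  if (p_enter > p_remove)
    stop("stepwise_select: p_enter must be <= p_remove")
  if (anyNA(features))
    stop("stepwise_select: features contain missing values; impute first")
  lev <- unique(labels)
  if (length(lev) != 2) stop("stepwise_select: labels must be binary")
  y <- as.numeric(labels == lev[2])
  n <- nrow(features)
  p <- ncol(features)
  nms <- colnames(features)
  if (is.null(nms)) nms <- paste0("V", seq_len(p))
  sel <- integer(0)
  log <- list()
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    # forward step
    cand <- setdiff(seq_len(p), sel)
    if (length(cand) > 0) {
      X0 <- cbind(1, features[, sel, drop = FALSE])
      Q <- qr.Q(qr(X0))
      e0 <- resid_q(Q, y)
      rss0 <- sum(e0^2)
      df1 <- n - ncol(X0) - 1
      pv <- vapply(cand, function(j) {
        xr <- resid_q(Q, features[, j])
        sxx <- sum(xr^2)
        if (sxx < 1e-12) return(1)
        rss1 <- rss0 - sum(e0 * xr)^2 / sxx
        f <- (rss0 - rss1) / (rss1 / df1)
        stats::pf(f, 1, df1, lower.tail = FALSE)
      }, numeric(1))
      ord <- order(pv, nms[cand])
      if (pv[ord[1]] < p_enter) {
        j <- cand[ord[1]]
        sel <- c(sel, j)
        log[[length(log) + 1]] <- data.frame(step = it, action = "add",
                                             feature = nms[j],
                                             p = pv[ord[1]])
        changed <- TRUE
      }
    }
    # backward step
    if (length(sel) > 0) {
      X <- cbind(1, features[, sel, drop = FALSE])
      fit <- stats::lm.fit(X, y)
      rdf <- n - ncol(X)
      s2 <- sum(fit$residuals^2) / rdf
      XtXi <- chol2inv(chol(crossprod(X)))
      se <- sqrt(s2 * diag(XtXi))
      tv <- fit$coefficients / se
      pv <- 2 * stats::pt(-abs(tv[-1]), rdf)
      ord <- order(-pv, nms[sel])
      if (pv[ord[1]] > p_remove) {
        j <- sel[ord[1]]
        log[[length(log) + 1]] <- data.frame(step = it, action = "remove",
                                             feature = nms[j],
                                             p = pv[ord[1]])
        sel <- setdiff(sel, j)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  names(sel) <- nms[sel]
  attr(sel, "log") <- if (length(log)) do.call(rbind, log) else
    data.frame(step = integer(), action = character(),
               feature = character(), p = numeric())
  attr(sel, "touched_ids") <- rownames(features)
  sel
}
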