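# The two evaluation protocols. Protocol "dataset1" splits the cohort
# into three parts; each part in turn provides the group statistics
# for the statistical-ROI features (CTH/TBM) while the other two parts
# are evaluated with repeated random 5% test / 95% train splits
# (3 x n_reps runs in total, averaged). Protocol "dataset2" is a
# single fixed train/test split with ROIs from a third, disjoint id
# set. Every fitted object's training ids are recorded in a run
# ledger, and an audit asserts zero leakage.

#' Protocol specification
#'
#' @param mode "dataset1" or "dataset2".
#' @param n_outer_parts outer parts for dataset1 (default 3).
#' @param test_fraction test fraction per repetition (default 0.05).
#' @param n_reps repetitions per outer part (default 100).
#' @param classifier "lda" or "svm".
#' @param correct apply control-trained age/sex correction.
#' @param select run stepwise selection inside each training fold.
#' @param global_selection if TRUE, stepwise selection runs once per
#'   outer part on all evaluation subjects before the repetitions —
#'   the (leaky) reading in which selection precedes cross-validation;
#'   off by default.
#' @param p_enter,p_remove stepwise thresholds.
#' @param impute missing-value strategy for [impute_missing()].
#' @param stratified stratify test draws by class.
#' @param seed integer master seed; per-repetition draws use a
#'   counter-based scheme on (seed, part, rep).
#' @return a `protocol_spec`.
#' @export
protocol_spec <- function(mode = c("dataset1", "dataset2"),
                          n_outer_parts = 3, test_fraction = 0.05,
                          n_reps = 100, classifier = c("lda", "svm"),
                          correct = TRUE, select = TRUE,
                          global_selection = FALSE,
                          p_enter = 0.05, p_remove = 0.10,
                          impute = "train-mean", stratified = TRUE,
                          seed = 1L) {
  mode <- match.arg(mode)
  classifier <- match.arg(classifier)
  if (test_fraction <= 0 || test_fraction >= 0.5)
    stop("protocol_spec: test_fraction must be in (0, 0.5)")
  if (n_outer_parts < 2) stop("protocol_spec: n_outer_parts must be >= 2")
  structure(list(mode = mode, n_outer_parts = n_outer_parts,
                 test_fraction = test_fraction, n_reps = n_reps,
                 classifier = classifier, correct = correct,
                 select = select, global_selection = global_selection,
                 p_enter = p_enter,
                 p_remove = p_remove, impute = impute,
                 stratified = stratified, seed = as.integer(seed)),
            class = "protocol_spec")
}

rep_seed <- function(seed, part, rep) {
  as.integer((as.numeric(seed) * 7919 + part * 100000 + rep * 7) %%
               2147483587 + 1)
}

# resolve one feature family for the given ROI source; providers are
# either a matrix (rows = ids) or function(roi_ids, need_ids)
resolve_features <- function(provider, roi_ids, need_ids) {
  M <- if (is.function(provider)) provider(roi_ids, need_ids) else provider
  miss <- setdiff(need_ids, rownames(M))
  if (length(miss) > 0)
    stop("feature provider lacks rows for ", paste(miss, collapse = ","))
  M[need_ids, , drop = FALSE]
}

# assemble all families into one matrix for the needed ids
assemble_features <- function(features, roi_ids, need_ids) {
  mats <- lapply(names(features), function(fam) {
    M <- resolve_features(features[[fam]], roi_ids, need_ids)
    if (is.null(colnames(M)))
      colnames(M) <- paste0(fam, seq_len(ncol(M)))
    M
  })
  do.call(cbind, mats)
}

# stratified draw of n_test ids preserving class proportions
draw_test <- function(ids, groups, n_test, stratified) {
  if (!stratified) return(sample(ids, n_test))
  gl <- split(ids, groups)
  alloc <- vapply(gl, length, integer(1)) * n_test / length(ids)
  base <- floor(alloc)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(alloc - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  unlist(Map(function(g, m) if (m > 0) sample(g, m) else character(0),
             gl, base), use.names = FALSE)
}

# one train/test evaluation: correction, imputation, selection, fit
fit_and_score <- function(Xall, manifest, train_ids, test_ids,
                          control_ids, contrast, spec) {
  covs <- manifest[match(rownames(Xall), manifest$id), c("age", "sex")]
  rownames(covs) <- rownames(Xall)
  touched <- character(0)
  if (spec$correct) {
    ctrl <- intersect(control_ids, rownames(Xall))
    ctrl <- setdiff(ctrl, test_ids)
    if (length(ctrl) < 3)
      stop("fit_and_score: fewer than 3 control subjects for correction")
    cm <- fit_correction(Xall, covs, ctrl)
    Xall <- apply_correction(Xall, cm, covs)
    touched <- union(touched, ctrl)
  }
  observed <- colSums(!is.na(Xall[train_ids, , drop = FALSE])) > 0
  if (!all(observed)) {
    if (!any(observed))
      stop("fit_and_score: no feature observed on the training set")
    Xall <- Xall[, observed, drop = FALSE]
  }
  Xall <- impute_missing(Xall, spec$impute, training_ids = train_ids)
  touched <- union(touched, train_ids)
  Xtr <- Xall[train_ids, , drop = FALSE]
  Xte <- Xall[test_ids, , drop = FALSE]
  ytr <- manifest$group[match(train_ids, manifest$id)]
  yte <- manifest$group[match(test_ids, manifest$id)]
  sel <- seq_len(ncol(Xtr))
  if (spec$select && ncol(Xtr) > 1) {
    s <- stepwise_select(Xtr, ytr, spec$p_enter, spec$p_remove)
    if (length(s) > 0) sel <- as.integer(s)
  }
  Xtr <- Xtr[, sel, drop = FALSE]
  Xte <- Xte[, sel, drop = FALSE]
  positive <- contrast[2]
  pred <- if (spec$classifier == "lda") {
    m <- suppressMessages(lda_fit(Xtr, ytr, positive = positive))
    lda_predict(m, Xte)
  } else {
    m <- svm_fit(Xtr, ytr, positive = positive)
    svm_predict(m, Xte)
  }
  list(metrics = evaluate(pred, yte, positive, classes = contrast),
       selected = colnames(Xall)[sel], touched = touched)
}

#' Run the dataset1 cross-validation protocol
#'
#' For each of the `n_outer_parts` parts: statistical ROIs are built
#' from that part only (via the feature providers), and the remaining
#' parts are evaluated with `n_reps` random test/train splits
#' (test = `test_fraction`, stratified). Covariate correction is
#' refit on each training fold's controls; imputation and stepwise
#' selection see training rows only. Results are the unweighted mean
#' over all `n_outer_parts * n_reps` runs with a percentile CI.
#'
#' @param manifest data frame (id, group, age, sex).
#' @param features named list of feature providers (matrix with id
#'   rownames, or function(roi_ids, need_ids) returning one).
#' @param contrast character pair, less-affected group first, e.g.
#'   c("HC","AD"); the second entry is the positive class.
#' @param spec a [protocol_spec()].
#' @return an `eval_result`: list with `runs` (data frame of per-run
#'   metrics), `mean` (ccr/sen/spe), `ci`, and `ledger`.
#' @export
run_dataset1 <- function(manifest, features, contrast,
                         spec = protocol_spec()) {
  cls_ids <- manifest$id[manifest$group %in% contrast]
  if (length(unique(manifest$group[manifest$id %in% cls_ids])) != 2)
    stop("run_dataset1: cohort lacks one of the contrast groups")
  hc_ids <- manifest$id[manifest$group == "HC"]
  set.seed(spec$seed)
  grp <- manifest$group[match(cls_ids, manifest$id)]
  part_of <- unlist(lapply(split(seq_along(cls_ids), grp), function(ix)
    stats::setNames(sample(rep_len(seq_len(spec$n_outer_parts),
                                   length(ix))), cls_ids[ix])))
  names(part_of) <- sub("^.*\\.", "", names(part_of))
  ledger <- list()
  runs <- list()
  for (part in seq_len(spec$n_outer_parts)) {
    roi_ids <- cls_ids[part_of[cls_ids] == part]
    eval_ids <- setdiff(cls_ids, roi_ids)
    need_ids <- union(eval_ids, setdiff(hc_ids, roi_ids))
    Xall <- assemble_features(features, roi_ids, need_ids)
    spec_part <- spec
    if (isTRUE(spec$global_selection) && spec$select && ncol(Xall) > 1) {
      Xe <- impute_missing(Xall[eval_ids, , drop = FALSE], spec$impute,
                           eval_ids)
      gsel <- stepwise_select(Xe,
                              manifest$group[match(eval_ids, manifest$id)],
                              spec$p_enter, spec$p_remove)
      if (length(gsel) > 0)
        Xall <- Xall[, as.integer(gsel), drop = FALSE]
      spec_part$select <- FALSE
    }
    egrp <- manifest$group[match(eval_ids, manifest$id)]
    n_test <- max(2, round(spec$test_fraction * length(eval_ids)))
    for (rep in seq_len(spec$n_reps)) {
      set.seed(rep_seed(spec$seed, part, rep))
      test_ids <- character(0)
      for (attempt in seq_len(100)) {
        test_ids <- draw_test(eval_ids, egrp, n_test, spec$stratified)
        tg <- manifest$group[match(test_ids, manifest$id)]
        if (length(unique(tg)) == 2) break
        if (attempt == 100)
          stop("run_dataset1: could not draw a two-class test set")
      }
      train_ids <- setdiff(eval_ids, test_ids)
      fs <- fit_and_score(Xall, manifest, train_ids, test_ids,
                          hc_ids, contrast, spec_part)
      runs[[length(runs) + 1]] <-
        data.frame(part = part, rep = rep, t(fs$metrics))
      ledger[[length(ledger) + 1]] <-
        list(part = part, rep = rep, roi_ids = roi_ids,
             train_ids = train_ids, test_ids = test_ids,
             touched_ids = fs$touched, selected = fs$selected,
             metrics = fs$metrics)
    }
  }
  runs <- do.call(rbind, runs)
  structure(list(runs = runs,
                 mean = colMeans(runs[, c("ccr", "sen", "spe")]),
                 ci = ci_from_runs(runs$ccr),
                 ledger = ledger, contrast = contrast, spec = spec),
            class = "eval_result")
}

#' Run the dataset2 fixed-split protocol
#'
#' Single evaluation with a fixed train/test split; statistical ROIs
#' come from `roi_source_ids`, which must be disjoint from both.
#'
#' @param manifest data frame (id, group, age, sex).
#' @param features named list of feature providers.
#' @param contrast character pair (positive class second).
#' @param train_ids,test_ids,roi_source_ids pairwise-disjoint id sets.
#' @param spec a [protocol_spec()].
#' @return an `eval_result` with a single run.
#' @export
run_dataset2 <- function(manifest, features, contrast, train_ids,
                         test_ids, roi_source_ids,
                         spec = protocol_spec(mode = "dataset2")) {
  sets <- list(train_ids, test_ids, roi_source_ids)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(sets[[i]], sets[[j]])) > 0)
      stop("run_dataset2: id sets overlap (",
           paste(intersect(sets[[i]], sets[[j]]), collapse = ","), ")")
  hc_ids <- manifest$id[manifest$group == "HC"]
  set.seed(spec$seed)
  need_ids <- union(union(train_ids, test_ids),
                    setdiff(hc_ids, roi_source_ids))
  Xall <- assemble_features(features, roi_source_ids, need_ids)
  fs <- fit_and_score(Xall, manifest, train_ids, test_ids,
                      setdiff(hc_ids, roi_source_ids), contrast, spec)
  runs <- data.frame(part = 1, rep = 1, t(fs$metrics))
  structure(list(runs = runs, mean = fs$metrics, ci = NULL,
                 ledger = list(list(part = 1, rep = 1,
                                    roi_ids = roi_source_ids,
                                    train_ids = train_ids,
                                    test_ids = test_ids,
                                    touched_ids = fs$touched,
                                    selected = fs$selected,
                                    metrics = fs$metrics)),
                 contrast = contrast, spec = spec),
            class = "eval_result")
}

#' Audit an evaluation ledger for leakage
#'
#' Asserts, for every recorded run: train and test ids are disjoint,
#' ROI-source and evaluation ids are disjoint, and no fitted object
#' touched a test subject.
#'
#' @param result an `eval_result`.
#' @return number of violations (0 = clean), with per-run details in
#'   attribute "violations".
#' @export
audit_ledger <- function(result) {
  bad <- list()
  for (e in result$ledger) {
    v <- character(0)
    if (length(intersect(e$train_ids, e$test_ids)) > 0)
      v <- c(v, "train/test overlap")
    if (length(intersect(e$roi_ids, union(e$train_ids, e$test_ids))) > 0)
      v <- c(v, "ROI/evaluation overlap")
    if (length(intersect(e$touched_ids, e$test_ids)) > 0)
      v <- c(v, "fit touched a test subject")
    if (length(v) > 0)
      bad[[length(bad) + 1]] <- list(part = e$part, rep = e$rep,
                                     violations = v)
  }
  structure(length(bad), violations = bad)
}

#' Compare feature families and their combination
#'
#' Runs the dataset1 protocol once per feature family and once for the
#' concatenated set ("All"), then tests All vs each family on the
#' run-level CCR distributions with [compare_runs()].
#'
#' @param manifest data frame (id, group, age, sex).
#' @param features named list of feature providers (e.g. MBL, HV,
#'   CTH, TBM).
#' @param contrast character pair (positive class second).
#' @param spec a [protocol_spec()].
#' @param alpha significance level for the All-vs-family tests.
#' @return a `feature_comparison`: list with `results` (named
#'   eval_results incl. "All"), `table` (data frame of CCR/CI/SEN/SPE
#'   per family), and `tests` (compare_runs output per family).
#' @export
run_feature_comparison <- function(manifest, features, contrast,
                                   spec = protocol_spec(),
                                   alpha = 1e-4) {
  fams <- names(features)
  results <- lapply(fams, function(f)
    run_dataset1(manifest, features[f], contrast, spec))
  names(results) <- fams
  results$All <- run_dataset1(manifest, features, contrast, spec)
  tests <- lapply(fams, function(f)
    compare_runs(results$All$runs$ccr, results[[f]]$runs$ccr, alpha))
  names(tests) <- fams
  tab <- do.call(rbind, lapply(c(fams, "All"), function(f) {
    r <- results[[f]]
    data.frame(feature = f, ccr = r$mean["ccr"], ci_low = r$ci["low"],
               ci_high = r$ci["high"], sen = r$mean["sen"],
               spe = r$mean["spe"],
               significant = if (f == "All") NA else tests[[f]]$significant,
               row.names = NULL)
  }))
  structure(list(results = results, table = tab, tests = tests,
                 contrast = contrast),
            class = "feature_comparison")
}
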