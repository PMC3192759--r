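test_that("protocol specification validates its invariants", {
  expect_error(protocol_spec(test_fraction = 0.6), "test_fraction")
  expect_error(protocol_spec(n_outer_parts = 1), "n_outer_parts")
  s <- protocol_spec(n_reps = 7, seed = 42)
  expect_equal(s$n_reps, 7)
})

test_that("dataset1 runs the full 3 x n_reps schedule without leakage", {
  tb <- sample_feature_table(c(HC = 150, AD = 150), 1, informative = 1,
                             effect_size_d = 1.2, age_slope = 0.02,
                             seed = 30)
  spec <- protocol_spec(n_reps = 100, select = FALSE, seed = 11)
  r <- run_dataset1(manifest_of(tb), list(HV = tb$X), c("HC", "AD"),
                    spec)
  expect_equal(nrow(r$runs), 300)
  expect_equal(sort(unique(r$runs$part)), 1:3)
  # test sets are 5% of the evaluation subjects (200 -> 10)
  expect_true(all(vapply(r$ledger, function(e) length(e$test_ids),
                         integer(1)) == 10))
  expect_equal(audit_ledger(r), 0, ignore_attr = TRUE)
  # aggregate equals the unweighted mean over recorded runs
  expect_equal(unname(r$mean["ccr"]), mean(r$runs$ccr))
  # same seed reproduces the result exactly
  r2 <- run_dataset1(manifest_of(tb), list(HV = tb$X), c("HC", "AD"),
                     spec)
  expect_identical(r$runs, r2$runs)
})

test_that("ROI-dependent providers see only the ROI part", {
  tb <- sample_feature_table(c(HC = 60, AD = 60), 3, informative = 1,
                             effect_size_d = 1, seed = 31)
  seen <- list()
  provider <- function(roi_ids, need_ids) {
    seen[[length(seen) + 1]] <<- list(roi = roi_ids, need = need_ids)
    tb$X[need_ids, , drop = FALSE]
  }
  spec <- protocol_spec(n_reps = 3, select = FALSE, seed = 2)
  r <- run_dataset1(manifest_of(tb), list(TBM = provider),
                    c("HC", "AD"), spec)
  expect_equal(length(seen), 3)       # one call per outer part
  for (s in seen)
    expect_length(intersect(s$roi, s$need), 0)
  expect_equal(audit_ledger(r), 0, ignore_attr = TRUE)
})

test_that("dataset2 demands disjoint id sets and is deterministic", {
  tb <- sample_feature_table(c(HC = 60, AD = 60), 4, informative = 1:2,
                             effect_size_d = 2, seed = 32)
  man <- manifest_of(tb)
  ids <- man$id
  roi <- ids[c(1:10, 61:70)]
  train <- ids[c(11:40, 71:100)]
  test <- ids[c(41:60, 101:120)]
  expect_error(run_dataset2(man, list(F = tb$X), c("HC", "AD"),
                            train, test, c(roi, train[1])), "overlap")
  r <- run_dataset2(man, list(F = tb$X), c("HC", "AD"), train, test, roi)
  r2 <- run_dataset2(man, list(F = tb$X), c("HC", "AD"), train, test, roi)
  expect_identical(r$runs, r2$runs)
  expect_gt(r$mean[["sen"]], 75)
  expect_gt(r$mean[["spe"]], 75)
})

test_that("correction inside folds uses only training controls", {
  tb <- sample_feature_table(c(HC = 80, AD = 80), 2, informative = 1,
                             effect_size_d = 1, age_slope = 0.05,
                             seed = 33)
  spec <- protocol_spec(n_reps = 5, seed = 3)
  r <- run_dataset1(manifest_of(tb), list(F = tb$X), c("HC", "AD"),
                    spec)
  ok <- vapply(r$ledger, function(e)
    length(intersect(e$touched_ids, e$test_ids)) == 0, logical(1))
  expect_true(all(ok))
})

test_that("feature comparison table has the per-family report shape", {
  set.seed(34)
  fams <- list()
  n <- c(HC = 80, AD = 80)
  for (f in c("MBL", "HV", "CTH", "TBM")) {
    tb <- sample_feature_table(n, 3, informative = 1, effect_size_d = 1,
                               seed = match(f, c("MBL", "HV", "CTH",
                                                 "TBM")) + 50)
    colnames(tb$X) <- paste0(f, 1:3)
    fams[[f]] <- tb$X
  }
  man <- manifest_of(sample_feature_table(n, 1, seed = 51))
  spec <- protocol_spec(n_reps = 5, select = FALSE, seed = 5)
  fc <- run_feature_comparison(man, fams, c("HC", "AD"), spec)
  expect_equal(fc$table$feature, c("MBL", "HV", "CTH", "TBM", "All"))
  expect_true(all(c("ccr", "ci_low", "ci_high", "sen", "spe") %in%
                    colnames(fc$table)))
  expect_true(is.na(fc$table$significant[5]))
  expect_named(fc$tests, c("MBL", "HV", "CTH", "TBM"))
})

test_that("a pure-noise family does not drag the combination down", {
  set.seed(35)
  n <- c(HC = 120, AD = 120)
  good1 <- sample_feature_table(n, 4, informative = 1:2,
                                effect_size_d = 1.2, seed = 61)
  noise <- sample_feature_table(n, 4, seed = 62)
  colnames(good1$X) <- paste0("G", 1:4)
  colnames(noise$X) <- paste0("N", 1:4)
  man <- manifest_of(good1)
  spec <- protocol_spec(n_reps = 15, seed = 6)
  r_good <- run_dataset1(man, list(G = good1$X), c("HC", "AD"), spec)
  r_noise <- run_dataset1(man, list(N = noise$X), c("HC", "AD"), spec)
  r_both <- run_dataset1(man, list(G = good1$X, N = noise$X),
                         c("HC", "AD"), spec)
  expect_lt(abs(r_noise$mean[["ccr"]] - 50), 12)
  expect_gt(r_both$mean[["ccr"]], r_good$mean[["ccr"]] - 3)
})

test_that("global selection precedes the repetitions when requested", {
  tb <- sample_feature_table(c(HC = 60, AD = 60), 8, informative = 1:2,
                             effect_size_d = 1.5, seed = 40)
  spec <- protocol_spec(n_reps = 3, global_selection = TRUE, seed = 4)
  r <- run_dataset1(manifest_of(tb), list(F = tb$X), c("HC", "AD"),
                    spec)
  expect_equal(nrow(r$runs), 9)
  # within-repetition feature sets are fixed per part
  sel_by_part <- split(vapply(r$ledger, function(e)
    paste(sort(e$selected), collapse = ","), character(1)),
    vapply(r$ledger, `[[`, integer(1), "part"))
  for (s in sel_by_part) expect_equal(length(unique(s)), 1L)
})
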