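# End-to-end orchestration: phantom cohort -> four feature families ->
# harmonized classification under the dataset1 protocol -> a results
# table in the CCR [CI] SEN SPE layout. All randomness flows from one
# master seed in the config.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_all()], with the
#' demo-scale defaults (32^3 grid, 15 subjects per group). Every entry
#' can be overridden via `...` (top-level names replace whole
#' sections).
#'
#' @param ... named overrides.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    shape = c(32, 32, 32), spacing = c(1, 1, 1), n_parcels = 84,
    n_per_group = c(HC = 15, `S-MCI` = 15, `P-MCI` = 15, AD = 15),
    effects = effect_spec(),
    n_atlas_pool = 6, atlas_k = 3,
    tbm_templates = c(hc = 3, mci = 3, ad = 3), tbm_alpha = 0.05,
    cth_fwhm_mm = 10, cth_alpha = 0.05,
    mbl_d = 10, mbl_k = 8,
    contrasts = list(c("HC", "AD")),
    protocol = list(n_reps = 20, test_fraction = 0.05,
                    classifier = "lda"),
    families = c("MBL", "HV", "CTH", "TBM"),
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full phantom pipeline
#'
#' Generates the template and cohort, extracts all configured feature
#' families (multi-atlas HV from a held-out atlas pool, statistical-ROI
#' TBM and CTH via per-part providers, transductive MBL), and runs the
#' dataset1 feature-family comparison for each configured contrast.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with `cohort`, `features` (providers), and
#'   `comparisons` (one `feature_comparison` per contrast).
#' @export
run_all <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  say("phantom: template ", paste(config$shape, collapse = "x"))
  tpl <- make_template(config$shape, config$spacing, config$n_parcels)
  say("phantom: cohort n = ", sum(config$n_per_group))
  cohort <- sample_cohort(tpl, tpl$labelmap, config$n_per_group,
                          config$effects, seed = seed)
  features <- list()
  if ("HV" %in% config$families) {
    say("HV: atlas pool (", config$n_atlas_pool, ") + segmentation")
    pool_cohort <- sample_cohort(tpl, tpl$labelmap,
                                 c(HC = config$n_atlas_pool),
                                 config$effects, seed = seed + 1L)
    pool <- lapply(pool_cohort$subjects, function(s)
      atlas_entry(s$image, s$labels, s$id))
    hv <- vapply(cohort$subjects, function(s)
      segment_hippo_subject(s, pool, config$atlas_k)$hv_mm3, numeric(1))
    features$HV <- matrix(hv, ncol = 1,
                          dimnames = list(cohort$manifest$id, "HV"))
  }
  if ("CTH" %in% config$families) {
    say("CTH: surface extraction + thickness")
    ct <- cth_node_table(cohort, fwhm_mm = config$cth_fwhm_mm)
    features$CTH <- local({
      ct <- ct; alpha <- config$cth_alpha; man <- cohort$manifest
      function(roi_ids, need_ids) {
        contrast <- unique(man$group[man$id %in% roi_ids])
        contrast <- STUDY_GROUPS[STUDY_GROUPS %in% contrast]
        cth_stat_roi_features(ct$thick, man$group[match(rownames(ct$thick),
                                                        man$id)],
                              ct$node_parcels, contrast, alpha,
                              roi_rows = roi_ids)[need_ids, , drop = FALSE]
      }
    })
  }
  if ("TBM" %in% config$families) {
    say("TBM: template library + Jacobian maps")
    lib <- build_template_library(cohort, config$tbm_templates["hc"],
                                  config$tbm_templates["mci"],
                                  config$tbm_templates["ad"],
                                  seed = seed + 2L)
    cache_env <- new.env()
    cache_env$jac <- list()
    features$TBM <- local({
      cohort <- cohort; lib <- lib; alpha <- config$tbm_alpha
      man <- cohort$manifest
      function(roi_ids, need_ids) {
        contrast <- unique(man$group[man$id %in% roi_ids])
        contrast <- STUDY_GROUPS[STUDY_GROUPS %in% contrast]
        tb <- tbm_features(cohort, lib, roi_ids, need_ids, contrast,
                           alpha, jac_cache = cache_env$jac)
        cache_env$jac <- tb$jacobians
        tb$features
      }
    })
  }
  if ("MBL" %in% config$families) {
    say("MBL: similarity graph + embedding")
    features$MBL <- local({
      cohort <- cohort; d <- config$mbl_d; k <- config$mbl_k
      function(roi_ids, need_ids)
        mbl_features(cohort, ids = need_ids, d = d, k = k)
    })
  }
  features <- features[intersect(config$families, names(features))]
  comparisons <- lapply(config$contrasts, function(ctr) {
    say("protocol: ", ctr[1], " vs ", ctr[2])
    spec <- do.call(protocol_spec,
                    c(config$protocol, list(seed = seed + 3L)))
    run_feature_comparison(cohort$manifest, features, ctr, spec)
  })
  names(comparisons) <- vapply(config$contrasts, paste,
                               character(1), collapse = "vs")
  list(cohort = cohort, features = features, comparisons = comparisons)
}

#' Format a feature-comparison table
#'
#' Prints one row per feature family in the layout
#' `CCR [lo hi] SEN SPE`, with a dagger marking families whose run
#' distribution differs significantly from the combined ("All") rows.
#'
#' @param comparison a `feature_comparison` (or the `comparisons`
#'   element of [run_all()] output).
#' @return the formatted data frame, invisibly.
#' @export
report <- function(comparison) {
  if (!inherits(comparison, "feature_comparison")) {
    for (cmp in comparison$comparisons) report(cmp)
    return(invisible(NULL))
  }
  tab <- comparison$table
  cat(sprintf("%s vs %s\n", comparison$contrast[1],
              comparison$contrast[2]))
  cat(sprintf("%-5s %-16s %5s %5s\n", "", "CCR [95% CI]", "SEN", "SPE"))
  for (i in seq_len(nrow(tab))) {
    dag <- if (isTRUE(tab$significant[i])) "†" else " "
    cat(sprintf("%-5s %3.0f%s [%.0f %.0f]%6.0f %5.0f\n",
                tab$feature[i], tab$ccr[i], dag, tab$ci_low[i],
                tab$ci_high[i], tab$sen[i], tab$spe[i]))
  }
  invisible(tab)
}
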