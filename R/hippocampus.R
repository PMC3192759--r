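# Multi-atlas hippocampus segmentation: atlas selection by image
# similarity, label propagation through FFD registration into a
# spatial prior, and EM refinement of an intensity mixture under that
# prior. The resulting bilateral volume is the single HV feature.

#' Atlas entry
#'
#' @param image [image3d()] atlas intensity image.
#' @param labels aligned [labelmap3d()].
#' @param id unique atlas identifier (used for deterministic
#'   tie-breaks).
#' @return object of class `atlas_entry`.
#' @export
atlas_entry <- function(image, labels, id) {
  stopifnot(identical(dim(image$data), dim(labels$labels)))
  structure(list(image = image, labels = labels, id = as.character(id)),
            class = "atlas_entry")
}

hippo_mask <- function(labels) {
  array(labels$labels %in% c(4L, 5L), dim(labels$labels))
}

ncc_value <- function(a, b) {
  ac <- a - mean(a); bc <- b - mean(b)
  den <- sqrt(sum(ac^2)) * sqrt(sum(bc^2))
  if (den < 1e-12) return(0)
  sum(ac * bc) / den
}

#' Select the most similar atlases for a query image
#'
#' Ranks the atlas pool by normalized cross-correlation with the query
#' after affine alignment to the pool mean image (the pool shares one
#' grid), and returns the top `k`. Similarity can be restricted to a
#' region of interest (e.g. around the hippocampi), which matches
#' queries to atlases of similar local anatomy rather than similar
#' global shape. Ties break deterministically by atlas id.
#'
#' @param query [image3d()].
#' @param pool list of [atlas_entry()] objects.
#' @param k number of atlases to keep (k <= pool size).
#' @param align if FALSE the query is assumed already aligned to the
#'   pool grid and the affine step is skipped.
#' @param roi logical array (pool grid): if given, similarity is
#'   computed over these voxels only.
#' @return list of `k` atlas entries, most similar first.
#' @export
select_atlases <- function(query, pool, k, align = TRUE, roi = NULL) {
  if (length(pool) == 0) stop("select_atlases: empty atlas pool")
  if (k > length(pool)) stop("select_atlases: k exceeds pool size")
  if (align) {
    mean_img <- pool[[1]]$image
    mean_img$data <- Reduce(`+`, lapply(pool, function(a) a$image$data)) /
      length(pool)
    aff <- affine_align(query, mean_img, iters = 60)
    f <- deformation_field(img_geom(mean_img), 10, affine = aff)
    query <- warp(query, f, pad = border_value(query))
  }
  sims <- if (is.null(roi)) {
    vapply(pool, function(a) ncc_value(query$data, a$image$data),
           numeric(1))
  } else {
    vapply(pool, function(a) ncc_value(query$data[roi],
                                       a$image$data[roi]), numeric(1))
  }
  ids <- vapply(pool, `[[`, character(1), "id")
  ord <- order(-sims, ids)
  pool[ord[seq_len(k)]]
}

#' Propagate atlas labels into a spatial hippocampus prior
#'
#' Registers each atlas to the query with a B-spline FFD (affine
#' pre-alignment included), warps its binary hippocampus mask onto the
#' query grid, and averages the warped masks voxelwise. Atlases whose
#' registration fails are dropped with a warning; an error is raised
#' only if all fail.
#'
#' @param query [image3d()].
#' @param atlases list of [atlas_entry()] objects (>= 1).
#' @param registration_params list of arguments passed to
#'   [ffd_register()] (control_spacing_mm, levels, iters, reg_weight).
#' @param affine_pre if TRUE run [affine_align()] per atlas first.
#' @return a `spatial_prior`: list with `prob` (3D array in [0,1]) and
#'   the query geometry.
#' @export
propagate_labels <- function(query, atlases,
                             registration_params = list(
                               control_spacing_mm = 10, levels = 2,
                               iters = c(30, 10)),
                             affine_pre = FALSE) {
  if (length(atlases) == 0) stop("propagate_labels: no atlases")
  acc <- array(0, dim(query$data))
  n_ok <- 0L
  for (a in atlases) {
    warped <- tryCatch({
      aff <- if (affine_pre) affine_align(a$image, query, iters = 40)
        else affine3d()
      fld <- do.call(ffd_register,
                     c(list(moving = a$image, fixed = query, affine = aff),
                       registration_params))
      m <- a$image
      m$data <- hippo_mask(a$labels) + 0
      warp(m, fld, pad = 0)$data
    }, error = function(e) {
      warning("propagate_labels: atlas ", a$id, " dropped (",
              conditionMessage(e), ")")
      NULL
    })
    if (!is.null(warped)) { acc <- acc + warped; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) stop("propagate_labels: registration failed for all atlases")
  prob <- pmin(pmax(acc / n_ok, 0), 1)
  structure(list(prob = array(prob, dim(query$data)),
                 spacing = query$spacing, origin = query$origin),
            class = "spatial_prior")
}

#' EM segmentation under a spatial prior
#'
#' Gaussian intensity mixture whose first class (hippocampus) uses the
#' spatial prior, blended with a uniform prior as
#' `alpha * prior + (1 - alpha) / n_classes` to avoid zero-probability
#' lock-in. Runs on the dilated prior support. E-step posteriors;
#' M-step updates means, variances and (optionally) global mixing
#' weights that modulate the spatial prior, `pi_k(v) proportional to
#' w_k prior_k(v)` — this lets the model grow or shrink the structure
#' relative to the atlas prior instead of regressing to the atlas
#' mean. Stops when the log-likelihood gain drops below `tol`; the
#' log-likelihood trace is non-decreasing.
#'
#' @param query [image3d()].
#' @param prior `spatial_prior` from [propagate_labels()].
#' @param n_classes number of mixture classes (>= 2; class 1 is
#'   hippocampus).
#' @param iters maximum EM iterations.
#' @param tol log-likelihood stopping tolerance.
#' @param alpha prior blending weight in [0,1].
#' @param update_mixing if TRUE, update global class mixing weights in
#'   the M-step. With spatially varying priors this weight update is
#'   only an approximate maximizer, so the log-likelihood trace is
#'   then no longer guaranteed monotone; the default FALSE keeps the
#'   exact EM contract.
#' @return list with `labels` ([labelmap3d()], hippocampus = 1),
#'   `mu`, `sigma`, `mixing`, `posterior1` (class-1 posterior on the
#'   support), `loglik` (trace).
#' @export
em_segment <- function(query, prior, n_classes = 2, iters = 50,
                       tol = 1e-4, alpha = 0.9, update_mixing = FALSE) {
  stopifnot(n_classes >= 2)
  supp <- dilate3(prior$prob > 0.01, 2L)
  if (!any(supp)) stop("em_segment: empty prior support")
  x <- query$data[supp]
  p1 <- alpha * prior$prob[supp] + (1 - alpha) / n_classes
  pri <- matrix((1 - p1) / (n_classes - 1), length(x), n_classes)
  pri[, 1] <- p1
  # init: hippocampus stats from the prior, others from quantile bands
  w1 <- prior$prob[supp]
  mu <- numeric(n_classes); sg <- numeric(n_classes)
  mu[1] <- if (sum(w1) > 0) sum(w1 * x) / sum(w1) else mean(x)
  sg[1] <- max(stats::sd(x) / 2, 1e-3)
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_classes))
  for (kk in 2:n_classes) mu[kk] <- qs[kk]
  sg[2:n_classes] <- max(stats::sd(x) / 2, 1e-3)
  var_floor <- 1e-4 * stats::var(x)
  mix <- rep(1 / n_classes, n_classes)
  loglik <- numeric(0)
  r <- NULL
  for (it in seq_len(iters)) {
    pv <- sweep(pri, 2L, mix * n_classes, "*")
    pv <- pv / rowSums(pv)
    dens <- vapply(seq_len(n_classes), function(kk)
      stats::dnorm(x, mu[kk], sg[kk]), numeric(length(x)))
    num <- pv * dens
    tot <- rowSums(num)
    tot[tot < 1e-300] <- 1e-300
    loglik <- c(loglik, sum(log(tot)))
    r <- num / tot
    for (kk in seq_len(n_classes)) {
      nk <- sum(r[, kk])
      if (nk < 1e-8) next
      mu[kk] <- sum(r[, kk] * x) / nk
      v <- sum(r[, kk] * (x - mu[kk])^2) / nk
      if (v < var_floor) {
        v <- var_floor
        message("em_segment: variance floored for class ", kk)
      }
      sg[kk] <- sqrt(v)
    }
    if (update_mixing) mix <- colMeans(r)
    if (it > 1 && loglik[it] - loglik[it - 1] < tol) break
  }
  lab <- array(0L, dim(query$data))
  lab[supp] <- ifelse(max.col(r, ties.method = "first") == 1L, 1L, 0L)
  out_labels <- labelmap3d(lab, NULL,
                           c(background = 0L, hippocampus = 1L),
                           spacing = query$spacing, origin = query$origin)
  list(labels = out_labels, mu = mu, sigma = sg, mixing = mix,
       posterior1 = r[, 1], loglik = loglik)
}

#' Bilateral hippocampal volume
#'
#' Voxel count of all hippocampus labels times voxel volume; the single
#' HV feature in mm^3. Depends only on the labels, never on image
#' intensities.
#'
#' @param labels a [labelmap3d()] whose legend contains at least one
#'   label whose name contains "hippocampus".
#' @param spacing voxel size in mm (defaults to the label map's).
#' @return volume in mm^3.
#' @export
hippocampal_volume <- function(labels, spacing = labels$spacing) {
  nm <- names(labels$legend)
  codes <- labels$legend[nm == "hippocampus" |
                           grepl("(left|right)-hippocampus", nm)]
  if (length(codes) == 0)
    stop("hippocampal_volume: no hippocampus label in legend")
  n <- sum(labels$labels %in% codes)
  if (n == 0) stop("hippocampal_volume: hippocampus label absent from grid")
  n * prod(spacing)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical arrays of equal dimension.
#' @return 2|A n B| / (|A| + |B|).
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Full hippocampal-volume feature for one subject
#'
#' Convenience chain: atlas selection, label propagation, EM
#' refinement, volume measurement.
#'
#' @param subject a `subject_record` (or any list with `image`).
#' @param pool list of [atlas_entry()] objects.
#' @param k atlases to select.
#' @param n_classes,alpha EM settings; the default three-class mixture
#'   (hippocampus / boundary tissue / white matter) absorbs
#'   partial-volume voxels at the blurred hippocampal rim.
#' @param ... passed to [propagate_labels()].
#' @return list with `hv_mm3`, `labels`, `prior`, `em`.
#' @export
segment_hippo_subject <- function(subject, pool, k = 3, n_classes = 3,
                                  alpha = 0.9,
                                  registration_params = list(
                                    control_spacing_mm = 3, levels = 2,
                                    iters = c(40, 20),
                                    reg_weight = 0.001), ...) {
  # similarity in a region around the pooled hippocampus masks, so the
  # selected atlases match the query's local anatomy
  roi <- dilate3(Reduce(`|`, lapply(pool, function(a)
    hippo_mask(a$labels))), 3L)
  sel <- select_atlases(subject$image, pool, k, align = FALSE, roi = roi)
  prior <- propagate_labels(subject$image, sel,
                            registration_params = registration_params, ...)
  em <- em_segment(subject$image, prior, n_classes = n_classes,
                   alpha = alpha, update_mixing = TRUE)
  list(hv_mm3 = hippocampal_volume(em$labels), labels = em$labels,
       prior = prior, em = em)
}

#' HV feature matrix for a cohort
#'
#' Uses held-out cohort subjects as the atlas pool (their label maps
#' act as atlas segmentations), mirroring the use of study images as
#' atlases.
#'
#' @param cohort a `cohort`.
#' @param atlas_ids subject ids forming the atlas pool; excluded from
#'   the output rows.
#' @param k atlases selected per query.
#' @param ... passed to [segment_hippo_subject()].
#' @return one-column matrix "HV" (mm^3), rownames = subject ids.
#' @export
hv_features <- function(cohort, atlas_ids, k = 3, ...) {
  pool <- lapply(Filter(function(s) s$id %in% atlas_ids, cohort$subjects),
                 function(s) atlas_entry(s$image, s$labels, s$id))
  rest <- Filter(function(s) !(s$id %in% atlas_ids), cohort$subjects)
  hv <- vapply(rest, function(s)
    segment_hippo_subject(s, pool, k, ...)$hv_mm3, numeric(1))
  matrix(hv, ncol = 1,
         dimnames = list(vapply(rest, `[[`, character(1), "id"), "HV"))
}
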