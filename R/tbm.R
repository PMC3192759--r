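# Multi-template tensor-based morphometry. Each template in a
# stratified library is registered to a subject; Jacobian-determinant
# maps are computed on the template grid and resampled into a common
# reference space (the mean anatomical template). Voxelwise two-sample
# t-maps between groups define statistical ROIs per parcel, and the
# feature is the p-value-weighted mean Jacobian over the ROI voxels,
# averaged across templates.

#' Build a stratified template library
#'
#' Randomly draws `n_hc`/`n_mci`/`n_ad` subjects (MCI pooled over
#' S-MCI and P-MCI), builds the mean anatomical reference by affine
#' co-alignment and voxelwise averaging with one refinement pass
#' (re-register to the mean, re-average), and stores a reference->
#' template deformation for every template.
#'
#' @param cohort a `cohort`.
#' @param n_hc,n_mci,n_ad templates per group (defaults 10/10/10).
#' @param seed integer seed for the draw.
#' @param registration_params arguments for the reference->template
#'   [ffd_register()] calls.
#' @return a `template_library`: list of `templates` (id, group, image),
#'   `reference` ([image3d()]), `to_template` (deformation fields,
#'   fixed = reference, moving = template), and the template ids.
#' @export
build_template_library <- function(cohort, n_hc = 10, n_mci = 10,
                                   n_ad = 10, seed = 1L,
                                   registration_params = list(
                                     control_spacing_mm = 10, levels = 2,
                                     iters = c(25, 8))) {
  set.seed(seed)
  man <- cohort$manifest
  pick <- function(groups, n, what) {
    ids <- man$id[man$group %in% groups]
    if (length(ids) < n)
      stop("build_template_library: not enough ", what, " subjects (",
           length(ids), " < ", n, ")")
    sample(ids, n)
  }
  ids <- c(if (n_hc > 0) pick("HC", n_hc, "HC"),
           if (n_mci > 0) pick(c("S-MCI", "P-MCI"), n_mci, "MCI"),
           if (n_ad > 0) pick("AD", n_ad, "AD"))
  subj <- cohort$subjects[match(ids, man$id)]
  imgs <- lapply(subj, `[[`, "image")
  # iteration 0: average after affine alignment to the first template
  align_avg <- function(ref) {
    acc <- array(0, dim(ref$data))
    for (im in imgs) {
      if (identical(im$data, ref$data)) { acc <- acc + im$data; next }
      aff <- affine_align(im, ref, iters = 40)
      f <- deformation_field(img_geom(ref), 10, affine = aff)
      acc <- acc + warp(im, f, pad = border_value(im))$data
    }
    image3d(acc / length(imgs), spacing = ref$spacing, origin = ref$origin)
  }
  reference <- align_avg(imgs[[1]])
  reference <- align_avg(reference)       # one refinement pass
  to_template <- lapply(imgs, function(im)
    do.call(ffd_register, c(list(moving = im, fixed = reference),
                            registration_params)))
  structure(list(
    templates = Map(function(s, im) list(id = s$id, group = s$group,
                                         image = im), subj, imgs),
    reference = reference, to_template = to_template, ids = ids),
    class = "template_library")
}

#' Per-template Jacobian maps of a subject in reference space
#'
#' For each template: FFD-register template -> subject (fixed =
#' template, so the Jacobian lives on the template grid and J < 1
#' marks subject tissue contraction), then normalize into reference
#' space: the map is resampled through the stored reference->template
#' field and multiplied by that field's own Jacobian, so by the chain
#' rule every normalized map expresses subject volume change relative
#' to the common reference anatomy, whichever template produced it. A
#' failed per-template registration yields a NULL map with a warning.
#'
#' @param subject `subject_record` (or list with `image`).
#' @param library a `template_library`.
#' @param registration_params arguments for [ffd_register()].
#' @return list of [image3d()] Jacobian maps in reference space, one
#'   per template (NULL where registration failed), named by template
#'   id.
#' @export
subject_jacobians <- function(subject, library,
                              registration_params = list(
                                control_spacing_mm = 6, levels = 2,
                                iters = c(25, 8))) {
  maps <- lapply(seq_along(library$templates), function(i) {
    tpl <- library$templates[[i]]
    tryCatch({
      fld <- do.call(ffd_register,
                     c(list(moving = subject$image, fixed = tpl$image),
                       registration_params))
      J <- jacobian_map(fld)
      # chain rule: (template->subject J at T_{r->t}(x)) * (r->t J at x)
      Jr <- warp(J, library$to_template[[i]], pad = 1)
      Jt <- jacobian_map(library$to_template[[i]])
      image3d(Jr$data * Jt$data, spacing = Jr$spacing, origin = Jr$origin)
    }, error = function(e) {
      warning("subject_jacobians: template ", tpl$id, " failed (",
              conditionMessage(e), ")")
      NULL
    })
  })
  names(maps) <- vapply(library$templates, `[[`, character(1), "id")
  maps
}

#' Voxelwise two-sample t-map between two sets of Jacobian maps
#'
#' Welch's unequal-variance t-test per voxel within a mask, two-sided
#' p-values. Voxels with zero pooled variance are flagged and excluded
#' (NA in both maps).
#'
#' @param maps_A,maps_B lists of [image3d()] maps (>= 2 each); group A
#'   is the less-affected group of the contrast.
#' @param mask logical array; voxels outside are excluded.
#' @param contrast label for the comparison (e.g. "HCvsAD").
#' @return a `stat_map`: list with `t`, `p`, `mean_A`, `mean_B` (3D
#'   arrays, NA outside mask or where flagged), `contrast`, `n_A`,
#'   `n_B`.
#' @export
voxelwise_ttest <- function(maps_A, maps_B, mask = NULL,
                            contrast = "AvsB") {
  maps_A <- Filter(Negate(is.null), maps_A)
  maps_B <- Filter(Negate(is.null), maps_B)
  nA <- length(maps_A); nB <- length(maps_B)
  if (nA < 2 || nB < 2)
    stop("voxelwise_ttest: need >= 2 maps per group")
  d <- dim(maps_A[[1]]$data)
  if (is.null(mask)) mask <- array(TRUE, d)
  XA <- vapply(maps_A, function(m) m$data[mask], numeric(sum(mask)))
  XB <- vapply(maps_B, function(m) m$data[mask], numeric(sum(mask)))
  mA <- rowMeans(XA); mB <- rowMeans(XB)
  vA <- rowSums((XA - mA)^2) / (nA - 1)
  vB <- rowSums((XB - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  ok <- se2 > 1e-24
  tv <- pv <- rep(NA_real_, length(mA))
  tv[ok] <- (mA[ok] - mB[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((vA[ok] / nA)^2 / (nA - 1) + (vB[ok] / nB)^2 / (nB - 1))
  pv[ok] <- 2 * stats::pt(-abs(tv[ok]), df)
  put <- function(v) { a <- array(NA_real_, d); a[mask] <- v; a }
  structure(list(t = put(tv), p = put(pv), mean_A = put(mA),
                 mean_B = put(mB), contrast = contrast,
                 n_A = nA, n_B = nB), class = "stat_map")
}

# voxels passing the statistical-ROI criterion: significant AND
# atrophic (map mean lower in the more-affected group B)
stat_roi_voxels <- function(statmap, alpha) {
  sel <- !is.na(statmap$p) & statmap$p < alpha &
    statmap$mean_A > statmap$mean_B
  sel
}

#' Statistical-ROI TBM features for one subject
#'
#' Per parcel, the member voxels are those significant at `alpha` in
#' the group t-map with the atrophic direction (mean Jacobian lower in
#' the more-affected group). The feature is the p-value-weighted mean
#' Jacobian over member voxels, weight w = -log10(p); it is computed
#' per template map and averaged over templates. Parcels with no
#' member voxels fall back to the unweighted parcel mean (flagged in
#' the "empty" attribute).
#'
#' @param subject_maps list of reference-space Jacobian [image3d()]
#'   maps for one subject (one per template; NULLs skipped).
#' @param statmap a `stat_map` built from subjects disjoint from this
#'   one (enforced by the cross-validation layer).
#' @param parcellation 3D integer parcel array in reference space
#'   (codes > 0 inside tissue).
#' @param alpha voxelwise significance threshold (default 0.05).
#' @return named numeric feature vector, one entry per parcel;
#'   attribute "empty" marks parcels with no significant voxels.
#' @export
stat_roi_features <- function(subject_maps, statmap, parcellation,
                              alpha = 0.05) {
  subject_maps <- Filter(Negate(is.null), subject_maps)
  if (length(subject_maps) == 0)
    stop("stat_roi_features: no usable Jacobian maps for subject")
  sel <- stat_roi_voxels(statmap, alpha)
  codes <- sort(setdiff(unique(as.integer(parcellation)), 0L))
  if (!any(sel & parcellation > 0))
    stop("stat_roi_features: no significant voxels in any parcel; ",
         "consider a larger alpha")
  w <- -log10(statmap$p)
  per_tpl <- vapply(subject_maps, function(m) {
    vapply(codes, function(pc) {
      inp <- parcellation == pc
      mem <- inp & sel
      if (any(mem)) {
        ww <- w[mem]
        sum(ww * m$data[mem]) / sum(ww)
      } else {
        mean(m$data[inp])
      }
    }, numeric(1))
  }, numeric(length(codes)))
  feat <- rowMeans(matrix(per_tpl, nrow = length(codes)))
  names(feat) <- paste0("TBM_p", codes - min(codes) + 1L)
  empty <- vapply(codes, function(pc) !any(parcellation == pc & sel),
                  logical(1))
  attr(feat, "empty") <- empty
  feat
}

#' TBM feature matrix for a cohort
#'
#' Full chain for a set of subjects: per-subject multi-template
#' Jacobian maps, a group t-map from the ROI-source subjects only, and
#' statistical-ROI features for every listed subject.
#'
#' @param cohort a `cohort`.
#' @param library a `template_library`.
#' @param roi_ids subject ids used to build the statistical map (must
#'   be disjoint from `feature_ids`; checked).
#' @param feature_ids subjects to featurize.
#' @param contrast character pair, less-affected group first, e.g.
#'   `c("HC","AD")`.
#' @param alpha significance threshold.
#' @param jac_cache optional precomputed list (by subject id) of
#'   reference-space Jacobian map lists, to reuse across calls.
#' @param ... passed to [subject_jacobians()].
#' @return list with `features` (matrix subjects x parcels), `statmap`,
#'   and `jacobians` (the cache, augmented).
#' @export
tbm_features <- function(cohort, library, roi_ids, feature_ids,
                         contrast, alpha = 0.05, jac_cache = list(),
                         ...) {
  if (length(intersect(roi_ids, feature_ids)) > 0)
    stop("tbm_features: ROI-source and feature subjects overlap")
  man <- cohort$manifest
  get_maps <- function(id) {
    if (is.null(jac_cache[[id]])) {
      s <- cohort$subjects[[match(id, man$id)]]
      jac_cache[[id]] <<- subject_jacobians(s, library, ...)
    }
    jac_cache[[id]]
  }
  mean_map <- function(id) {
    maps <- Filter(Negate(is.null), get_maps(id))
    acc <- Reduce(`+`, lapply(maps, `[[`, "data")) / length(maps)
    image3d(acc, spacing = library$reference$spacing,
            origin = library$reference$origin)
  }
  gA <- man$group[match(roi_ids, man$id)] == contrast[1]
  maps_A <- lapply(roi_ids[gA], mean_map)
  maps_B <- lapply(roi_ids[!gA], mean_map)
  parc <- cohort$labelmap$parcels
  mask <- parc > 0
  statmap <- voxelwise_ttest(maps_A, maps_B, mask,
                             paste0(contrast[1], "vs", contrast[2]))
  feats <- t(vapply(feature_ids, function(id)
    as.numeric(stat_roi_features(get_maps(id), statmap, parc, alpha)),
    numeric(length(setdiff(unique(as.integer(parc)), 0L)))))
  colnames(feats) <- names(stat_roi_features(get_maps(feature_ids[1]),
                                             statmap, parc, alpha))
  rownames(feats) <- feature_ids
  list(features = feats, statmap = statmap, jacobians = jac_cache)
}
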