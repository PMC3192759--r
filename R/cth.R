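# Simplified cortical-thickness stage. The inner (WM/GM) boundary is
# linked to the outer (GM/CSF) boundary by streamlines of the Laplace
# equation solved over the grey-matter ribbon (inner boundary 0, outer
# boundary 1); thickness is the Euclidean distance between linked
# endpoints (the t-link definition), computed in each subject's native
# space. Node-level group t-tests define statistical ROIs whose mean
# thickness is the CTH feature, so the number of features depends on
# the contrast.

# shift an array by one voxel along axis, zero-filled
shift1 <- function(a, ax, dir) {
  d <- dim(a)
  out <- array(0, d)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  if (dir > 0) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
  else { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Solve Laplace's equation on the GM ribbon by Jacobi iteration.
# inner voxels fixed at 0, outer voxels fixed at 1.
laplace_ribbon <- function(gm, inner, outer, iters = 250, tol = 1e-4) {
  phi <- array(0, dim(gm))
  phi[outer] <- 1
  phi[gm] <- 0.5
  for (it in seq_len(iters)) {
    s <- shift1(phi, 1, 1) + shift1(phi, 1, -1) +
      shift1(phi, 2, 1) + shift1(phi, 2, -1) +
      shift1(phi, 3, 1) + shift1(phi, 3, -1)
    newphi <- s / 6
    delta <- max(abs(newphi[gm] - phi[gm]))
    phi[gm] <- newphi[gm]
    if (delta < tol) break
  }
  phi
}

#' Extract linked inner/outer cortical boundary nodes
#'
#' Inner nodes sit on the WM/GM interface (face midpoints); each is
#' linked to its GM/CSF correspondent by integrating the gradient of
#' the Laplace solution over the ribbon. Nodes whose streamline cannot
#' reach the outer boundary (ribbon holes) are flagged missing; more
#' than 50% flagged is an error. Parcel ids are inherited from the
#' nearest parcel label.
#'
#' @param labels a [labelmap3d()] with GM=2, interior labels
#'   (WM/hippocampi/amygdala) and CSF=1 (background counts as outer).
#' @param step_mm streamline integration step.
#' @param max_len_mm streamline length cap before flagging.
#' @param indicator_sigma Gaussian smoothing (voxels) applied to the
#'   boundary indicator functions before locating their 0.5-crossings;
#'   suppresses voxel staircase artefacts in the endpoint positions.
#' @return a `cortical_surface_pair`: list with `inner`, `outer`
#'   (n x 3 mm), `flagged`, `parcel`, `voxel` (0-based inner voxel
#'   coords), `spacing`.
#' @export
extract_surface_pair <- function(labels, step_mm = 0.3,
                                 max_len_mm = 12, indicator_sigma = 1) {
  lab <- labels$labels
  d <- dim(lab)
  gm <- lab == 2L
  if (!any(gm)) stop("extract_surface_pair: no grey-matter ribbon")
  interior <- array(lab %in% c(3L, 4L, 5L, 6L, 7L), d)
  outerm <- array(lab %in% c(0L, 1L), d)
  phi <- laplace_ribbon(gm, interior, outerm)
  phi[interior] <- 0; phi[outerm] <- 1
  # seed voxels: GM voxels with a face-adjacent interior voxel
  touch <- array(FALSE, d)
  for (ax in 1:3) for (dir in c(-1, 1))
    touch <- touch | (gm & shift1(interior + 0, ax, dir) > 0)
  vox <- which(touch, arr.ind = TRUE) - 1L
  n <- nrow(vox)
  sp <- labels$spacing
  seeds <- sweep(vox %*% diag(sp), 2L, labels$origin, "+")
  gphi <- gradient3(phi, sp)
  # march along the (normalized) gradient of phi from each seed until
  # the smooth indicator `chi` crosses 0.5; linear refinement of the
  # crossing gives sub-voxel endpoints on both boundaries
  march <- function(start, chi, sgn, pad) {
    pos <- start
    endp <- start
    done <- rep(FALSE, nrow(start))
    flagged <- rep(FALSE, nrow(start))
    chi_prev <- interp3(chi, world_to_vox(pos, sp, labels$origin),
                        "linear", pad)
    h <- step_mm
    for (stp in seq_len(ceiling(max_len_mm / h))) {
      act <- !done & !flagged
      if (!any(act)) break
      idx <- which(act)
      V <- world_to_vox(pos[idx, , drop = FALSE], sp, labels$origin)
      g <- cbind(interp3(gphi[[1]], V, "linear", 0),
                 interp3(gphi[[2]], V, "linear", 0),
                 interp3(gphi[[3]], V, "linear", 0))
      gn <- sqrt(rowSums(g^2))
      stuck <- gn < 1e-9
      flagged[idx[stuck]] <- TRUE
      mv <- idx[!stuck]
      if (length(mv) == 0) next
      gu <- sgn * g[!stuck, , drop = FALSE] / gn[!stuck]
      newpos <- pos[mv, , drop = FALSE] + h * gu
      ch <- interp3(chi, world_to_vox(newpos, sp, labels$origin),
                    "linear", pad)
      crossed <- ch >= 0.5
      if (any(crossed)) {
        ci <- mv[crossed]
        frac <- (0.5 - chi_prev[ci]) / (ch[crossed] - chi_prev[ci])
        frac[!is.finite(frac)] <- 0.5
        frac <- pmin(pmax(frac, 0), 1)
        endp[ci, ] <- pos[ci, , drop = FALSE] +
          frac * h * gu[crossed, , drop = FALSE]
        done[ci] <- TRUE
      }
      keep <- mv[!crossed]
      pos[keep, ] <- newpos[!crossed, , drop = FALSE]
      chi_prev[keep] <- ch[!crossed]
    }
    flagged[!done] <- TRUE
    list(endp = endp, flagged = flagged)
  }
  chi_in <- gauss_smooth3(interior + 0, indicator_sigma)
  chi_out <- gauss_smooth3(outerm + 0, indicator_sigma)
  dn <- march(seeds, chi_in, -1, 0)    # down-gradient to WM surface
  up <- march(seeds, chi_out, +1, 1)   # up-gradient to CSF surface
  inner <- dn$endp
  out <- up$endp
  flagged <- dn$flagged | up$flagged
  if (mean(flagged) > 0.5)
    stop("extract_surface_pair: ", round(100 * mean(flagged)),
         "% of nodes could not reach the outer boundary (ribbon holes)")
  parcel <- rep(NA_integer_, n)
  if (!is.null(labels$parcels))
    parcel <- as.integer(interp3(labels$parcels,
                                 vox + 0, "nearest", 0))
  structure(list(inner = inner, outer = out, flagged = flagged,
                 parcel = parcel, voxel = vox, spacing = sp,
                 origin = labels$origin),
            class = "cortical_surface_pair")
}

#' t-link cortical thickness
#'
#' Euclidean distance between linked inner and outer nodes, in native
#' space; flagged nodes yield NA.
#'
#' @param pair a `cortical_surface_pair`.
#' @return numeric vector of per-node thickness in mm.
#' @export
tlink_thickness <- function(pair) {
  th <- sqrt(rowSums((pair$outer - pair$inner)^2))
  th[pair$flagged] <- NA_real_
  th
}

# node adjacency: nodes whose source voxels are 26-neighbours
surface_adjacency <- function(pair) {
  vhash <- function(v) v[, 1] + 4096 * (v[, 2] + 4096 * v[, 3])
  d_hash <- vhash(pair$voxel)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  ii <- jj <- integer(0)
  for (o in seq_len(nrow(offs))) {
    j <- match(vhash(sweep(pair$voxel, 2L, offs[o, ], "+")), d_hash)
    keep <- !is.na(j)
    ii <- c(ii, which(keep)); jj <- c(jj, j[keep])
  }
  list(i = ii, j = jj)
}

#' Heat-kernel smoothing of node values on the surface graph
#'
#' Explicit diffusion with the unit-weight graph Laplacian over the
#' 26-neighbourhood adjacency of inner-surface voxels, run long enough
#' that the accumulated per-axis kernel variance is
#' (fwhm / sqrt(8 log 2))^2. The symmetric Laplacian preserves the
#' global mean exactly; fwhm = 0 is the identity.
#'
#' @param pair a `cortical_surface_pair`.
#' @param values per-node values (NA allowed; NAs are held out and
#'   returned unchanged).
#' @param fwhm_mm kernel full width at half maximum in mm.
#' @return smoothed values.
#' @export
smooth_thickness <- function(pair, values, fwhm_mm = 20) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(values)
  ok <- !is.na(values)
  adj <- surface_adjacency(pair)
  keep <- ok[adj$i] & ok[adj$j]
  map <- cumsum(ok)
  i <- map[adj$i[keep]]; j <- map[adj$j[keep]]
  v <- values[ok]
  x <- pair$inner[ok, , drop = FALSE]
  n <- length(v)
  deg <- tabulate(i, n)
  if (max(deg) == 0) return(values)
  tau <- 0.9 / max(deg)
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  # per-step added variance along one tangential axis
  edge_d2 <- rowSums((x[i, , drop = FALSE] - x[j, , drop = FALSE])^2)
  v1 <- tau * sum(edge_d2) / n / 2
  sigma2 <- (fwhm_mm / sqrt(8 * log(2)))^2
  m <- max(1L, round(sigma2 / v1))
  for (s in seq_len(m)) {
    v <- v + tau * (as.numeric(W %*% v) - deg * v)
  }
  out <- values
  out[ok] <- v
  out
}

# map a subject's node thickness onto the template's reference nodes
# through an affine subject->template transform; returns a vector over
# reference nodes (NA where nothing maps)
map_to_reference <- function(pair, thickness, ref_pair, aff) {
  tp <- apply_affine(aff, pair$inner)
  vv <- round(world_to_vox(tp, ref_pair$spacing, ref_pair$origin))
  hash <- function(v) v[, 1] + 4096 * (v[, 2] + 4096 * v[, 3])
  hv <- hash(vv)
  ok <- !is.na(thickness)
  sums <- tapply(thickness[ok], hv[ok], mean)
  ref_h <- hash(ref_pair$voxel)
  out <- as.numeric(sums[as.character(ref_h)])
  # fill small gaps from the 26-neighbourhood
  if (anyNA(out)) {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    miss <- which(is.na(out))
    for (mi in miss) {
      nh <- sweep(offs, 2L, as.numeric(ref_pair$voxel[mi, ]), "+")
      vals <- as.numeric(sums[as.character(hash(nh))])
      if (any(!is.na(vals))) out[mi] <- mean(vals, na.rm = TRUE)
    }
  }
  out
}

#' Flag a subject's cortical thickness as missing
#'
#' Marks the subject so downstream feature assembly yields missing CTH
#' entries (never silently zero, never imputed here).
#'
#' @param subject a `subject_record`.
#' @return the updated record.
#' @export
flag_missing_cth <- function(subject) {
  subject$cth_missing <- TRUE
  if (!is.null(subject$features$CTH))
    subject$features$CTH[] <- NA_real_
  subject
}

#' Statistical-ROI cortical-thickness features
#'
#' Node-wise two-sample t-tests between the contrast groups over the
#' ROI-source subjects select nodes with p < alpha that are thinner in
#' the more-affected group; each parcel containing at least one
#' selected node contributes one feature: the subject's mean thickness
#' over that parcel's selected nodes. With `alpha >= 1` every node is
#' selected (degenerate threshold), making features plain parcel
#' means.
#'
#' @param thick matrix (subjects x reference nodes) of smoothed
#'   thickness, NA allowed.
#' @param groups factor/character group per row of `thick`.
#' @param node_parcels parcel id per reference node.
#' @param contrast character pair, less-affected group first.
#' @param alpha node significance threshold.
#' @param roi_rows rows (ids or indices) used for the statistics; the
#'   returned features still cover all rows.
#' @param min_coverage minimum fraction of (non-flagged) subjects a
#'   node must be observed in to be eligible, so every feature is
#'   computable cohort-wide.
#' @return matrix (subjects x selected parcels), column names
#'   "CTH_p<parcel>"; attribute "nodes" lists selected node indices
#'   per parcel.
#' @export
cth_stat_roi_features <- function(thick, groups, node_parcels, contrast,
                                  alpha = 0.05,
                                  roi_rows = seq_len(nrow(thick)),
                                  min_coverage = 0.8) {
  if (is.character(roi_rows)) roi_rows <- match(roi_rows, rownames(thick))
  TA <- thick[roi_rows[groups[roi_rows] == contrast[1]], , drop = FALSE]
  TB <- thick[roi_rows[groups[roi_rows] == contrast[2]], , drop = FALSE]
  nn <- ncol(thick)
  present <- rowSums(!is.na(thick)) > 0     # flagged subjects excluded
  covered <- colMeans(!is.na(thick[present, , drop = FALSE])) >=
    min_coverage
  if (alpha >= 1) {
    sel_nodes <- covered
  } else {
    nA <- colSums(!is.na(TA)); nB <- colSums(!is.na(TB))
    mA <- colMeans(TA, na.rm = TRUE); mB <- colMeans(TB, na.rm = TRUE)
    vA <- apply(TA, 2, stats::var, na.rm = TRUE)
    vB <- apply(TB, 2, stats::var, na.rm = TRUE)
    se2 <- vA / nA + vB / nB
    tv <- (mA - mB) / sqrt(se2)
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    pv <- 2 * stats::pt(-abs(tv), df)
    sel_nodes <- !is.na(pv) & pv < alpha & mA > mB & nA >= 2 & nB >= 2 &
      covered
  }
  if (!any(sel_nodes))
    stop("cth_stat_roi_features: no significant nodes; ",
         "consider a larger alpha")
  parcels <- sort(unique(node_parcels[sel_nodes]))
  parcels <- parcels[!is.na(parcels) & parcels > 0]
  feats <- vapply(parcels, function(pc) {
    nodes <- which(sel_nodes & node_parcels == pc)
    rowMeans(thick[, nodes, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(thick)))
  feats <- matrix(feats, nrow = nrow(thick),
                  dimnames = list(rownames(thick),
                                  paste0("CTH_p", parcels - 100L)))
  feats[is.nan(feats)] <- NA_real_
  attr(feats, "nodes") <- lapply(parcels, function(pc)
    which(sel_nodes & node_parcels == pc))
  feats
}

#' Reference-node thickness table for a cohort
#'
#' Extracts each subject's surface pair in native space, measures and
#' smooths t-link thickness, and maps it onto the template's reference
#' nodes through an affine subject->template alignment. Subjects
#' flagged CTH-missing get an all-NA row.
#'
#' @param cohort a `cohort`.
#' @param ids subjects to process (default all).
#' @param fwhm_mm surface smoothing kernel (default 20).
#' @param use_affine if FALSE, assume subjects are already in template
#'   space (phantom subjects are generated on the template grid).
#' @return list with `thick` (matrix subjects x reference nodes),
#'   `ref_pair`, `node_parcels`.
#' @export
cth_node_table <- function(cohort, ids = cohort$manifest$id,
                           fwhm_mm = 20, use_affine = FALSE) {
  ref_pair <- extract_surface_pair(cohort$labelmap)
  nref <- nrow(ref_pair$inner)
  thick <- matrix(NA_real_, length(ids), nref,
                  dimnames = list(ids, NULL))
  for (id in ids) {
    s <- cohort$subjects[[match(id, cohort$manifest$id)]]
    if (isTRUE(s$cth_missing)) next
    pr <- tryCatch(extract_surface_pair(s$labels), error = function(e) NULL)
    if (is.null(pr)) next
    th <- smooth_thickness(pr, tlink_thickness(pr), fwhm_mm)
    aff <- if (use_affine)
      affine_align(cohort$template$image, s$image, iters = 40)
    else affine3d()
    thick[id, ] <- map_to_reference(pr, th, ref_pair, aff)
  }
  list(thick = thick, ref_pair = ref_pair,
       node_parcels = ref_pair$parcel)
}
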