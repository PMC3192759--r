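# Spatial transforms. The total transform of a deformation field is
#   T(x) = A x + t + u(x)
# mapping FIXED-image world coordinates to MOVING-image world
# coordinates (pull-back convention): warping samples the moving image
# at T(x), and the Jacobian determinant det(dT/dx) > 1 means the fixed
# template locally expands into the subject. u is a cubic B-spline over
# a control-point lattice covering the fixed domain plus one boundary
# ring.

#' Affine transform
#'
#' @param A 3x3 linear part (must be invertible).
#' @param t length-3 translation in mm.
#' @return object of class `affine3d`.
#' @export
affine3d <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  if (abs(det(A)) < 1e-8) stop("affine3d: linear part is singular")
  structure(list(A = A, t = as.numeric(t)), class = "affine3d")
}

#' @rdname affine3d
#' @param aff an `affine3d`.
#' @param pts n x 3 matrix of world coordinates.
#' @export
apply_affine <- function(aff, pts) {
  sweep(pts %*% t(aff$A), 2L, aff$t, "+")
}

#' @rdname affine3d
#' @export
affine_inverse <- function(aff) {
  Ai <- solve(aff$A)
  affine3d(Ai, -as.vector(Ai %*% aff$t))
}

# Cubic B-spline kernel and its derivative.
bspline_b3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}
bspline_b3d <- function(t) {
  a <- abs(t)
  s <- sign(t)
  ifelse(a < 1, s * (-12 * a + 9 * a^2) / 6,
         ifelse(a < 2, s * (-3 * (2 - a)^2) / 6, 0))
}

#' B-spline free-form deformation field
#'
#' @param domain geometry of the fixed image: a list with `dim`,
#'   `spacing`, `origin`, or an [image3d()] from which these are taken.
#' @param cp_spacing_mm control-point spacing in mm (scalar or per axis).
#' @param cp control-point displacement array (nc1 x nc2 x nc3 x 3, mm);
#'   zeros if NULL.
#' @param affine `affine3d` component applied before the B-spline term.
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(domain, cp_spacing_mm, cp = NULL,
                              affine = affine3d()) {
  if (inherits(domain, "image3d"))
    domain <- list(dim = dim(domain$data), spacing = domain$spacing,
                   origin = domain$origin)
  cs <- rep_len(as.numeric(cp_spacing_mm), 3L)
  if (any(cs < 2 * domain$spacing))
    stop("deformation_field: control spacing must be >= 2 voxels")
  extent <- (domain$dim - 1) * domain$spacing
  nc <- ceiling(extent / cs) + 3L
  cp_origin <- domain$origin - cs
  if (is.null(cp)) cp <- array(0, c(nc, 3L))
  stopifnot(identical(dim(cp), as.integer(c(nc, 3L))))
  if (any(!is.finite(cp))) stop("deformation_field: non-finite displacements")
  structure(list(domain = domain, cp = cp, cp_spacing = cs,
                 cp_origin = cp_origin, affine = affine),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat("<deformation_field> control grid ",
      paste(dim(x$cp)[1:3], collapse = "x"), " @ ",
      paste(signif(x$cp_spacing, 3), collapse = "x"), " mm, max |u| ",
      signif(max(abs(x$cp)), 3), " mm\n", sep = "")
  invisible(x)
}

# Per-axis B-spline basis matrix evaluated at world coordinates xs.
bspline_basis_1d <- function(xs, origin, spacing, nc, deriv = FALSE) {
  tt <- outer((xs - origin) / spacing, seq_len(nc) - 1, "-")
  B <- if (deriv) bspline_b3d(tt) / spacing else bspline_b3(tt)
  matrix(B, length(xs), nc)
}

# Basis matrices of a field for an arbitrary evaluation geometry.
field_basis <- function(field, geom, deriv = FALSE) {
  nc <- dim(field$cp)[1:3]
  lapply(1:3, function(ax) {
    xs <- geom$origin[ax] + (seq_len(geom$dim[ax]) - 1) * geom$spacing[ax]
    bspline_basis_1d(xs, field$cp_origin[ax], field$cp_spacing[ax], nc[ax],
                     deriv = deriv)
  })
}

# Displacement components on a full grid (list of 3 arrays) via
# separable tensor contraction; Bx/By/Bz from field_basis().
disp_on_grid <- function(field, Bx, By, Bz) {
  lapply(1:3, function(a)
    ttm(ttm(ttm(field$cp[, , , a, drop = FALSE][, , , 1], Bx, 1), By, 2), Bz, 3))
}

# Displacement at arbitrary world points (n x 3), direct 64-term sum.
displacement_at <- function(field, pts) {
  nc <- dim(field$cp)[1:3]
  tt <- sweep(sweep(pts, 2L, field$cp_origin, "-"), 2L,
              field$cp_spacing, "/")
  i0 <- floor(tt)
  out <- matrix(0, nrow(pts), 3L)
  cpm <- matrix(field$cp, prod(nc), 3L)
  for (ox in -1:2) for (oy in -1:2) for (oz in -1:2) {
    cx <- pmin(pmax(i0[, 1] + ox, 0), nc[1] - 1)
    cy <- pmin(pmax(i0[, 2] + oy, 0), nc[2] - 1)
    cz <- pmin(pmax(i0[, 3] + oz, 0), nc[3] - 1)
    w <- bspline_b3(tt[, 1] - (i0[, 1] + ox)) *
      bspline_b3(tt[, 2] - (i0[, 2] + oy)) *
      bspline_b3(tt[, 3] - (i0[, 3] + oz))
    idx <- 1 + cx + nc[1] * (cy + nc[2] * cz)
    out <- out + w * cpm[idx, , drop = FALSE]
  }
  out
}

# Total transform T(x) at arbitrary world points.
transform_points <- function(field, pts) {
  apply_affine(field$affine, pts) + displacement_at(field, pts)
}

# Total transform on the full domain grid (fast separable path).
transform_grid <- function(field, geom = field$domain) {
  X <- sweep(grid_coords(geom$dim) %*% diag(geom$spacing), 2L,
             geom$origin, "+")
  B <- field_basis(field, geom)
  U <- disp_on_grid(field, B[[1]], B[[2]], B[[3]])
  apply_affine(field$affine, X) + cbind(as.vector(U[[1]]),
                                        as.vector(U[[2]]),
                                        as.vector(U[[3]]))
}

#' Warp an image through a deformation field
#'
#' Pull-back resampling: output voxel x takes the moving-image value at
#' T(x). Linear interpolation by default; nearest-neighbour for label
#' grids. Out-of-domain samples take `pad`.
#'
#' @param image moving [image3d()] (or `labelmap3d` with
#'   `interpolation = "nearest"`).
#' @param field `deformation_field` whose domain defines the output grid.
#' @param interpolation "linear" or "nearest".
#' @param pad padding value for samples outside the moving image.
#' @return an [image3d()] (or label array for labelmap input) on the
#'   field's domain grid.
#' @export
warp <- function(image, field, interpolation = c("linear", "nearest"),
                 pad = 0) {
  interpolation <- match.arg(interpolation)
  P <- transform_grid(field)
  if (inherits(image, "labelmap3d")) {
    V <- world_to_vox(P, image$spacing, image$origin)
    lab <- array(as.integer(interp3(image$labels, V, "nearest", pad)),
                 field$domain$dim)
    par <- if (!is.null(image$parcels))
      array(as.integer(interp3(image$parcels, V, "nearest", 0)),
            field$domain$dim)
    return(labelmap3d(lab, par, image$legend,
                      spacing = field$domain$spacing,
                      origin = field$domain$origin))
  }
  V <- world_to_vox(P, image$spacing, image$origin)
  image3d(array(interp3(image$data, V, interpolation, pad),
                field$domain$dim),
          spacing = field$domain$spacing, origin = field$domain$origin)
}

#' Jacobian-determinant map of a deformation field
#'
#' Determinant of the analytic spatial gradient of the total transform
#' (affine plus B-spline displacement), evaluated at the voxel centres
#' of the field's domain. Equals 1 everywhere for the identity
#' transform; values below 1 mark local contraction of the fixed
#' template into the subject (atrophy under the convention used here).
#'
#' @param field a `deformation_field`.
#' @return an [image3d()] of determinant values.
#' @export
jacobian_map <- function(field) {
  geom <- field$domain
  B <- field_basis(field, geom, deriv = FALSE)
  D <- field_basis(field, geom, deriv = TRUE)
  J <- vector("list", 9L)   # dT_a/dx_b, column-major a + 3*(b-1)
  for (a in 1:3) {
    cpa <- field$cp[, , , a, drop = FALSE][, , , 1]
    for (b in 1:3) {
      M <- lapply(1:3, function(ax) if (ax == b) D[[ax]] else B[[ax]])
      du <- ttm(ttm(ttm(cpa, M[[1]], 1), M[[2]], 2), M[[3]], 3)
      J[[a + 3 * (b - 1)]] <- field$affine$A[a, b] + du
    }
  }
  detv <- J[[1]] * (J[[5]] * J[[9]] - J[[8]] * J[[6]]) -
    J[[4]] * (J[[2]] * J[[9]] - J[[8]] * J[[3]]) +
    J[[7]] * (J[[2]] * J[[6]] - J[[5]] * J[[3]])
  image3d(detv, spacing = geom$spacing, origin = geom$origin)
}

# Smooth random field for synthesis: control displacements drawn
# N(0, amp_mm) and lightly smoothed over the control lattice.
random_field <- function(domain, cp_spacing_mm, amp_mm, seed = NULL,
                         affine = affine3d()) {
  if (!is.null(seed)) set.seed(seed)
  f <- deformation_field(domain, cp_spacing_mm, affine = affine)
  nc <- dim(f$cp)[1:3]
  cp <- array(stats::rnorm(prod(nc) * 3, sd = amp_mm), c(nc, 3L))
  for (a in 1:3) cp[, , , a] <- gauss_smooth3(cp[, , , a], 0.6)
  # zero displacement at the boundary ring so the head stays in frame
  cp[c(1, nc[1]), , , ] <- 0; cp[, c(1, nc[2]), , ] <- 0
  cp[, , c(1, nc[3]), ] <- 0
  f$cp <- cp
  f
}
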