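#' 3D scalar image
#'
#' The currency of all image stages: a dense 3D array with voxel spacing
#' and a world origin. Voxel indices are 0-based in all coordinate
#' computations; world mm = origin + index * spacing.
#'
#' @param data 3D numeric array, all dims >= 8.
#' @param spacing per-axis voxel size in mm (positive).
#' @param origin world coordinate of voxel (0,0,0) in mm.
#' @return an object of class `image3d`.
#' @export
image3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(dim(data) < 8L))
    stop("image3d: all dimensions must be >= 8, got ",
         paste(dim(data), collapse = "x"))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("image3d: spacing must be positive")
  if (any(!is.finite(data))) stop("image3d: data contains non-finite values")
  structure(list(data = data, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "image3d")
}

#' @export
print.image3d <- function(x, ...) {
  cat("<image3d> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = "x"),
      " mm, intensity range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.image3d <- function(x) dim(x$data)

#' Label map aligned to an image
#'
#' Holds an anatomical label grid (background/CSF/GM/WM/hippocampi/
#' amygdala region) and a parallel parcel grid partitioning brain tissue
#' into regions for ROI-wise features. Both grids share the image
#' geometry; the legend names every label that occurs.
#'
#' @param labels 3D integer array of anatomical labels.
#' @param parcels 3D integer array of parcel ids (0 outside tissue), or
#'   NULL.
#' @param legend named integer vector mapping label names to codes.
#' @param spacing,origin geometry, as in [image3d()].
#' @return an object of class `labelmap3d`.
#' @export
labelmap3d <- function(labels, parcels = NULL, legend,
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (!is.null(parcels)) stopifnot(identical(dim(parcels), dim(labels)))
  present <- unique(as.integer(labels))
  if (!all(present %in% legend))
    stop("labelmap3d: labels ", paste(setdiff(present, legend), collapse = ","),
         " missing from legend")
  structure(list(labels = labels, parcels = parcels, legend = legend,
                 spacing = rep_len(as.numeric(spacing), 3L),
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "labelmap3d")
}

#' @export
print.labelmap3d <- function(x, ...) {
  cat("<labelmap3d> ", paste(dim(x$labels), collapse = "x"),
      " voxels, ", length(x$legend), " legend entries",
      if (!is.null(x$parcels)) paste0(", ",
        length(setdiff(unique(as.integer(x$parcels)), 0L)), " parcels"),
      "\n", sep = "")
  invisible(x)
}

# World mm coordinates of every voxel centre, n x 3, array order.
world_grid <- function(img) {
  P <- grid_coords(dim(img$data))
  sweep(P %*% diag(img$spacing), 2L, img$origin, "+")
}

# world mm -> 0-based voxel coords for a given geometry
world_to_vox <- function(pts, spacing, origin) {
  sweep(pts, 2L, origin, "-") %*% diag(1 / spacing)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti preserving voxel spacing. `write_image`
#' accepts an [image3d()] or a `labelmap3d` (labels grid written).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param x object to write.
#' @return `read_image` returns an [image3d()].
#' @export
read_image <- function(path) {
  nii <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(nii)[1:3]
  image3d(array(as.numeric(nii), dim = dim(nii)[1:3]), spacing = sp)
}

#' @rdname read_image
#' @export
write_image <- function(x, path) {
  arr <- if (inherits(x, "labelmap3d")) x$labels else x$data
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- x$spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}
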