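# Low-level dense-array helpers shared by the phantom generator, the
# registration engine and the feature extractors. Everything operates on
# plain 3D double arrays; points are 0-based voxel coordinates unless a
# function says world mm.

#' Tensor-times-matrix along one mode
#'
#' Contracts a dense array `A` with matrix `M` along dimension `mode`:
#' the result has `nrow(M)` entries along that mode. This is the work
#' horse behind separable B-spline evaluation, Gaussian smoothing and
#' block downsampling.
#'
#' @param A numeric array.
#' @param M matrix with `ncol(M) == dim(A)[mode]`.
#' @param mode dimension index to contract.
#' @return array with `dim(A)[mode]` replaced by `nrow(M)`.
#' @keywords internal
ttm <- function(A, M, mode) {
  d <- dim(A)
  nd <- length(d)
  perm <- c(mode, setdiff(seq_len(nd), mode))
  Ap <- aperm(A, perm)
  dim(Ap) <- c(d[mode], prod(d[-mode]))
  R <- M %*% Ap
  dim(R) <- c(nrow(M), d[perm[-1]])
  aperm(R, order(perm))
}

#' Trilinear / nearest-neighbour sampling of a 3D array
#'
#' @param arr 3D array.
#' @param pts n x 3 matrix of 0-based voxel coordinates.
#' @param method "linear" or "nearest".
#' @param pad value returned for points outside the array domain.
#' @return numeric vector of length n.
#' @keywords internal
interp3 <- function(arr, pts, method = c("linear", "nearest"), pad = 0) {
  method <- match.arg(method)
  d <- dim(arr)
  x <- pts[, 1L]; y <- pts[, 2L]; z <- pts[, 3L]
  valid <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  out <- rep(pad, length(x))
  if (!any(valid)) return(out)
  x <- x[valid]; y <- y[valid]; z <- z[valid]
  if (method == "nearest") {
    xi <- pmin(pmax(round(x), 0), d[1] - 1)
    yi <- pmin(pmax(round(y), 0), d[2] - 1)
    zi <- pmin(pmax(round(z), 0), d[3] - 1)
    out[valid] <- arr[1 + xi + d[1] * (yi + d[2] * zi)]
    return(out)
  }
  xi <- pmin(floor(x), d[1] - 2); yi <- pmin(floor(y), d[2] - 2)
  zi <- pmin(floor(z), d[3] - 2)
  xi <- pmax(xi, 0); yi <- pmax(yi, 0); zi <- pmax(zi, 0)
  fx <- x - xi; fy <- y - yi; fz <- z - zi
  i000 <- 1 + xi + d[1] * (yi + d[2] * zi)
  dx <- 1L; dy <- d[1]; dz <- d[1] * d[2]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * arr[i000] +
    fx * (1 - fy) * (1 - fz) * arr[i000 + dx] +
    (1 - fx) * fy * (1 - fz) * arr[i000 + dy] +
    fx * fy * (1 - fz) * arr[i000 + dx + dy] +
    (1 - fx) * (1 - fy) * fz * arr[i000 + dz] +
    fx * (1 - fy) * fz * arr[i000 + dx + dz] +
    (1 - fx) * fy * fz * arr[i000 + dy + dz] +
    fx * fy * fz * arr[i000 + dx + dy + dz]
  out[valid] <- v
  out
}

# Trilinear value and its exact spatial derivative at arbitrary points
# (derivatives in value per voxel along each axis; piecewise constant
# per cell, consistent with the interpolated cost surface). Returns an
# n x 4 matrix (v, dx, dy, dz); out-of-domain rows are (pad, 0, 0, 0).
interp3_wgrad <- function(arr, pts, pad = 0) {
  d <- dim(arr)
  x <- pts[, 1L]; y <- pts[, 2L]; z <- pts[, 3L]
  valid <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  out <- matrix(0, length(x), 4L)
  out[, 1L] <- pad
  if (!any(valid)) return(out)
  x <- x[valid]; y <- y[valid]; z <- z[valid]
  xi <- pmax(pmin(floor(x), d[1] - 2), 0)
  yi <- pmax(pmin(floor(y), d[2] - 2), 0)
  zi <- pmax(pmin(floor(z), d[3] - 2), 0)
  fx <- x - xi; fy <- y - yi; fz <- z - zi
  i000 <- 1 + xi + d[1] * (yi + d[2] * zi)
  dx <- 1L; dy <- d[1]; dz <- d[1] * d[2]
  c000 <- arr[i000];           c100 <- arr[i000 + dx]
  c010 <- arr[i000 + dy];      c110 <- arr[i000 + dx + dy]
  c001 <- arr[i000 + dz];      c101 <- arr[i000 + dx + dz]
  c011 <- arr[i000 + dy + dz]; c111 <- arr[i000 + dx + dy + dz]
  # interpolate along x first
  a00 <- c000 + fx * (c100 - c000); a10 <- c010 + fx * (c110 - c010)
  a01 <- c001 + fx * (c101 - c001); a11 <- c011 + fx * (c111 - c011)
  g00 <- c100 - c000; g10 <- c110 - c010
  g01 <- c101 - c001; g11 <- c111 - c011
  b0 <- a00 + fy * (a10 - a00); b1 <- a01 + fy * (a11 - a01)
  gb0 <- g00 + fy * (g10 - g00); gb1 <- g01 + fy * (g11 - g01)
  v <- b0 + fz * (b1 - b0)
  gx <- gb0 + fz * (gb1 - gb0)
  gy <- (a10 - a00) + fz * ((a11 - a01) - (a10 - a00))
  gz <- b1 - b0
  out[valid, 1L] <- v
  out[valid, 2L] <- gx
  out[valid, 3L] <- gy
  out[valid, 4L] <- gz
  out
}

# Central-difference spatial gradient, units value per mm; one-sided at
# the faces. Returns a list of three arrays.
gradient3 <- function(arr, spacing) {
  d <- dim(arr)
  g <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    D <- matrix(0, n, n)
    if (n >= 3) {
      idx <- 2:(n - 1)
      D[cbind(idx, idx + 1L)] <- 0.5
      D[cbind(idx, idx - 1L)] <- -0.5
    }
    D[1, 1:2] <- c(-1, 1)
    D[n, (n - 1):n] <- c(-1, 1)
    g[[ax]] <- ttm(arr, D, ax) / spacing[ax]
  }
  g
}

# 1D Gaussian convolution matrix with reflecting boundaries.
gauss_mat <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + seq(-r, r)
    idx <- ifelse(idx < 1, 2 - idx, idx)         # reflect low
    idx <- ifelse(idx > n, 2 * n - idx, idx)     # reflect high
    for (j in seq_along(idx)) M[i, idx[j]] <- M[i, idx[j]] + k[j]
  }
  M
}

# Separable Gaussian smoothing of a 3D array, sigma per axis in voxels.
gauss_smooth3 <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) arr <- ttm(arr, gauss_mat(d[ax], sigma_vox[ax]), ax)
  }
  arr
}

# Factor-2 block-mean downsampling matrix (drops a trailing odd sample).
downsample_mat <- function(n) {
  m <- n %/% 2L
  M <- matrix(0, m, n)
  M[cbind(seq_len(m), 2L * seq_len(m) - 1L)] <- 0.5
  M[cbind(seq_len(m), 2L * seq_len(m))] <- 0.5
  M
}

# Binary dilation of a logical 3D array by `steps` 6-connected layers.
dilate3 <- function(mask, steps = 1L) {
  d <- dim(mask)
  m <- mask
  for (s in seq_len(steps)) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    m <- out
  }
  m
}

# n x 3 matrix of 0-based voxel coordinates for a full grid of dims d,
# in column-major (R array) order.
grid_coords <- function(d) {
  cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
}
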