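# Intensity-based registration: affine pre-alignment followed by cubic
# B-spline free-form deformation, both optimized multi-resolution. The
# default similarity is negative normalized cross-correlation (robust
# to the smooth multiplicative bias fields the phantom carries); sum of
# squared differences is available. The optimizer is plain gradient
# descent with backtracking step halving -- only the recovery
# properties matter, not equivalence with any particular registration
# package.

# Local (windowed) normalized cross-correlation: robust to smooth
# multiplicative bias fields, which distort the global-NCC optimum.
# Box-window statistics via separable banded matrices; the gradient
# follows the standard windowed-CC derivation (per-voxel local means,
# mean-chain terms dropped).
make_lncc <- function(fdata, radius = 3L) {
  d <- dim(fdata)
  Bm <- lapply(d, function(n) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - radius):min(n, i + radius)
      M[i, j] <- 1
    }
    M
  })
  boxs <- function(a) ttm(ttm(ttm(a, Bm[[1]], 1), Bm[[2]], 2), Bm[[3]], 3)
  cnt <- boxs(array(1, d))
  fb <- boxs(fdata) / cnt
  cf <- fdata - fb
  Bf <- boxs(cf^2)
  list(boxs = boxs, cnt = cnt, cf = cf, Bf = Bf, d = d,
       eps = 1e-5 * mean(Bf))
}

lncc_cost <- function(st, w) {
  w <- array(w, st$d)
  wb <- st$boxs(w) / st$cnt
  cw <- w - wb
  A <- st$boxs(st$cf * cw)
  Cw <- st$boxs(cw^2)
  denom <- st$Bf * Cw
  valid <- st$Bf > st$eps & Cw > 1e-5 * mean(Cw)
  n <- length(w)
  val <- array(0, st$d)
  val[valid] <- A[valid]^2 / denom[valid]
  T1 <- array(0, st$d); T2 <- array(0, st$d)
  T1[valid] <- A[valid] / denom[valid]
  T2[valid] <- A[valid]^2 / (denom[valid] * Cw[valid])
  dw <- -(2 / n) * (st$boxs(T1) * st$cf - st$boxs(T2) * cw)
  list(cost = -sum(val) / n, dw = as.vector(dw))
}

# similarity value and d(cost)/d(warped intensity) vector
sim_cost <- function(f, w, metric) {
  n <- length(f)
  if (metric == "ssd") {
    r <- w - f
    return(list(cost = sum(r^2) / n, dw = 2 * r / n))
  }
  fc <- f - mean(f)
  wc <- w - mean(w)
  fn <- sqrt(sum(fc^2)); wn <- sqrt(sum(wc^2))
  if (wn < 1e-12 || fn < 1e-12)
    return(list(cost = 0, dw = rep(0, n)))
  ncc <- sum(fc * wc) / (fn * wn)
  dw <- -(fc / (fn * wn) - ncc * wc / wn^2)
  list(cost = -ncc, dw = dw)
}

img_geom <- function(img) list(dim = dim(img$data), spacing = img$spacing,
                               origin = img$origin)

downsample_image <- function(img) {
  A <- lapply(dim(img$data), downsample_mat)
  image3d(ttm(ttm(ttm(img$data, A[[1]], 1), A[[2]], 2), A[[3]], 3),
          spacing = 2 * img$spacing, origin = img$origin + img$spacing / 2)
}

image_pyramid <- function(img, levels) {
  py <- vector("list", levels)
  py[[levels]] <- img
  if (levels > 1) for (l in (levels - 1):1) py[[l]] <- downsample_image(py[[l + 1]])
  py
}

# robust background estimate: median intensity of the six faces
border_value <- function(img) {
  d <- dim(img$data)
  stats::median(c(img$data[c(1, d[1]), , ], img$data[, c(1, d[2]), ],
                  img$data[, , c(1, d[3])]))
}

com_mm <- function(img) {
  w <- img$data - min(img$data)
  s <- sum(w)
  if (s <= 0) return(img$origin + (dim(img$data) - 1) / 2 * img$spacing)
  P <- world_grid(img)
  colSums(P * as.vector(w)) / s
}

#' Affine image alignment
#'
#' Estimates the affine transform (fixed world -> moving world)
#' minimizing the chosen dissimilarity, by multi-resolution quasi-Newton
#' descent from a centre-of-mass initialization. The best-cost trace is
#' attached as attribute `"trace"` and is non-increasing.
#'
#' @param moving,fixed [image3d()] objects.
#' @param metric "ncc" (negative normalized cross-correlation, default)
#'   or "ssd".
#' @param iters optimizer iterations per resolution level.
#' @param levels number of resolution levels.
#' @param init optional initial [affine3d()] (default: centre-of-mass
#'   translation).
#' @return an [affine3d()].
#' @export
affine_align <- function(moving, fixed, metric = c("ncc", "ssd"),
                         iters = 60, levels = 2, init = NULL) {
  metric <- match.arg(metric)
  t0 <- if (is.null(init)) com_mm(moving) - com_mm(fixed) else init$t
  # overlap check: does the translated fixed domain intersect moving?
  lo_f <- fixed$origin + t0; hi_f <- lo_f + (dim(fixed$data) - 1) * fixed$spacing
  lo_m <- moving$origin; hi_m <- lo_m + (dim(moving$data) - 1) * moving$spacing
  if (any(hi_f < lo_m) || any(lo_f > hi_m))
    stop("affine_align: images do not overlap after centre-of-mass init")
  pad <- border_value(moving)
  par <- c(t0, if (is.null(init)) rep(0, 9) else as.vector(init$A - diag(3)))
  trace <- numeric(0)
  fp <- image_pyramid(fixed, levels)
  mp <- image_pyramid(moving, levels)
  for (l in seq_len(levels)) {
    fx <- fp[[l]]; mv <- mp[[l]]
    X <- world_grid(fx)
    f <- as.vector(fx$data)
    eval_p <- function(p) {
      A <- diag(3) + matrix(p[4:12], 3, 3)
      P <- sweep(X %*% t(A), 2L, p[1:3], "+")
      V <- world_to_vox(P, mv$spacing, mv$origin)
      vg <- interp3_wgrad(mv$data, V, pad)
      c(sim_cost(f, vg[, 1], metric), list(vg = vg))
    }
    cache <- new.env()
    cost_fn <- function(p) {
      e <- eval_p(p)
      assign("last", list(p = p, e = e), envir = cache)
      trace <<- c(trace, e$cost)
      e$cost
    }
    grad_fn <- function(p) {
      last <- get0("last", envir = cache)
      e <- if (!is.null(last) && identical(last$p, p)) last$e else eval_p(p)
      g <- numeric(12)
      for (a in 1:3) {
        ga <- e$dw * e$vg[, 1 + a] / mv$spacing[a]
        g[a] <- sum(ga)
        g[3 + a + 3 * (0:2)] <- colSums(ga * X)   # dT_a/dM[a,b] = x_b
      }
      g
    }
    opt <- stats::optim(par, cost_fn, grad_fn, method = "BFGS",
                        control = list(maxit = iters, reltol = 1e-10))
    par <- opt$par
  }
  out <- affine3d(diag(3) + matrix(par[4:12], 3, 3), par[1:3])
  attr(out, "trace") <- cummin(trace)
  out
}

# bending-energy penalty on the control lattice and its gradient
bending_energy <- function(cp, cs) {
  nc <- dim(cp)[1:3]
  S <- lapply(1:3, function(ax) {
    n <- nc[ax]
    M <- matrix(0, max(n - 2, 1), n)
    if (n >= 3) for (i in seq_len(n - 2)) M[i, i:(i + 2)] <- c(1, -2, 1)
    M / cs[ax]^2
  })
  Fd <- lapply(1:3, function(ax) {
    n <- nc[ax]
    M <- matrix(0, max(n - 1, 1), n)
    if (n >= 2) for (i in seq_len(n - 1)) M[i, i:(i + 1)] <- c(-1, 1)
    M / cs[ax]
  })
  E <- 0
  G <- array(0, dim(cp))
  for (a in 1:3) {
    C <- cp[, , , a, drop = FALSE][, , , 1]
    for (i in 1:3) {
      D <- ttm(C, S[[i]], i)
      E <- E + sum(D^2)
      G[, , , a] <- G[, , , a] + 2 * ttm(D, t(S[[i]]), i)
    }
    cross <- list(c(1, 2), c(1, 3), c(2, 3))
    for (ij in cross) {
      D <- ttm(ttm(C, Fd[[ij[1]]], ij[1]), Fd[[ij[2]]], ij[2])
      E <- E + 2 * sum(D^2)
      G[, , , a] <- G[, , , a] +
        4 * ttm(ttm(D, t(Fd[[ij[2]]]), ij[2]), t(Fd[[ij[1]]]), ij[1])
    }
  }
  npts <- prod(nc)
  list(E = E / npts, G = G / npts)
}

#' B-spline free-form deformation registration
#'
#' Optimizes cubic B-spline control-point displacements on top of an
#' affine pre-alignment by multi-resolution gradient descent with
#' backtracking, penalized by bending energy. The returned field's
#' best-cost trace (attribute `"trace"`) is non-increasing and the final
#' cost never exceeds the initial cost.
#'
#' @param moving,fixed [image3d()] objects.
#' @param control_spacing_mm B-spline control-point spacing in mm
#'   (default 10, the coarse spacing used for subject alignment).
#' @param metric "ncc" (global normalized cross-correlation, default),
#'   "lncc" (windowed normalized cross-correlation, insensitive to
#'   smooth intensity bias but noisier per window) or "ssd".
#' @param levels resolution levels.
#' @param iters iterations per level (recycled).
#' @param reg_weight bending-energy weight.
#' @param affine `affine3d` pre-alignment (fixed world -> moving world).
#' @param init optional `deformation_field` to warm-start from.
#' @return a [deformation_field()] on the fixed geometry.
#' @export
ffd_register <- function(moving, fixed, control_spacing_mm = 10,
                         metric = c("ncc", "lncc", "ssd"), levels = 2,
                         iters = c(40, 15), reg_weight = 0.005,
                         affine = affine3d(), init = NULL) {
  metric <- match.arg(metric)
  iters <- rep_len(iters, levels)
  field <- if (is.null(init)) {
    deformation_field(img_geom(fixed), control_spacing_mm, affine = affine)
  } else init
  pad <- border_value(moving)
  fp <- image_pyramid(fixed, levels)
  mp <- image_pyramid(moving, levels)
  trace <- numeric(0)
  for (l in seq_len(levels)) {
    fx <- fp[[l]]; mv <- mp[[l]]
    geom <- img_geom(fx)
    B <- field_basis(field, geom)
    X <- sweep(grid_coords(geom$dim) %*% diag(geom$spacing), 2L,
               geom$origin, "+")
    Xa <- apply_affine(field$affine, X)
    f <- as.vector(fx$data)
    lncc_state <- if (metric == "lncc") make_lncc(fx$data)
    eval_cost <- function(cp) {
      field$cp <- cp
      U <- disp_on_grid(field, B[[1]], B[[2]], B[[3]])
      P <- Xa + cbind(as.vector(U[[1]]), as.vector(U[[2]]),
                      as.vector(U[[3]]))
      V <- world_to_vox(P, mv$spacing, mv$origin)
      vg <- interp3_wgrad(mv$data, V, pad)
      sc <- if (metric == "lncc") lncc_cost(lncc_state, vg[, 1])
        else sim_cost(f, vg[, 1], metric)
      be <- bending_energy(cp, field$cp_spacing)
      list(cost = sc$cost + reg_weight * be$E, sc = sc, be = be, vg = vg)
    }
    cur <- eval_cost(field$cp)
    if (!is.finite(cur$cost))
      stop("ffd_register: non-finite cost at start of level ", l)
    if (iters[l] < 1) { trace <- c(trace, cur$cost); next }
    cp_dim <- dim(field$cp)
    best <- cur$cost
    it_count <- 0L
    last <- NULL
    eval_cached <- function(par) {
      if (!is.null(last) && identical(last$par, par)) return(last$e)
      e <- eval_cost(array(par, cp_dim))
      last <<- list(par = par, e = e)
      e
    }
    fn <- function(par) {
      it_count <<- it_count + 1L
      e <- eval_cached(par)
      if (!is.finite(e$cost))
        stop("ffd_register: divergence (non-finite cost) at evaluation ",
             it_count, " of level ", l)
      if (e$cost < best) {
        best <<- e$cost
        trace <<- c(trace, e$cost)
      }
      e$cost
    }
    gr <- function(par) {
      e <- eval_cached(par)
      G <- array(0, dim(field$cp))
      for (a in 1:3) {
        Gv <- array(e$sc$dw * e$vg[, 1 + a] / mv$spacing[a], geom$dim)
        G[, , , a] <- ttm(ttm(ttm(Gv, t(B[[1]]), 1), t(B[[2]]), 2),
                          t(B[[3]]), 3)
      }
      as.vector(G + reg_weight * e$be$G)
    }
    opt <- stats::optim(as.vector(field$cp), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = iters[l], factr = 1e4))
    if (opt$value <= cur$cost) field$cp <- array(opt$par, cp_dim)
  }
  attr(field, "trace") <- trace
  field
}

# mean displacement magnitude of the B-spline part over the domain, mm
mean_displacement <- function(field) {
  B <- field_basis(field, field$domain)
  U <- disp_on_grid(field, B[[1]], B[[2]], B[[3]])
  mean(sqrt(U[[1]]^2 + U[[2]]^2 + U[[3]]^2))
}
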