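# Manifold-based learning features: intensity patches from a region
# around the hippocampi and amygdala after coarse alignment to the
# template, a k-NN similarity graph from pairwise patch distances, and
# Laplacian eigenmaps coordinates (generalized eigenproblem
# L y = lambda D y) as unsupervised per-subject features. No label
# ever enters this module.

#' Region-of-interest mask around hippocampi and amygdala
#'
#' @param labelmap template [labelmap3d()].
#' @param dilate_vox dilation of the hippocampus+amygdala labels in
#'   voxels (default 4).
#' @return logical 3D array in template space.
#' @export
mbl_roi_mask <- function(labelmap, dilate_vox = 4L) {
  m <- array(labelmap$labels %in% c(4L, 5L, 6L), dim(labelmap$labels))
  dilate3(m, dilate_vox)
}

#' Extract a z-scored ROI intensity patch from a subject
#'
#' Samples the template-space ROI voxels from the subject image warped
#' through `field` (identity if NULL, for images already on the
#' template grid), then z-scores within the ROI.
#'
#' @param subject_image [image3d()].
#' @param roi_mask logical array in template space.
#' @param field `deformation_field` (fixed = template, moving =
#'   subject) or NULL.
#' @param template_geom geometry list for the ROI grid (required if
#'   `field` is NULL and the subject grid differs).
#' @return numeric vector of length `sum(roi_mask)`.
#' @export
extract_roi_patch <- function(subject_image, roi_mask, field = NULL,
                              template_geom = NULL) {
  d <- dim(roi_mask)
  if (is.null(field)) {
    if (!identical(dim(subject_image$data), d))
      stop("extract_roi_patch: subject grid differs from ROI grid and ",
           "no deformation field was given")
    vals <- subject_image$data[roi_mask]
  } else {
    if (!identical(as.integer(field$domain$dim), as.integer(d)))
      stop("extract_roi_patch: ROI lies outside the field domain")
    P <- transform_grid(field)
    idx <- which(as.vector(roi_mask))
    V <- world_to_vox(P[idx, , drop = FALSE], subject_image$spacing,
                      subject_image$origin)
    vals <- interp3(subject_image$data, V, "linear",
                    border_value(subject_image))
  }
  s <- stats::sd(vals)
  (vals - mean(vals)) / if (s > 0) s else 1
}

#' Build a k-NN similarity graph from patches
#'
#' Pairwise dissimilarity is the Euclidean distance between patches;
#' edges follow the symmetrized union k-NN rule, with Gaussian weights
#' `exp(-d^2 / (2 sigma^2))` and `sigma` the median k-NN distance
#' (identical patches get weight 1).
#'
#' @param patches numeric matrix, one row per subject.
#' @param k neighbourhood size (n >= k+1 required).
#' @param sigma kernel bandwidth; NULL for the median k-NN rule.
#' @return a `similarity_graph`: list with `W` (symmetric, zero
#'   diagonal), `k`, `sigma`.
#' @export
build_similarity_graph <- function(patches, k = 10, sigma = NULL) {
  X <- as.matrix(patches)
  n <- nrow(X)
  if (n < k + 1) stop("build_similarity_graph: need n >= k+1 subjects")
  D <- as.matrix(stats::dist(X))
  nn <- t(apply(D, 1, function(r) order(r)[2:(k + 1)]))
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) A[i, nn[i, ]] <- TRUE
  A <- A | t(A)
  diag(A) <- FALSE
  if (is.null(sigma)) {
    knn_d <- D[cbind(rep(seq_len(n), k), as.vector(nn))]
    sigma <- stats::median(knn_d)
  }
  W <- matrix(0, n, n)
  W[A] <- exp(-D[A]^2 / (2 * max(sigma, 1e-12)^2))
  dimnames(W) <- dimnames(D)
  structure(list(W = W, k = k, sigma = sigma),
            class = "similarity_graph")
}

graph_components <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  igraph::components(g)
}

#' Laplacian eigenmaps embedding
#'
#' Solves the generalized eigenproblem `L y = lambda D y` with
#' `L = D - W` via the symmetric normalized form, discards the
#' constant eigenvector (lambda = 0), and returns the eigenvectors of
#' the `d` smallest remaining eigenvalues. Columns are D-orthogonal;
#' each column's sign is fixed so its largest-magnitude entry is
#' positive. A disconnected graph is an error naming the component
#' sizes.
#'
#' @param graph a `similarity_graph`.
#' @param d embedding dimension (d < n-1); default 20.
#' @return an `embedding`: list with `Y` (n x d), `lambda`
#'   (ascending), `degree`.
#' @export
laplacian_eigenmaps <- function(graph, d = 20) {
  W <- graph$W
  n <- nrow(W)
  if (d >= n - 1)
    stop("laplacian_eigenmaps: d must be < n-1 (n = ", n, ")")
  comp <- graph_components(W)
  if (comp$no > 1)
    stop("laplacian_eigenmaps: graph is disconnected (component sizes ",
         paste(comp$csize, collapse = ", "), ")")
  deg <- rowSums(W)
  s <- 1 / sqrt(deg)
  Lsym <- -(s %o% s) * W
  diag(Lsym) <- diag(Lsym) + 1
  e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  ord <- rev(seq_len(n))                 # ascending eigenvalues
  vals <- pmax(e$values[ord], 0)
  vecs <- e$vectors[, ord, drop = FALSE]
  keep <- 2:(d + 1)                      # drop the constant eigenvector
  Y <- vecs[, keep, drop = FALSE] * s
  # unit-norm columns: scale-free in W, still mutually D-orthogonal
  Y <- sweep(Y, 2L, sqrt(colSums(Y^2)), "/")
  for (j in seq_len(ncol(Y))) {
    im <- which.max(abs(Y[, j]))
    if (Y[im, j] < 0) Y[, j] <- -Y[, j]
  }
  rownames(Y) <- rownames(W)
  colnames(Y) <- paste0("MBL", seq_len(d))
  structure(list(Y = Y, lambda = vals[keep], degree = deg),
            class = "embedding")
}

#' Nyström out-of-sample extension of an embedding
#'
#' Approximates embedding coordinates for held-out subjects from a
#' training-set embedding, using the random-walk form of the
#' eigenproblem: `y_j(x) = sum_i (w(x,i)/d(x)) Y_ij / (1 - lambda_j)`
#' with the training graph's kernel bandwidth. This gives strict
#' train/test separation as an alternative to the default transductive
#' embedding.
#'
#' @param embedding an `embedding` from [laplacian_eigenmaps()].
#' @param graph the `similarity_graph` the embedding came from.
#' @param train_patches,new_patches patch matrices (rows = subjects).
#' @return matrix of embedding coordinates for the new patches.
#' @export
nystrom_extend <- function(embedding, graph, train_patches,
                           new_patches) {
  Xt <- as.matrix(train_patches)
  Xn <- as.matrix(new_patches)
  D2 <- outer(rowSums(Xn^2), rowSums(Xt^2), "+") - 2 * Xn %*% t(Xt)
  W <- exp(-pmax(D2, 0) / (2 * max(graph$sigma, 1e-12)^2))
  # keep each new point's k nearest training neighbours, as in the graph
  k <- min(graph$k, ncol(W))
  for (i in seq_len(nrow(W))) {
    keep <- order(D2[i, ])[seq_len(k)]
    W[i, -keep] <- 0
  }
  P <- W / rowSums(W)
  sweep(P %*% embedding$Y, 2L, pmax(1 - embedding$lambda, 1e-8), "/")
}

#' MBL feature matrix for a set of subjects
#'
#' Full chain: ROI patch per subject (optionally through a coarse
#' 10 mm FFD alignment to the template), symmetrized k-NN similarity
#' graph, Laplacian eigenmaps. If the graph is disconnected, k is
#' increased (with a message) until it connects. The embedding is
#' transductive: it is computed jointly over all listed subjects and
#' uses no labels.
#'
#' @param cohort a `cohort`.
#' @param ids subjects to embed (default all).
#' @param d embedding dimension (default 20).
#' @param k initial neighbourhood size.
#' @param register if TRUE, align each subject to the template with a
#'   coarse 10 mm B-spline registration before sampling the ROI;
#'   phantom subjects already live on the template grid, so the
#'   default is FALSE.
#' @param dilate_vox ROI dilation around hippocampi/amygdala.
#' @param scale_by_lambda if TRUE, scale coordinate j by
#'   1/sqrt(lambda_j) (off by default).
#' @return feature matrix (subjects x d) with the graph and embedding
#'   as attributes.
#' @export
mbl_features <- function(cohort, ids = cohort$manifest$id, d = 20,
                         k = 10, register = FALSE, dilate_vox = 4L,
                         scale_by_lambda = FALSE) {
  roi <- mbl_roi_mask(cohort$labelmap, dilate_vox)
  geom <- img_geom(cohort$template$image)
  patches <- t(vapply(ids, function(id) {
    s <- cohort$subjects[[match(id, cohort$manifest$id)]]
    fld <- if (register) {
      ffd_register(s$image, cohort$template$image,
                   control_spacing_mm = 10, levels = 2, iters = c(25, 8))
    } else NULL
    extract_roi_patch(s$image, roi, fld)
  }, numeric(sum(roi))))
  rownames(patches) <- ids
  kk <- k
  repeat {
    graph <- build_similarity_graph(patches, kk)
    if (graph_components(graph$W)$no == 1) break
    kk <- kk + 1
    if (kk >= length(ids))
      stop("mbl_features: graph cannot be connected")
    message("mbl_features: graph disconnected; increasing k to ", kk)
  }
  emb <- laplacian_eigenmaps(graph, d)
  Y <- emb$Y
  if (scale_by_lambda) Y <- sweep(Y, 2L, sqrt(pmax(emb$lambda, 1e-12)), "/")
  attr(Y, "graph") <- graph
  attr(Y, "embedding") <- emb
  Y
}
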