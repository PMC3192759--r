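test_that("concentric spheres give the analytic shell thickness", {
  pr <- extract_surface_pair(sphere_labels())
  th <- tlink_thickness(pr)
  expect_equal(sum(pr$flagged), 0L)
  expect_true(all(abs(th - 3) <= 0.3))
  expect_lt(abs(mean(th) - 3), 0.1)
})

test_that("mildly anisotropic shells stay near the planted margin", {
  d <- c(56, 56, 56); ctr <- (d - 1) / 2
  P <- admri:::grid_coords(d)
  rho <- function(semi) sqrt(((P[, 1] - ctr[1]) / semi[1])^2 +
                               ((P[, 2] - ctr[2]) / semi[2])^2 +
                               ((P[, 3] - ctr[3]) / semi[3])^2)
  lab <- array(1L, d)
  lab[array(rho(c(23, 21, 20)) < 1, d)] <- 2L
  lab[array(rho(c(20, 18, 17)) < 1, d)] <- 3L
  lm <- labelmap3d(lab, NULL, c(background = 0L, CSF = 1L, GM = 2L,
                                WM = 3L))
  th <- tlink_thickness(extract_surface_pair(lm))
  # normal distance between offset ellipsoid shells is close to the
  # 3 mm axis margin for mild eccentricity
  expect_lt(abs(mean(th, na.rm = TRUE) - 3) / 3, 0.15)
  expect_gt(mean(abs(th - 3) < 0.45, na.rm = TRUE), 0.9)
})

test_that("node count is stable under sub-voxel translation", {
  n0 <- nrow(extract_surface_pair(sphere_labels())$inner)
  n1 <- nrow(extract_surface_pair(
    sphere_labels(centre = (c(56, 56, 56) - 1) / 2 + c(0.35, -0.4, 0.3))
  )$inner)
  expect_lt(abs(n1 - n0) / n0, 0.05)
})

test_that("t-link distance is plain Euclidean between linked nodes", {
  pr <- extract_surface_pair(sphere_labels())
  same <- pr; same$outer <- pr$inner
  expect_true(all(tlink_thickness(same)[!same$flagged] == 0))
  offs <- pr; offs$outer <- pr$inner +
    matrix(rep(c(1, 2, 2), each = nrow(pr$inner)), ncol = 3)
  th345 <- tlink_thickness(offs)[!offs$flagged]
  expect_equal(th345, rep(3, length(th345)), tolerance = 1e-12)
})

test_that("surface smoothing: identity at fwhm 0, constants, mean", {
  pr <- extract_surface_pair(sphere_labels())
  th <- tlink_thickness(pr)
  expect_identical(smooth_thickness(pr, th, 0), th)
  konst <- rep(2.5, length(th))
  expect_equal(smooth_thickness(pr, konst, 15), konst, tolerance = 1e-9)
  sm <- smooth_thickness(pr, th, 15)
  expect_lt(abs(mean(sm) - mean(th)), 1e-6)
  expect_lt(var(sm), var(th))
})

test_that("smoothing kernel width matches the requested FWHM", {
  pr <- extract_surface_pair(sphere_labels())
  set.seed(10)
  noise <- rnorm(nrow(pr$inner))
  fwhm <- 10
  sm <- smooth_thickness(pr, noise, fwhm)
  # correlation of smoothed white noise decays as exp(-d^2/(4 sigma^2));
  # the half-maximum distance is 2 sigma sqrt(log 2)
  D <- as.matrix(dist(pr$inner))
  v <- outer(sm - mean(sm), sm - mean(sm))
  bins <- cut(D[upper.tri(D)], breaks = seq(0, 20, 1))
  corr <- tapply(v[upper.tri(D)], bins, mean)
  corr <- corr / corr[1]
  d_half <- which(corr < 0.5)[1] - 0.5     # bin midpoints
  sigma <- fwhm / sqrt(8 * log(2))
  expected <- 2 * sigma * sqrt(log(2))
  expect_lt(abs(d_half - expected) / expected, 0.25)
})

test_that("planted cortical thinning is recovered at the node level", {
  tpl <- tpl48()
  eff <- effect_spec()
  th_of <- function(grp, seed) {
    s <- sample_subject(tpl, tpl$labelmap, grp, 75, "F", eff, seed = seed)
    mean(tlink_thickness(extract_surface_pair(s$labels)), na.rm = TRUE)
  }
  hc <- vapply(1:4, function(i) th_of("HC", 800 + i), numeric(1))
  ad <- vapply(1:4, function(i) th_of("AD", 900 + i), numeric(1))
  expect_lt(abs((mean(hc) - mean(ad)) - 0.5), 0.15)
})

test_that("statistical-ROI thickness features follow the stated rules", {
  set.seed(20)
  n_nodes <- 60
  node_parcels <- rep(c(101L, 102L, 103L), each = 20)
  groups <- rep(c("HC", "AD"), each = 10)
  thick <- matrix(3 + rnorm(20 * n_nodes, sd = 0.1), 20, n_nodes,
                  dimnames = list(sprintf("S%02d", 1:20), NULL))
  # plant thinning in parcel 102 for AD
  thick[groups == "AD", 21:40] <- thick[groups == "AD", 21:40] - 0.6
  f <- cth_stat_roi_features(thick, groups, node_parcels, c("HC", "AD"),
                             alpha = 0.01)
  expect_equal(colnames(f), "CTH_p2")
  # alpha = 1 degenerates to plain parcel means
  f1 <- cth_stat_roi_features(thick, groups, node_parcels, c("HC", "AD"),
                              alpha = 1)
  expect_equal(ncol(f1), 3)
  expect_equal(unname(f1[1, 1]), mean(thick[1, 1:20]), tolerance = 1e-12)
  # two significant nodes with thickness 2 and 3 average to 2.5
  th2 <- matrix(3, 20, 2, dimnames = list(rownames(thick), NULL))
  th2[groups == "AD", ] <- 2
  th2[1, ] <- c(2.0, 3.0)
  f2 <- cth_stat_roi_features(th2, groups, rep(101L, 2), c("HC", "AD"),
                              alpha = 1)
  expect_equal(unname(f2[1, 1]), 2.5)
  expect_error(cth_stat_roi_features(thick * 0 + 3, groups, node_parcels,
                                     c("HC", "AD"), alpha = 1e-9),
               "larger alpha")
})

test_that("missing-thickness flags propagate to the feature table", {
  tpl <- tpl32()
  eff <- eff_zero()
  eff$missing_cth_fraction <- 0.25
  co <- sample_cohort(tpl, tpl$labelmap, c(HC = 4, AD = 4), eff, seed = 6)
  expect_equal(sum(co$manifest$cth_missing), 2)
  ct <- cth_node_table(co, fwhm_mm = 5)
  miss_rows <- rowSums(!is.na(ct$thick)) == 0
  expect_equal(unname(miss_rows[co$manifest$id]),
               co$manifest$cth_missing)
  # flag_missing_cth marks a clean subject
  s <- flag_missing_cth(co$subjects[[1]])
  expect_true(s$cth_missing)
})

test_that("thickness is invariant to intensity rescaling", {
  tpl <- tpl32()
  s <- sample_subject(tpl, tpl$labelmap, "HC", 75, "F", eff_zero(),
                      seed = 3)
  pr <- extract_surface_pair(s$labels)   # labels only: trivially invariant
  s$image$data <- s$image$data * 10
  pr2 <- extract_surface_pair(s$labels)
  expect_identical(tlink_thickness(pr), tlink_thickness(pr2))
})
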