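# Small cohorts on the 32^3 grid keep the registration budget modest;
# the planted-atrophy recovery runs once on the 48^3 template.

mini_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tpl <- tpl32()
      cache <<- sample_cohort(tpl, tpl$labelmap,
                              c(HC = 4, `S-MCI` = 2, `P-MCI` = 2, AD = 4),
                              effect_spec(), seed = 77)
    }
    cache
  }
})

test_that("template library draw is seeded and stratified", {
  co <- mini_cohort()
  lib1 <- build_template_library(co, 2, 2, 2, seed = 3)
  lib2 <- build_template_library(co, 2, 2, 2, seed = 3)
  expect_identical(lib1$ids, lib2$ids)
  expect_identical(lib1$reference$data, lib2$reference$data)
  grp <- co$manifest$group[match(lib1$ids, co$manifest$id)]
  expect_equal(sum(grp == "HC"), 2)
  expect_equal(sum(grp %in% c("S-MCI", "P-MCI")), 2)
  expect_equal(sum(grp == "AD"), 2)
  expect_error(build_template_library(co, 8, 2, 2), "HC")
})

test_that("identical single-subject library returns that image", {
  tpl <- tpl32()
  s <- sample_subject(tpl, tpl$labelmap, "HC", 75, "F", eff_zero(),
                      seed = 1)
  s$id <- "S001"
  co <- list(subjects = list(s),
             manifest = data.frame(id = "S001", group = "HC", age = 75,
                                   sex = "F", cth_missing = FALSE),
             template = tpl, labelmap = tpl$labelmap)
  class(co) <- "cohort"
  lib <- build_template_library(co, 1, 0, 0, seed = 1)
  expect_equal(lib$reference$data, s$image$data, tolerance = 1e-12)
})

test_that("voxelwise t-test matches a scalar Welch oracle and nulls", {
  set.seed(42)
  mk <- function(v) image3d(array(v, c(8, 8, 8)))
  # identical groups: t = 0
  a <- lapply(1:3, function(i) mk(rep(i, 512)))
  sm0 <- voxelwise_ttest(a, a)
  expect_true(all(abs(sm0$t[!is.na(sm0$t)]) < 1e-12))
  # single-voxel oracle against stats::t.test
  xa <- rnorm(20); xb <- rnorm(20, 1)
  A <- lapply(xa, function(v) mk(v))
  B <- lapply(xb, function(v) mk(v))
  sm <- voxelwise_ttest(A, B)
  tt <- t.test(xa, xb)
  expect_equal(sm$t[1, 1, 1], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(sm$p[1, 1, 1], tt$p.value, tolerance = 1e-10)
  # null maps: about 5% of voxels significant
  An <- lapply(1:15, function(i) mk(rnorm(512)))
  Bn <- lapply(1:15, function(i) mk(rnorm(512)))
  smn <- voxelwise_ttest(An, Bn)
  expect_lt(abs(mean(smn$p < 0.05, na.rm = TRUE) - 0.05), 0.025)
  expect_error(voxelwise_ttest(A[1], B), ">= 2")
})

test_that("stat-ROI features follow the stated weighted-mean formula", {
  d <- c(8, 8, 8)
  parc <- array(101L, d)
  # uniform p = alpha/2, J = 1 everywhere -> every feature equals 1
  sm <- structure(list(t = array(1, d), p = array(0.025, d),
                       mean_A = array(1, d), mean_B = array(0.9, d),
                       contrast = "HCvsAD", n_A = 5, n_B = 5),
                  class = "stat_map")
  f <- stat_roi_features(list(image3d(array(1, d))), sm, parc,
                         alpha = 0.05)
  expect_equal(as.numeric(f), 1)
  # hand-computed two-voxel example: (2*0.9 + 3*0.8) / 5 = 0.84
  p <- array(1, d); p[1, 1, 1] <- 0.01; p[2, 1, 1] <- 0.001
  J <- array(1, d); J[1, 1, 1] <- 0.9; J[2, 1, 1] <- 0.8
  sm2 <- structure(list(t = array(1, d), p = p,
                        mean_A = array(1, d), mean_B = array(0.9, d),
                        contrast = "HCvsAD", n_A = 5, n_B = 5),
                   class = "stat_map")
  f2 <- stat_roi_features(list(image3d(J)), sm2, parc, alpha = 0.05)
  expect_equal(as.numeric(f2), (2 * 0.9 + 3 * 0.8) / 5, tolerance = 1e-12)
  # non-atrophic direction (mean lower in the less-affected group):
  # nothing qualifies anywhere -> error advising a larger alpha
  sm3 <- sm2
  sm3$mean_A <- array(0.9, d); sm3$mean_B <- array(1, d)
  expect_error(stat_roi_features(list(image3d(J)), sm3, parc,
                                 alpha = 0.05), "larger alpha")
  # a parcel without significant voxels falls back to the parcel mean
  parc2 <- parc; parc2[, , 5:8] <- 102L
  J4 <- array(1, d); J4[, , 5:8] <- 0.7
  f4 <- stat_roi_features(list(image3d(J4)), sm2, parc2, alpha = 0.05)
  expect_true(attr(f4, "empty")[2])
  expect_equal(as.numeric(f4[2]), 0.7, tolerance = 1e-12)
})

test_that("self-registration Jacobians are near one inside the brain", {
  co <- mini_cohort()
  tpl <- co$template
  s <- co$subjects[[1]]
  lib <- list(templates = list(list(id = s$id, group = s$group,
                                    image = s$image)),
              reference = tpl$image,
              to_template = list(deformation_field(
                admri:::img_geom(tpl$image), 10)),
              ids = s$id)
  class(lib) <- "template_library"
  maps <- subject_jacobians(s, lib)
  brain <- tpl$labelmap$labels >= 2
  expect_lt(mean(abs(maps[[1]]$data[brain] - 1)), 0.05)
})

test_that("planted regional shrinkage appears in the Jacobian maps", {
  # per-subject regional Jacobians carry ~10% deformation noise at
  # this resolution, so the calibration check uses a small group mean
  tpl <- tpl48()
  eff <- effect_spec()
  js <- vapply(c(77, 401, 403), function(sd) {
    q <- sample_subject(tpl, tpl$labelmap, "AD", 75, "F", eff, seed = sd)
    fld <- ffd_register(q$image, tpl$image, control_spacing_mm = 6,
                        levels = 2, iters = c(40, 20))
    mean(jacobian_map(fld)$data[q$truth$atrophy_region_mask])
  }, numeric(1))
  planted <- exp(effect_spec()$tbm_logj_shift[["AD"]])
  expect_lt(mean(js), 1)
  expect_lt(abs(mean(js) - planted) / planted, 0.10)
})

test_that("TBM features: count, template-consistency, group separation", {
  co <- mini_cohort()
  lib <- build_template_library(co, 1, 1, 1, seed = 9,
                                registration_params = list(
                                  control_spacing_mm = 10, levels = 2,
                                  iters = c(20, 6)))
  man <- co$manifest
  roi_ids <- man$id[c(1, 2, 9, 10)]       # 2 HC + 2 AD
  feat_ids <- setdiff(man$id[man$group %in% c("HC", "AD")], roi_ids)
  tb <- tbm_features(co, lib, roi_ids, feat_ids, c("HC", "AD"),
                     alpha = 0.2,
                     registration_params = list(control_spacing_mm = 6,
                                                levels = 2,
                                                iters = c(20, 6)))
  expect_equal(ncol(tb$features), 84)
  expect_equal(rownames(tb$features), feat_ids)
  expect_error(tbm_features(co, lib, roi_ids, roi_ids, c("HC", "AD")),
               "overlap")
})

test_that("per-template maps of one subject agree inside the brain", {
  # consistency of the multi-template readout: two different templates
  # see a positively correlated subject-specific volume pattern. The
  # attainable agreement is bounded by the phantom's internal texture
  # and its mild (1 mm) inter-subject deformations — geometric
  # compartments carry far less registration information than real
  # parenchyma — so the threshold asserts reproducible shared signal
  # rather than the near-perfect voxelwise agreement seen on real MRI.
  tpl <- tpl32()
  co <- sample_cohort(tpl, tpl$labelmap, c(HC = 2, AD = 1),
                      effect_spec(), seed = 31)
  s <- co$subjects[[3]]
  brain <- as.vector(co$labelmap$parcels > 0)
  Js <- lapply(1:2, function(i) {
    fld <- ffd_register(s$image, co$subjects[[i]]$image,
                        control_spacing_mm = 6, levels = 2,
                        iters = c(40, 15))
    jacobian_map(fld)$data
  })
  expect_gt(cor(Js[[1]][brain], Js[[2]][brain]), 0.15)
})
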