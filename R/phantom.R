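# Synthetic 3D brain phantom: nested ellipsoidal CSF/GM/WM
# compartments, a cortical ribbon of configurable thickness, two
# hippocampus-like blobs with an adjacent amygdala-like region, and a
# deterministic direction-cone parcellation of brain tissue. Geometry
# is analytic, so every planted effect (hippocampal volume factor,
# ribbon thinning, regional volume loss) has a closed-form ground
# truth.

PHANTOM_LABELS <- c(background = 0L, CSF = 1L, GM = 2L, WM = 3L,
                    `left-hippocampus` = 4L, `right-hippocampus` = 5L,
                    `amygdala-region` = 6L, ventricle = 7L)

# deterministic quasi-uniform directions on the sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# geometric parameters of the phantom, all lengths in mm
phantom_params <- function(shape, spacing = c(1, 1, 1), n_parcels = 84) {
  shape <- rep_len(as.integer(shape), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  L <- (shape - 1) * spacing / 2
  centre <- L                      # origin at 0, centre of the grid
  a_csf <- 0.90 * L * c(1, 0.92, 0.86)
  t_csf <- 2
  t_gm <- 3
  # the WM core is fixed; cortical thinning moves the outer (pial)
  # surface inward and the CSF gap absorbs the difference, as in real
  # atrophy (WM geometry is stable, sulcal CSF widens)
  a_wm <- a_csf - t_csf - t_gm
  if (any(a_wm < 3 * spacing))
    stop("phantom: shape too small to contain the white-matter core")
  hip_semi <- c(0.40, 0.30, 0.24) * a_wm
  hip_off <- c(0.50, -0.30, -0.15) * a_wm
  amy_semi <- c(0.16, 0.14, 0.13) * a_wm
  amy_off <- c(hip_off[1],
               hip_off[2] + 0.95 * (hip_semi[2] + amy_semi[2]),
               hip_off[3])
  vent_semi <- c(0.30, 0.20, 0.18) * a_wm
  vent_off <- c(0, 0.15, 0.10) * a_wm
  # the atrophy region sits on the ventricle wall, so planted tissue
  # loss displaces a high-contrast boundary (the signal tensor-based
  # morphometry reads on real images)
  atr_r0 <- 0.45 * min(a_wm)
  dirn <- c(-0.6, 0.6, 0.5); dirn <- dirn / sqrt(sum(dirn^2))
  r_wall <- 1 / sqrt(sum((dirn / vent_semi)^2))
  atr_centre <- centre + vent_off + (r_wall + 0.25 * atr_r0) * dirn
  list(shape = shape, spacing = spacing, n_parcels = n_parcels,
       centre = centre, a_csf = a_csf, a_wm = a_wm, t_csf = t_csf,
       t_gm = t_gm,
       hip_semi = hip_semi, hip_off = hip_off,
       amy_semi = amy_semi, amy_off = amy_off,
       vent_semi = vent_semi, vent_off = vent_off,
       atr_centre = atr_centre, atr_r0 = atr_r0,
       intensity = c(background = 10, CSF = 40, GM = 100, WM = 160,
                     hippocampus = 95, amygdala = 110),
       texture_amp = 8, smooth_vox = 0.6)
}

# fixed anatomical texture, deterministic and independent of the
# caller's RNG stream; defined in anatomy space so it deforms with the
# subject (shared internal structure, like real parenchyma)
phantom_texture <- function(d) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(state))
    assign(".Random.seed", state, envir = globalenv()))
  set.seed(48151623)
  tex <- gauss_smooth3(array(stats::rnorm(prod(d)), d), 2)
  tex / stats::sd(tex)
}

ellipsoid_rho2 <- function(P, centre, semi) {
  ((P[, 1] - centre[1]) / semi[1])^2 +
    ((P[, 2] - centre[2]) / semi[2])^2 +
    ((P[, 3] - centre[3]) / semi[3])^2
}

# Build the anatomy (intensity image + label map) from parameters.
phantom_anatomy <- function(p) {
  d <- p$shape
  geom <- image3d(array(0, d), spacing = p$spacing)   # geometry holder
  P <- world_grid(geom)
  a_wm <- p$a_wm
  a_gmo <- a_wm + p$t_gm
  if (any(p$hip_semi < 1.2 * p$spacing))
    stop("phantom: hippocampus semi-axes below 1.2 voxels at this ",
         "resolution; increase shape or the volume factor")
  lab <- integer(nrow(P))
  lab[ellipsoid_rho2(P, p$centre, p$a_csf) <= 1] <- 1L
  lab[ellipsoid_rho2(P, p$centre, a_gmo) <= 1] <- 2L
  lab[ellipsoid_rho2(P, p$centre, a_wm) <= 1] <- 3L
  lab[ellipsoid_rho2(P, p$centre + p$vent_off, p$vent_semi) <= 1 &
        lab == 3L] <- 7L
  in_wm <- lab == 3L
  for (s in c(-1, 1)) {
    off <- p$amy_off * c(s, 1, 1)
    sel <- ellipsoid_rho2(P, p$centre + off, p$amy_semi) <= 1 & in_wm
    lab[sel] <- 6L
  }
  for (s in c(-1, 1)) {
    off <- p$hip_off * c(s, 1, 1)
    sel <- ellipsoid_rho2(P, p$centre + off, p$hip_semi) <= 1 & lab %in% c(3L, 6L)
    lab[sel] <- if (s < 0) 4L else 5L
  }
  if (!any(lab == 4L) || !any(lab == 5L))
    stop("phantom: shape too small to contain the hippocampi")
  if (!any(lab == 6L))
    stop("phantom: shape too small to contain the amygdala region")
  if (!any(lab == 7L))
    stop("phantom: shape too small to contain the ventricle")
  ints <- p$intensity
  ivals <- c(ints["background"], ints["CSF"], ints["GM"], ints["WM"],
             ints["hippocampus"], ints["hippocampus"], ints["amygdala"],
             ints["CSF"])
  img <- array(ivals[lab + 1L], d)
  tissue <- lab >= 2L & lab != 7L
  if (p$texture_amp > 0)
    img <- img + p$texture_amp * as.vector(phantom_texture(d)) * tissue
  img <- gauss_smooth3(img, p$smooth_vox)
  # direction-cone parcellation of brain tissue (ventricle excluded)
  dirs <- fibonacci_sphere(p$n_parcels)
  V <- sweep(P[tissue, , drop = FALSE], 2L, p$centre, "-")
  V <- sweep(V, 2L, p$a_csf, "/")
  nv <- sqrt(rowSums(V^2)); nv[nv == 0] <- 1
  pc <- max.col((V / nv) %*% t(dirs), ties.method = "first")
  parcels <- integer(nrow(P))
  parcels[tissue] <- 100L + pc
  if (length(unique(pc)) != p$n_parcels)
    stop("phantom: ", p$n_parcels - length(unique(pc)),
         " parcels received no tissue voxels; use a larger shape or ",
         "fewer parcels")
  legend <- c(PHANTOM_LABELS,
              stats::setNames(100L + seq_len(p$n_parcels),
                              paste0("parcel_", seq_len(p$n_parcels))))
  list(image = image3d(array(img, d), spacing = p$spacing),
       labelmap = labelmap3d(array(lab, d), array(parcels, d), legend,
                             spacing = p$spacing))
}

#' Generate the phantom template
#'
#' Builds the smooth brain-like template image and its label map
#' (tissue classes, hippocampi, amygdala region, and `n_parcels`
#' direction-cone parcels of brain tissue). Fully deterministic.
#'
#' @param shape grid dimensions (>= 32 per axis recommended).
#' @param spacing voxel size in mm.
#' @param n_parcels number of tissue parcels (>= 2; default 84).
#' @param seed accepted for interface symmetry; the template is
#'   deterministic and does not consume randomness.
#' @return list with `image` ([image3d()]), `labelmap`
#'   ([labelmap3d()]), and `params` (the generating geometry).
#' @export
make_template <- function(shape = c(48, 48, 48), spacing = c(1, 1, 1),
                          n_parcels = 84, seed = NULL) {
  stopifnot(n_parcels >= 2)
  p <- phantom_params(shape, spacing, n_parcels)
  out <- phantom_anatomy(p)
  out$params <- p
  out
}

#' Group effect specification for the phantom cohort
#'
#' Encodes the disease-severity gradient planted in synthetic subjects:
#' multiplicative hippocampal volume factors, cortical-ribbon thickness
#' offsets, and regional log-Jacobian shifts per group (HC is the
#' identity), plus age/sex effects applied to all groups identically,
#' noise and bias-field levels, the missing-thickness fraction, and the
#' random-deformation amplitude.
#'
#' @param hv_factor named per-group multiplicative hippocampal volume
#'   factor (HC must be 1).
#' @param cth_offset_mm named per-group thickness offset in mm.
#' @param tbm_logj_shift named per-group regional log-Jacobian shift
#'   (negative = volume loss).
#' @param age_slope_hv relative hippocampal volume change per year of
#'   age (applied to every group).
#' @param age_slope_cth_mm thickness change in mm per year of age.
#' @param sex_hv_factor male/female hippocampal volume ratio.
#' @param sex_cth_offset_mm thickness offset for males in mm.
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param bias_amp log-amplitude of the smooth multiplicative bias
#'   field.
#' @param missing_cth_fraction fraction of subjects flagged as missing
#'   cortical thickness (default 0.13).
#' @param deform_amp_mm amplitude of the random B-spline deformation.
#' @param monotone if TRUE, enforce the ordering HC >= S-MCI >= P-MCI
#'   >= AD on all atrophy-sensitive quantities.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(
    hv_factor = c(HC = 1, `S-MCI` = 0.95, `P-MCI` = 0.90, AD = 0.85),
    cth_offset_mm = c(HC = 0, `S-MCI` = -0.15, `P-MCI` = -0.3, AD = -0.5),
    tbm_logj_shift = c(HC = 0, `S-MCI` = -0.08, `P-MCI` = -0.15, AD = -0.22),
    age_slope_hv = -0.005, age_slope_cth_mm = -0.008,
    sex_hv_factor = 1.06, sex_cth_offset_mm = -0.05,
    noise_sd = 5, bias_amp = 0.08, missing_cth_fraction = 0.13,
    deform_amp_mm = 1.0, monotone = TRUE) {
  if (any(hv_factor <= 0)) stop("effect_spec: volume factors must be > 0")
  if (hv_factor[["HC"]] != 1 || cth_offset_mm[["HC"]] != 0 ||
      tbm_logj_shift[["HC"]] != 0)
    stop("effect_spec: HC effects must be the identity")
  if (missing_cth_fraction < 0 || missing_cth_fraction > 1)
    stop("effect_spec: missing_cth_fraction must be in [0,1]")
  grp <- c("HC", "S-MCI", "P-MCI", "AD")
  if (monotone) {
    for (v in list(hv_factor[grp], cth_offset_mm[grp], tbm_logj_shift[grp]))
      if (any(diff(v) > 1e-12))
        stop("effect_spec: monotone ordering HC >= S-MCI >= P-MCI >= AD ",
             "violated")
  }
  structure(list(hv_factor = hv_factor, cth_offset_mm = cth_offset_mm,
                 tbm_logj_shift = tbm_logj_shift,
                 age_slope_hv = age_slope_hv,
                 age_slope_cth_mm = age_slope_cth_mm,
                 sex_hv_factor = sex_hv_factor,
                 sex_cth_offset_mm = sex_cth_offset_mm,
                 noise_sd = noise_sd, bias_amp = bias_amp,
                 missing_cth_fraction = missing_cth_fraction,
                 deform_amp_mm = deform_amp_mm, monotone = monotone),
            class = "effect_spec")
}

STUDY_GROUPS <- c("HC", "S-MCI", "P-MCI", "AD")

# smooth radial expansion used to plant regional volume loss: sampling
# positions are pushed away from the centre inside the core so the
# synthesized structure is contracted by exp(logj_shift) in volume.
radial_expand <- function(P, centre, logj_shift, r0, r1) {
  if (abs(logj_shift) < 1e-12) return(P)
  g_core <- exp(-logj_shift / 3)      # > 1 for volume loss
  D <- sweep(P, 2L, centre, "-")
  r <- sqrt(rowSums(D^2))
  s <- (r - r0) / (r1 - r0)
  s <- pmin(pmax(s, 0), 1)
  blend <- 1 - s^2 * (3 - 2 * s)      # 1 in core, 0 outside r1
  g <- 1 + (g_core - 1) * blend
  sweep(D * g, 2L, centre, "+")
}

#' Synthesize one phantom subject
#'
#' Applies, in order: group/age/sex adjustment of the anatomy
#' parameters (hippocampal volume factor, ribbon thinning), a random
#' smooth B-spline deformation, a regional radial contraction planting
#' the configured log-Jacobian shift, a smooth multiplicative bias
#' field, and additive Gaussian noise. All planted values are recorded
#' in the `truth` entry.
#'
#' @param template output of [make_template()].
#' @param labelmap the template label map (legend reused; geometry must
#'   match the template).
#' @param group one of HC, S-MCI, P-MCI, AD.
#' @param age,sex subject covariates (`sex` is "M" or "F").
#' @param effects an [effect_spec()].
#' @param seed integer seed; identical seeds give bit-identical
#'   subjects.
#' @return a `subject_record` list: id, group, age, sex, image, labels,
#'   truth (hippo_volume_mm3, cortical_thickness_mm,
#'   atrophy_region_mask, deformation, planted factors), features
#'   (empty), cth_missing flag.
#' @export
sample_subject <- function(template, labelmap, group, age, sex,
                           effects = effect_spec(), seed = 1L) {
  stopifnot(group %in% STUDY_GROUPS, sex %in% c("M", "F"))
  p <- template$params
  if (is.null(p)) stop("sample_subject: template must come from make_template()")
  set.seed(seed)
  f_hv <- effects$hv_factor[[group]] *
    (1 + effects$age_slope_hv * (age - 75)) *
    (if (sex == "M") effects$sex_hv_factor else 1)
  if (f_hv <= 0) stop("sample_subject: effective volume factor <= 0")
  p2 <- p
  p2$hip_semi <- p$hip_semi * f_hv^(1 / 3)
  p2$t_gm <- p$t_gm + effects$cth_offset_mm[[group]] +
    effects$age_slope_cth_mm * (age - 75) +
    (if (sex == "M") effects$sex_cth_offset_mm else 0)
  if (p2$t_gm <= 2 * min(p$spacing))
    stop("sample_subject: requested ribbon thickness unreachable at this ",
         "resolution")
  anat <- phantom_anatomy(p2)
  geom <- img_geom(template$image)
  field <- random_field(geom, cp_spacing_mm = 12,
                        amp_mm = effects$deform_amp_mm)
  shift <- effects$tbm_logj_shift[[group]]
  P <- transform_grid(field)
  P2 <- radial_expand(P, p$atr_centre, shift, p$atr_r0, 2 * p$atr_r0)
  V <- world_to_vox(P2, anat$image$spacing, anat$image$origin)
  img <- array(interp3(anat$image$data, V, "linear",
                       pad = p$intensity[["background"]]), geom$dim)
  lab <- array(as.integer(interp3(anat$labelmap$labels, V, "nearest", 0)),
               geom$dim)
  par <- array(as.integer(interp3(anat$labelmap$parcels, V, "nearest", 0)),
               geom$dim)
  if (effects$bias_amp > 0) {
    bias <- array(stats::rnorm(prod(geom$dim)), geom$dim)
    bias <- gauss_smooth3(bias, 6)
    bias <- bias / max(stats::sd(bias), 1e-12) * effects$bias_amp
    img <- img * exp(bias)
  }
  if (effects$noise_sd > 0)
    img <- img + array(stats::rnorm(prod(geom$dim), sd = effects$noise_sd),
                       geom$dim)
  hv_mm3 <- sum(lab %in% c(4L, 5L)) * prod(geom$spacing)
  if (hv_mm3 <= 0) stop("sample_subject: hippocampus vanished at this ",
                        "resolution; volume factor unreachable")
  atrophy_mask <- array(sqrt(rowSums(sweep(P, 2L, p$atr_centre, "-")^2)) <
                          p$atr_r0, geom$dim)
  if (abs(shift) > 1e-12 && !any(atrophy_mask))
    stop("sample_subject: empty atrophy region mask")
  structure(list(
    id = NA_character_, group = group, age = age, sex = sex,
    image = image3d(img, spacing = geom$spacing, origin = geom$origin),
    labels = labelmap3d(lab, par, anat$labelmap$legend,
                        spacing = geom$spacing, origin = geom$origin),
    truth = list(hippo_volume_mm3 = hv_mm3,
                 cortical_thickness_mm = p2$t_gm,
                 atrophy_region_mask = atrophy_mask,
                 deformation = field,
                 hv_factor = f_hv, logj_shift = shift),
    features = list(), cth_missing = FALSE), class = "subject_record")
}

#' Synthesize a phantom cohort
#'
#' Independent subjects per group with ages drawn from `age_dist`,
#' sexes from `sex_ratio` (probability of male), and a
#' `missing_cth_fraction` of subjects flagged as missing cortical
#' thickness using the deterministic count `floor(n * f + 0.5)`.
#'
#' @param template,labelmap from [make_template()].
#' @param n_per_group named vector of group sizes, names in
#'   HC/S-MCI/P-MCI/AD.
#' @param effects an [effect_spec()].
#' @param age_dist function(n) returning n ages in years.
#' @param sex_ratio probability that a subject is male.
#' @param seed integer seed.
#' @return a `cohort`: list of `subjects`, a `manifest` data frame
#'   (id, group, age, sex, cth_missing), and the template objects.
#' @export
sample_cohort <- function(template, labelmap, n_per_group,
                          effects = effect_spec(),
                          age_dist = function(n)
                            pmin(pmax(stats::rnorm(n, 75, 6), 55), 92),
                          sex_ratio = 0.55, seed = 1L) {
  stopifnot(all(names(n_per_group) %in% STUDY_GROUPS),
            all(n_per_group >= 0))
  set.seed(seed)
  groups <- rep(names(n_per_group), times = n_per_group)
  n <- length(groups)
  ages <- age_dist(n)
  sexes <- ifelse(stats::runif(n) < sex_ratio, "M", "F")
  n_miss <- floor(n * effects$missing_cth_fraction + 0.5)
  miss <- rep(FALSE, n)
  if (n_miss > 0) miss[sample.int(n, n_miss)] <- TRUE
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- vector("list", n)
  ids <- sprintf("S%03d", seq_len(n))
  for (i in seq_len(n)) {
    s <- sample_subject(template, labelmap, groups[i], ages[i], sexes[i],
                        effects, seed = sub_seeds[i])
    s$id <- ids[i]
    s$cth_missing <- miss[i]
    subjects[[i]] <- s
  }
  manifest <- data.frame(id = ids, group = groups, age = ages,
                         sex = sexes, cth_missing = miss,
                         stringsAsFactors = FALSE)
  structure(list(subjects = subjects, manifest = manifest,
                 template = template, labelmap = labelmap,
                 effects = effects),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$manifest), " subjects: ",
      paste(names(table(x$manifest$group)), table(x$manifest$group),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Image-free synthetic feature table
#'
#' Fast test bed for residualization, selection, classification and the
#' cross-validation protocols. Features are unit-variance Gaussian;
#' informative features carry a between-group mean difference of
#' `effect_size_d` (scaled by disease severity for more than two
#' groups); every feature carries the configured age and sex terms.
#'
#' @param n_per_group named group sizes.
#' @param n_features number of features.
#' @param informative indices of informative features.
#' @param effect_size_d standardized between-group mean difference
#'   (>= 0).
#' @param age_slope per-year mean shift added to all features.
#' @param sex_offset mean shift for males added to all features.
#' @param missing_spec NULL, or list(fraction=, features=) flagging
#'   `floor(n * fraction + 0.5)` subjects as missing those features.
#' @param seed integer seed.
#' @return list with `X` (matrix, NA for missing), `y` (factor),
#'   `covariates` (data frame: age, sex), `informative`, `missing_ids`.
#' @export
sample_feature_table <- function(n_per_group, n_features,
                                 informative = integer(0),
                                 effect_size_d = 1, age_slope = 0,
                                 sex_offset = 0, missing_spec = NULL,
                                 seed = 1L) {
  if (effect_size_d < 0) stop("sample_feature_table: effect size must be >= 0")
  stopifnot(all(informative %in% seq_len(n_features)))
  set.seed(seed)
  groups <- rep(names(n_per_group), times = n_per_group)
  n <- length(groups)
  k <- length(n_per_group)
  sev <- stats::setNames(if (k > 1) (seq_len(k) - 1) / (k - 1) else 0,
                         names(n_per_group))
  ages <- pmin(pmax(stats::rnorm(n, 75, 6), 55), 92)
  male <- stats::runif(n) < 0.55
  X <- matrix(stats::rnorm(n * n_features), n, n_features,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("f%02d", seq_len(n_features))))
  if (length(informative))
    X[, informative] <- X[, informative] + effect_size_d * sev[groups]
  X <- X + age_slope * (ages - 75) + sex_offset * male
  missing_ids <- character(0)
  if (!is.null(missing_spec) && missing_spec$fraction > 0) {
    m <- floor(n * missing_spec$fraction + 0.5)
    rows <- sample.int(n, m)
    X[rows, missing_spec$features] <- NA
    missing_ids <- rownames(X)[rows]
  }
  list(X = X, y = factor(groups, levels = names(n_per_group)),
       covariates = data.frame(age = ages,
                               sex = ifelse(male, "M", "F"),
                               row.names = rownames(X),
                               stringsAsFactors = FALSE),
       informative = informative, missing_ids = missing_ids)
}
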