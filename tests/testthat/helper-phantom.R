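# Shared fixtures, built once per test run and cached.

tpl48 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_template(c(48, 48, 48), 1, 84)
    cache
  }
})

tpl32 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_template(c(32, 32, 32), 1, 84)
    cache
  }
})

# identity effects, no noise/bias: subjects are pure warped templates
eff_zero <- function(deform_amp_mm = 1.0) {
  effect_spec(hv_factor = c(HC = 1, `S-MCI` = 1, `P-MCI` = 1, AD = 1),
              cth_offset_mm = c(HC = 0, `S-MCI` = 0, `P-MCI` = 0, AD = 0),
              tbm_logj_shift = c(HC = 0, `S-MCI` = 0, `P-MCI` = 0, AD = 0),
              age_slope_hv = 0, age_slope_cth_mm = 0,
              sex_hv_factor = 1, sex_cth_offset_mm = 0,
              noise_sd = 0, bias_amp = 0, missing_cth_fraction = 0,
              deform_amp_mm = deform_amp_mm)
}

# concentric-sphere label map: WM inside r_wm, GM ring to r_gm, CSF out
sphere_labels <- function(d = c(56, 56, 56), r_wm = 20, r_gm = 23,
                          centre = (d - 1) / 2) {
  P <- admri:::grid_coords(d)
  r <- sqrt(rowSums(sweep(P, 2, centre, "-")^2))
  lab <- array(1L, d)
  lab[array(r < r_gm, d)] <- 2L
  lab[array(r < r_wm, d)] <- 3L
  labelmap3d(lab, NULL, c(background = 0L, CSF = 1L, GM = 2L, WM = 3L))
}

# small group-spanning atlas pool on the 48^3 template (the study's
# atlas pool covers the full disease severity range, so similarity
# selection can match the query's local anatomy)
pool48 <- local({
  cache <- NULL
  function(n = 8) {
    if (is.null(cache)) {
      tpl <- tpl48()
      grps <- rep(c("HC", "S-MCI", "P-MCI", "AD"), each = 2)
      cache <<- lapply(seq_len(8), function(i) {
        s <- sample_subject(tpl, tpl$labelmap, grps[i], 75, "F",
                            effect_spec(), seed = 4200 + i)
        s$id <- sprintf("A%02d", i)
        atlas_entry(s$image, s$labels, s$id)
      })
    }
    cache[seq_len(n)]
  }
})

manifest_of <- function(tb) {
  data.frame(id = rownames(tb$X), group = as.character(tb$y),
             tb$covariates, stringsAsFactors = FALSE)
}
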