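# Small, fast core specification used throughout the suite.
small_spec <- function(seed = 1, ...) {
  args <- list(width_px = 192, height_px = 192, um_per_px = 1,
               n_nuclei = 20, seed = seed, od_noise_sd = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(core_spec, args)
}

# Hand-buildable class / zone maps for oracle tests.
as_class_map <- function(m) {
  structure(m, class = c("pixel_class_map", "matrix", "array"),
            levels = vitroquant:::PIXEL_CLASS_LEVELS)
}
as_zone_map <- function(m) {
  structure(m, class = c("zone_map", "matrix", "array"),
            levels = vitroquant:::ZONE_LEVELS)
}
tissue_of <- function(mask, um_per_px = 1) {
  vitroquant:::new_tissue_mask(mask, um_per_px)
}
labels_of <- function(lab) vitroquant:::new_nuclei_labels(lab)

null_sim_params <- function(n_cases = 200, seed = 1, ...) {
  args <- list(n_cases = n_cases, hr_terr_vn = 1,
               hr_covariates = c(age_ge18m = 1, mycn_mna = 1,
                                 del_11q = 1, hist_unb_pdnb = 1),
               stratum_effects = list(), seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_sim_params, args)
}
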