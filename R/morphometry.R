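#' Percent stained area
#'
#' Area positive for the stain divided by the total tissue area of the
#' cylinder, multiplied by 100.
#'
#' @param positive logical matrix of positive pixels.
#' @param tissue logical matrix or [tissue_mask].
#' @return percentage in \[0, 100\].
#' @export
percent_sa <- function(positive, tissue) {
  tis <- as_tissue_logical(tissue)
  if (!all(dim(positive) == dim(tis))) stop("mask shapes differ")
  n_tis <- sum(tis)
  if (n_tis == 0L) stop("empty tissue: %SA undefined")
  100 * sum(positive & tis) / n_tis
}

positive_mask <- function(classes) {
  classes >= PIXEL_CLASS_LEVELS[["WEAK"]]
}

#' Territorial percent stained area
#'
#' %SA of pixels that are positive (weak, moderate or strong) and located
#' in the territorial zone (intracellular, capsular or paracapsular).
#'
#' @param classes `pixel_class_map` from [classify_pixels()].
#' @param zones `zone_map` from [build_zones()].
#' @param tissue logical matrix or [tissue_mask].
#' @return percentage in \[0, 100\].
#' @export
territorial_sa <- function(classes, zones, tissue) {
  check_aligned(classes, zones)
  percent_sa(positive_mask(classes) & is_territorial(zones), tissue)
}

#' Interterritorial percent stained area
#'
#' %SA of positive pixels located in the interterritorial matrix,
#' peripheral to the territorial zone.
#'
#' @inheritParams territorial_sa
#' @return percentage in \[0, 100\].
#' @export
interterritorial_sa <- function(classes, zones, tissue) {
  check_aligned(classes, zones)
  percent_sa(positive_mask(classes) &
               zones == ZONE_LEVELS[["INTERTERRITORIAL"]], tissue)
}

check_aligned <- function(classes, zones) {
  if (!all(dim(classes) == dim(zones)))
    stop("class map and zone map shapes differ")
  invisible(TRUE)
}

#' H-score from pixel class fractions
#'
#' `100 * (1 * weak + 2 * moderate + 3 * strong)`, computed over tissue
#' pixel fractions; ranges from 0 (all negative) to 300 (all strong).
#'
#' @param ratios named fractions `c(negative, weak, moderate, strong)`
#'   summing to 1 (tolerance 1e-6), e.g. from [pixel_ratios()].
#' @return score in \[0, 300\].
#' @export
hscore <- function(ratios) {
  if (abs(sum(ratios) - 1) > 1e-6)
    stop("class fractions must sum to 1")
  s <- 100 * (ratios[["weak"]] + 2 * ratios[["moderate"]] +
              3 * ratios[["strong"]])
  min(max(s, 0), 300)
}

#' Full per-cylinder morphometry
#'
#' Runs the whole measurement chain on one core image: optical-density
#' transform, stain unmixing, tissue detection, nuclei segmentation,
#' zoning, pixel classification, and assembly of the measurement battery
#' (nuclei density and %SA, territorial and interterritorial VN %SA,
#' class ratios as percentages, H-score).
#'
#' @param image an [rgb_image].
#' @param config a [quant_config] bundling stain matrix, thresholds and
#'   segmentation/zoning parameters.
#' @param keep_maps if `TRUE`, attach the intermediate masks/maps as the
#'   `"maps"` attribute of the result.
#' @return one-row data.frame of class `core_metrics`.
#' @export
core_metrics <- function(image, config = quant_config(), keep_maps = FALSE) {
  stopifnot(inherits(image, "rgb_image"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  od <- stage("optical-density", rgb_to_od(image, config$i0, config$eps))
  conc <- stage("unmixing", unmix(od, config$stains))
  tissue <- stage("tissue-detection",
                  detect_tissue(image, config$od_floor,
                                config$close_radius_um, config$i0,
                                config$eps))
  nuc <- stage("nuclei-segmentation",
               segment_nuclei(conc[, , "hema"], tissue,
                              config$min_nucleus_area_um2,
                              config$max_nucleus_area_um2,
                              config$hema_threshold,
                              config$watershed_tolerance))
  zones <- stage("zoning",
                 suppressWarnings(build_zones(nuc, tissue, config$zone)))
  classes <- stage("classification",
                   classify_pixels(conc[, , "dab"], tissue,
                                   config$thresholds))
  ratios <- stage("class-ratios", pixel_ratios(classes))
  out <- data.frame(
    core_id = image$core_id,
    nuclei_density = nuclei_density(nuc, tissue),
    nuclei_sa = percent_sa(nuc$labels > 0L, tissue),
    inter_vn_sa = interterritorial_sa(classes, zones, tissue),
    terr_vn_sa = territorial_sa(classes, zones, tissue),
    ratio_weak = 100 * ratios[["weak"]],
    ratio_moderate = 100 * ratios[["moderate"]],
    ratio_strong = 100 * ratios[["strong"]],
    hscore = hscore(ratios),
    stringsAsFactors = FALSE
  )
  class(out) <- c("core_metrics", class(out))
  if (keep_maps)
    attr(out, "maps") <- list(tissue = tissue, nuclei = nuc, zones = zones,
                              classes = classes, concentrations = conc)
  out
}

#' Aggregate cylinder metrics into a case record
#'
#' Unweighted arithmetic mean of every numeric metric across the cylinders
#' of one case, with clinical metadata attached unchanged.  A case whose
#' averaged VN metrics are all zero is flagged `no_immunoreactivity`
#' (such samples are excluded from cohort statistics).
#'
#' @param cores data.frame of `core_metrics` rows (>= 1).
#' @param meta optional one-row data.frame of covariates and outcomes.
#' @param case_id identifier for the case.
#' @return one-row data.frame of class `case_record`.
#' @export
aggregate_case <- function(cores, meta = NULL, case_id = "case") {
  if (is.null(cores) || nrow(cores) == 0L)
    stop("at least one cylinder is required")
  num <- vapply(cores, is.numeric, logical(1))
  agg <- as.data.frame(as.list(colMeans(cores[, num, drop = FALSE])))
  out <- cbind(data.frame(case_id = case_id, n_cylinders = nrow(cores),
                          stringsAsFactors = FALSE), agg)
  out$no_immunoreactivity <-
    out$inter_vn_sa == 0 & out$terr_vn_sa == 0 & out$hscore == 0
  if (!is.null(meta)) {
    stopifnot(nrow(meta) == 1L)
    out <- cbind(out, meta[, setdiff(names(meta), names(out)), drop = FALSE])
  }
  class(out) <- c("case_record", class(out))
  out
}
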