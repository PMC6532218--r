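#' Quantification configuration
#'
#' Bundles every tunable of the image-analysis chain: the stain matrix,
#' optical-density constants, tissue/nuclei segmentation parameters,
#' intensity thresholds and zone band widths.  Echoed verbatim into run
#' manifests so outputs are regenerable from the manifest alone.
#'
#' @param stains 3 x 3 stain matrix ([stain_matrix_hdab()]).
#' @param thresholds [intensity_thresholds()].
#' @param zone [zone_params()].
#' @param i0,eps Beer-Lambert background intensity and log guard.
#' @param od_floor,close_radius_um tissue-detection parameters.
#' @param hema_threshold,min_nucleus_area_um2,max_nucleus_area_um2,watershed_tolerance
#'   nuclei-segmentation parameters.
#' @param um_per_px fallback physical scale used when an image file
#'   carries none.
#' @return list of class `quant_config`.
#' @export
quant_config <- function(stains = stain_matrix_hdab(),
                         thresholds = intensity_thresholds(),
                         zone = zone_params(),
                         i0 = 255, eps = 1, od_floor = 0.05,
                         close_radius_um = 3, hema_threshold = 0.4,
                         min_nucleus_area_um2 = 15,
                         max_nucleus_area_um2 = 400,
                         watershed_tolerance = 1, um_per_px = 1) {
  structure(list(stains = stains, thresholds = thresholds, zone = zone,
                 i0 = i0, eps = eps, od_floor = od_floor,
                 close_radius_um = close_radius_um,
                 hema_threshold = hema_threshold,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 max_nucleus_area_um2 = max_nucleus_area_um2,
                 watershed_tolerance = watershed_tolerance,
                 um_per_px = um_per_px),
            class = "quant_config")
}

#' Read a quantification configuration from YAML
#'
#' Unspecified fields keep their [quant_config()] defaults; `stains` may
#' be given as a list with `hema` and `dab` vectors.
#'
#' @param path YAML file.
#' @return a [quant_config].
#' @export
read_quant_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$stains))
    args$stains <- stain_matrix_hdab(unlist(y$stains$hema),
                                     unlist(y$stains$dab))
  if (!is.null(y$thresholds))
    args$thresholds <- do.call(intensity_thresholds, y$thresholds)
  if (!is.null(y$zone)) args$zone <- do.call(zone_params, y$zone)
  scalars <- intersect(names(y), c("i0", "eps", "od_floor",
                                   "close_radius_um", "hema_threshold",
                                   "min_nucleus_area_um2",
                                   "max_nucleus_area_um2",
                                   "watershed_tolerance", "um_per_px"))
  args <- c(args, y[scalars])
  do.call(quant_config, args)
}

# Serializable echo of a config (stain matrix flattened row-wise).
config_as_list <- function(config) {
  out <- unclass(config)
  out$stains <- list(hema = unname(config$stains["hema", ]),
                     dab = unname(config$stains["dab", ]),
                     residual = unname(config$stains["residual", ]))
  out$thresholds <- unclass(config$thresholds)
  out$zone <- unclass(config$zone)
  out
}

# Deterministic djb2 hash of the JSON-serialized config; recorded in run
# manifests so reruns can prove they used identical settings.
config_hash <- function(config) {
  s <- jsonlite::toJSON(config_as_list(config), auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Read a core image from PNG (or TIFF)
#'
#' @param path image file; PNG always supported, TIFF when the `tiff`
#'   package is available.
#' @param um_per_px physical scale to attach (raster files carry none).
#' @param core_id identifier; defaults to the file name.
#' @return an [rgb_image].
#' @export
read_core_image <- function(path, um_per_px = 1, core_id = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the `tiff` package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  if (is.null(core_id)) core_id <- tools::file_path_sans_ext(basename(path))
  rgb_image(round(arr * 255), um_per_px, core_id)
}

#' Write a core image to PNG
#'
#' @param image an [rgb_image].
#' @param path output path (.png).
#' @export
write_core_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Quantify one core image file
#'
#' Thin orchestration over [core_metrics()]: reads the image, computes the
#' per-cylinder measurement row, and writes the row as CSV together with a
#' JSON manifest echoing the configuration and its hash.
#'
#' @param image_path path to a PNG/TIFF core image.
#' @param config a [quant_config].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return the `core_metrics` row, invisibly carrying the manifest as
#'   attribute `"manifest"`.
#' @export
run_core <- function(image_path, config = quant_config(), out_dir = NULL) {
  image <- read_core_image(image_path, um_per_px = config$um_per_px)
  metrics <- core_metrics(image, config)
  manifest <- list(tool = "vitroquant", step = "quantify",
                   input = basename(image_path),
                   config = config_as_list(config),
                   config_hash = config_hash(config))
  attr(metrics, "manifest") <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    base <- tools::file_path_sans_ext(basename(image_path))
    utils::write.csv(metrics,
                     file.path(out_dir, paste0(base, "_metrics.csv")),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(base, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  metrics
}

# Column groups used by the cohort report.
vn_metric_cols <- function() c("nuclei_density", "nuclei_sa", "inter_vn_sa",
                               "terr_vn_sa", "ratio_weak", "ratio_moderate",
                               "ratio_strong", "hscore")
inrg_factor_cols <- function() c("age_ge18m", "stage_m", "hist_unb_pdnb",
                                 "mycn_mna", "profile_sca", "del_11q",
                                 "high_risk", "high_instability")

#' Cohort-level statistical report
#'
#' Joins per-case metrics with clinical metadata, excludes cases with no
#' immunoreactivity, and runs the full battery: Mann-Whitney tests of each
#' metric against each binary prognostic factor, Q3 dichotomization with
#' Kaplan-Meier / log-rank for EFS and OS, and Cox backward-Wald models of
#' each endpoint combining the INRG factors with the high-VN indicators
#' found significant by log-rank.  Degenerate tests are reported as NA
#' rows (with warnings) rather than failing the run.
#'
#' @param cases data.frame with the metric columns, binary factor columns
#'   and `efs_time`/`efs_event`/`os_time`/`os_event` (e.g. from
#'   [simulate_cohort()] or a join of [aggregate_case()] rows).
#' @param metrics which metric columns to analyze.
#' @param factors which binary factor columns to test against.
#' @param alpha significance level for log-rank screening (default 0.05).
#' @param alpha_stay Cox backward-elimination retention threshold.
#' @param out_dir output directory for tidy CSV/JSON reports; `NULL`
#'   skips writing.
#' @return list of class `cohort_report`: `rank_tests`, `survival_tests`,
#'   `cox` (per endpoint), `n_cases`, `n_excluded`.
#' @export
run_cohort <- function(cases, metrics = intersect(vn_metric_cols(),
                                                  names(cases)),
                       factors = intersect(inrg_factor_cols(),
                                           names(cases)),
                       alpha = 0.05, alpha_stay = 0.1, out_dir = NULL) {
  needed <- c("efs_time", "efs_event", "os_time", "os_event")
  missing_cols <- setdiff(needed, names(cases))
  if (length(missing_cols) > 0)
    stop("schema error, missing outcome columns: ",
         paste(missing_cols, collapse = ", "))
  if (length(metrics) == 0L) stop("no metric columns found")

  vn_cols <- intersect(c("inter_vn_sa", "terr_vn_sa", "hscore"),
                       names(cases))
  excluded <- if (length(vn_cols) > 0)
    rowSums(cases[, vn_cols, drop = FALSE] != 0) == 0
  else rep(FALSE, nrow(cases))
  n_excluded <- sum(excluded)
  cases <- cases[!excluded, , drop = FALSE]
  cases <- cases[order(cases$case_id %||% seq_len(nrow(cases))), ,
                 drop = FALSE]

  rank_tests <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(factors, function(f) {
      res <- tryCatch(mann_whitney(cases[[m]], cases[[f]] > 0),
                      error = function(e) NULL,
                      warning = function(w) NULL)
      data.frame(metric = m, factor = f,
                 u = if (is.null(res)) NA_real_ else res$u,
                 p_value = if (is.null(res)) NA_real_ else res$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(rank_tests) && anyNA(rank_tests$p_value))
    warning("some rank tests were degenerate and reported as NA")

  endpoints <- list(EFS = c("efs_time", "efs_event"),
                    OS = c("os_time", "os_event"))
  survival_tests <- do.call(rbind, lapply(metrics, function(m) {
    dich <- tryCatch(q3_dichotomize(cases[[m]]),
                     warning = function(w) NULL, error = function(e) NULL)
    do.call(rbind, lapply(names(endpoints), function(ep) {
      cols <- endpoints[[ep]]
      res <- if (is.null(dich)) NULL else
        tryCatch(logrank_test(cases[[cols[1]]], cases[[cols[2]]],
                              dich$high),
                 error = function(e) NULL)
      rate <- function(high) {
        if (is.null(dich)) return(NA_real_)
        sel <- dich$high == high
        if (!any(sel)) return(NA_real_)
        km_estimate(cases[[cols[1]]][sel],
                    cases[[cols[2]]][sel])$rate_at_horizon
      }
      data.frame(metric = m, endpoint = ep,
                 q3 = if (is.null(dich)) NA_real_ else dich$threshold,
                 chisq = if (is.null(res)) NA_real_ else res$chisq,
                 p_value = if (is.null(res)) NA_real_ else res$p_value,
                 rate5y_high = rate(TRUE), rate5y_low = rate(FALSE),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(survival_tests) && anyNA(survival_tests$p_value))
    warning("some survival tests were degenerate and reported as NA")

  cox <- lapply(names(endpoints), function(ep) {
    cols <- endpoints[[ep]]
    sig <- survival_tests$metric[survival_tests$endpoint == ep &
                                 !is.na(survival_tests$p_value) &
                                 survival_tests$p_value < alpha]
    covs <- intersect(factors, names(cases))
    dat <- cases
    for (m in sig) {
      ind <- paste0("high_", m)
      dat[[ind]] <- as.integer(q3_dichotomize(dat[[m]])$high)
      covs <- c(covs, ind)
    }
    if (length(covs) == 0L) return(NULL)
    tryCatch(cox_backward(dat, cols[1], cols[2], covs,
                          alpha_stay = alpha_stay),
             error = function(e) NULL)
  })
  names(cox) <- names(endpoints)

  report <- structure(list(rank_tests = rank_tests,
                           survival_tests = survival_tests, cox = cox,
                           n_cases = nrow(cases),
                           n_excluded = n_excluded,
                           alpha = alpha, alpha_stay = alpha_stay),
                      class = "cohort_report")
  if (!is.null(out_dir)) write_cohort_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_cohort_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$rank_tests,
                   file.path(out_dir, "rank_tests.csv"), row.names = FALSE)
  utils::write.csv(report$survival_tests,
                   file.path(out_dir, "survival_tests.csv"),
                   row.names = FALSE)
  for (ep in names(report$cox)) {
    if (!is.null(report$cox[[ep]]))
      utils::write.csv(report$cox[[ep]]$table,
                       file.path(out_dir, paste0("cox_", tolower(ep),
                                                 ".csv")),
                       row.names = FALSE)
  }
  summary <- list(n_cases = report$n_cases,
                  n_excluded = report$n_excluded,
                  alpha = report$alpha, alpha_stay = report$alpha_stay,
                  cox_retained = lapply(report$cox, function(x)
                    if (is.null(x)) character(0) else x$retained))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d cases analyzed (%d excluded for no immunoreactivity)\n",
              x$n_cases, x$n_excluded))
  sig <- x$rank_tests[!is.na(x$rank_tests$p_value) &
                      x$rank_tests$p_value < x$alpha, ]
  cat(sprintf("rank tests significant at %.2g: %d of %d\n", x$alpha,
              nrow(sig), nrow(x$rank_tests)))
  for (ep in names(x$cox)) {
    if (!is.null(x$cox[[ep]]))
      cat(sprintf("Cox %s retained: %s\n", ep,
                  paste(x$cox[[ep]]$retained, collapse = ", ")))
  }
  invisible(x)
}
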