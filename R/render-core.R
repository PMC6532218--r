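#' Specification of a synthetic TMA core
#'
#' Parameters of the forward model that renders an IHC-like cylinder:
#' nuclei counterstained with hematoxylin, plus DAB deposits placed either
#' in the territorial zone (intracellular + pericellular bands, the strong
#' pattern), the interterritorial matrix (the weak-to-moderate pattern),
#' or both.  Defaults emulate a down-scaled 1 mm cylinder at a nuclei
#' density in the range observed for neuroblastoma cores.
#'
#' @param width_px,height_px image size in pixels.
#' @param um_per_px physical scale (micrometres per pixel).
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_um length-2 vector `c(mean, sd)` of nuclear radii
#'   in micrometres.
#' @param pattern one of `"TERRITORIAL"`, `"INTERTERRITORIAL"`, `"MIXED"`,
#'   `"NONE"`.
#' @param class_mix named fractions `c(weak, moderate, strong)` among
#'   positive pixels; must sum to at most 1 (renormalized internally).
#' @param target_positive_fraction fraction of tissue area stained.
#' @param seed RNG seed; identical specs render bit-identical cores.
#' @param od_noise_sd Gaussian noise sd added in OD space (0 = noise-free).
#' @param cluster_size mean number of nuclei per nest cluster.
#' @param cluster_sd_um spatial spread of a nest cluster.
#' @param tissue_radius_frac cylinder radius as a fraction of the half
#'   image size.
#' @param hema_tissue,hema_nucleus hematoxylin concentration of the faint
#'   tissue tint and of nuclei.
#' @param dab_levels DAB concentrations rendered for weak/moderate/strong
#'   pixels.
#' @param zone [zone_params] used both to define ground-truth zones and as
#'   the analysis default.
#' @return list of class `core_spec`.
#' @export
core_spec <- function(width_px = 384, height_px = 384, um_per_px = 1,
                      n_nuclei = 75, nucleus_radius_um = c(4, 0.5),
                      pattern = c("MIXED", "TERRITORIAL",
                                  "INTERTERRITORIAL", "NONE"),
                      class_mix = c(weak = 0.25, moderate = 0.35,
                                    strong = 0.40),
                      target_positive_fraction = 0.15, seed = 1L,
                      od_noise_sd = 0.01, cluster_size = 8,
                      cluster_sd_um = 25, tissue_radius_frac = 0.94,
                      hema_tissue = 0.08, hema_nucleus = 0.85,
                      dab_levels = c(weak = 0.25, moderate = 0.55,
                                     strong = 0.95),
                      zone = zone_params()) {
  pattern <- match.arg(pattern)
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               um_per_px = um_per_px, n_nuclei = as.integer(n_nuclei),
               nucleus_radius_um = nucleus_radius_um, pattern = pattern,
               class_mix = class_mix,
               target_positive_fraction = target_positive_fraction,
               seed = as.integer(seed), od_noise_sd = od_noise_sd,
               cluster_size = cluster_size, cluster_sd_um = cluster_sd_um,
               tissue_radius_frac = tissue_radius_frac,
               hema_tissue = hema_tissue, hema_nucleus = hema_nucleus,
               dab_levels = dab_levels, zone = zone)
  validate_core_spec(spec)
  structure(spec, class = "core_spec")
}

validate_core_spec <- function(s) {
  stopifnot(s$width_px > 0, s$height_px > 0, s$um_per_px > 0,
            s$n_nuclei >= 0, length(s$nucleus_radius_um) == 2,
            s$nucleus_radius_um[1] > 0, s$nucleus_radius_um[2] >= 0,
            s$od_noise_sd >= 0)
  if (s$target_positive_fraction < 0 || s$target_positive_fraction > 1)
    stop("target_positive_fraction must lie in [0, 1]")
  cm <- s$class_mix
  if (any(cm < 0) || any(cm > 1) || sum(cm) > 1 + 1e-9)
    stop("class_mix entries must lie in [0, 1] and sum to <= 1")
  if (s$pattern != "NONE" && s$target_positive_fraction > 0 && sum(cm) <= 0)
    stop("class_mix must have positive mass when staining is requested")
  invisible(s)
}

#' Render a synthetic IHC core with exact ground truth
#'
#' Forward model: nuclei are placed in Poisson-cluster nests inside a
#' circular tissue disc (rejection-sampled so that no two nuclei fully
#' overlap); DAB deposits are sampled per pixel inside the zone dictated
#' by `spec$pattern`; per-pixel optical density is the stain-vector mix of
#' hematoxylin and DAB concentrations (plus optional Gaussian OD noise)
#' and transmitted intensity follows Beer-Lambert,
#' `v = round(i0 * 10^-OD)`.  Ground truth masks, zone and class maps and
#' the derived scalar metrics are returned alongside the image.
#'
#' @param spec a [core_spec].
#' @param i0 incident intensity (default 255).
#' @return list with elements `image` ([rgb_image]) and `truth`
#'   (class `ground_truth`: `nuclei_mask`, `cell_mask`, `tissue_mask`,
#'   `zone_map_true`, `class_map_true`, `true_terr_sa`, `true_inter_sa`,
#'   `true_nuclei_density`, `true_hscore`, `true_class_fractions`).
#' @export
render_core <- function(spec, i0 = 255) {
  stopifnot(inherits(spec, "core_spec"))
  validate_core_spec(spec)
  withr::with_seed(spec$seed, render_core_impl(spec, i0))
}

render_core_impl <- function(spec, i0) {
  h <- spec$height_px; w <- spec$width_px; upp <- spec$um_per_px
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r_tis <- spec$tissue_radius_frac * min(h, w) / 2
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  tissue <- (rows - cy)^2 + (cols - cx)^2 <= r_tis^2
  n_tissue <- sum(tissue)

  nuc <- place_nuclei(spec, cy, cx, r_tis)
  nuclei_mask <- rasterize_nuclei(nuc, h, w, upp)
  labels <- new_nuclei_labels(nuclei_mask)
  tmask <- new_tissue_mask(tissue, upp)
  zones <- suppressWarnings(build_zones(labels, tmask, spec$zone))

  cls <- matrix(PIXEL_CLASS_LEVELS[["NEGATIVE"]], h, w)
  f <- if (spec$pattern == "NONE") 0 else spec$target_positive_fraction
  n_pos <- round(f * n_tissue)
  if (n_pos > 0) {
    terr <- is_territorial(zones) & tissue
    allowed <- switch(spec$pattern,
      TERRITORIAL = which(terr),
      INTERTERRITORIAL = which(!terr & tissue),
      MIXED = which(tissue))
    if (length(allowed) < n_pos) {
      warning("requested positive fraction exceeds the pattern zone; ",
              "spilling over into remaining tissue")
      extra <- setdiff(which(tissue), allowed)
      pos_idx <- c(allowed, sample(extra, n_pos - length(allowed)))
    } else {
      pos_idx <- sample(allowed, n_pos)
    }
    cls[pos_idx] <- assign_classes(spec, pos_idx, terr)
  }
  cls[!tissue] <- PIXEL_CLASS_LEVELS[["NON_TISSUE"]]
  class_map <- structure(cls, class = c("pixel_class_map", "matrix", "array"),
                         levels = PIXEL_CLASS_LEVELS)

  conc <- array(0, dim = c(h, w, 3),
                dimnames = list(NULL, NULL, c("hema", "dab", "residual")))
  hema <- matrix(0, h, w)
  hema[tissue] <- spec$hema_tissue
  hema[nuclei_mask > 0L] <- spec$hema_nucleus
  dab <- matrix(0, h, w)
  dab[cls == PIXEL_CLASS_LEVELS[["WEAK"]]] <- spec$dab_levels[["weak"]]
  dab[cls == PIXEL_CLASS_LEVELS[["MODERATE"]]] <- spec$dab_levels[["moderate"]]
  dab[cls == PIXEL_CLASS_LEVELS[["STRONG"]]] <- spec$dab_levels[["strong"]]
  conc[, , 1] <- hema; conc[, , 2] <- dab
  od <- mix_stains(conc)
  if (spec$od_noise_sd > 0)
    od <- od + array(stats::rnorm(length(od), 0, spec$od_noise_sd), dim(od))
  px <- pmin(pmax(round(i0 * 10^(-od)), 0), 255)

  fracs <- tabulate(cls[tissue] - 0L, nbins = 4L) / n_tissue
  names(fracs) <- c("negative", "weak", "moderate", "strong")
  positive <- cls >= PIXEL_CLASS_LEVELS[["WEAK"]]
  truth <- structure(list(
    nuclei_mask = nuclei_mask,
    cell_mask = cell_regions(labels, upp, spec$zone),
    tissue_mask = tissue,
    zone_map_true = zones,
    class_map_true = class_map,
    true_terr_sa = 100 * sum(positive & is_territorial(zones)) / n_tissue,
    true_inter_sa = 100 *
      sum(positive & zones == ZONE_LEVELS[["INTERTERRITORIAL"]]) / n_tissue,
    true_nuclei_density = labels$n_objects / (n_tissue * (upp / 1000)^2),
    true_hscore = min(300, 100 * (fracs[["weak"]] + 2 * fracs[["moderate"]] +
                                  3 * fracs[["strong"]])),
    true_class_fractions = fracs,
    n_nuclei_placed = labels$n_objects
  ), class = "ground_truth")

  list(image = rgb_image(px, upp, core_id = sprintf("synthetic-%d", spec$seed)),
       truth = truth)
}

# Poisson-cluster nucleus placement with rejection sampling; errors when
# the geometry cannot accommodate the requested count.
place_nuclei <- function(spec, cy, cx, r_tis) {
  n <- spec$n_nuclei
  if (n == 0L) return(data.frame(row = numeric(0), col = numeric(0),
                                 r_px = numeric(0)))
  upp <- spec$um_per_px
  radii_px <- pmax(1, stats::rnorm(n, spec$nucleus_radius_um[1],
                                   spec$nucleus_radius_um[2]) / upp)
  n_clusters <- max(1L, round(n / spec$cluster_size))
  th <- stats::runif(n_clusters, 0, 2 * pi)
  rr <- r_tis * 0.8 * sqrt(stats::runif(n_clusters))
  centers <- cbind(cy + rr * sin(th), cx + rr * cos(th))
  assign <- sample(n_clusters, n, replace = TRUE)
  sd_px <- spec$cluster_sd_um / upp
  placed <- matrix(numeric(0), 0, 2)
  placed_r <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(400L)) {
      # first 200 tries near the assigned cluster, then anywhere
      if (attempt <= 200L) {
        p <- centers[assign[i], ] + stats::rnorm(2, 0, sd_px)
      } else {
        a <- stats::runif(1, 0, 2 * pi)
        d <- (r_tis - radii_px[i] - 1) * sqrt(stats::runif(1))
        p <- c(cy + d * sin(a), cx + d * cos(a))
      }
      if (sqrt((p[1] - cy)^2 + (p[2] - cx)^2) > r_tis - radii_px[i] - 1) next
      if (nrow(placed) > 0) {
        dd <- sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2)
        if (any(dd < 0.95 * (placed_r + radii_px[i]))) next
      }
      placed <- rbind(placed, p)
      placed_r <- c(placed_r, radii_px[i])
      ok <- TRUE
      break
    }
    if (!ok) stop("impossible geometry: could not place nucleus ", i,
                  " of ", n, " without overlap")
  }
  data.frame(row = placed[, 1], col = placed[, 2], r_px = placed_r)
}

rasterize_nuclei <- function(nuc, h, w, upp) {
  lab <- matrix(0L, h, w)
  for (i in seq_len(nrow(nuc))) {
    r <- nuc$r_px[i]
    r0 <- max(1L, floor(nuc$row[i] - r)); r1 <- min(h, ceiling(nuc$row[i] + r))
    c0 <- max(1L, floor(nuc$col[i] - r)); c1 <- min(w, ceiling(nuc$col[i] + r))
    rs <- r0:r1; cs <- c0:c1
    sub <- outer((rs - nuc$row[i])^2, (cs - nuc$col[i])^2, "+") <= r^2
    block <- lab[rs, cs, drop = FALSE]
    block[sub & block == 0L] <- i
    lab[rs, cs] <- block
  }
  lab
}

# Class assignment for positive pixels: the two pure patterns follow
# class_mix; the MIXED pattern ties intensity to location (territorial ->
# strong, interterritorial -> weak/moderate in class_mix proportion),
# matching the staining association the analysis is designed to detect.
assign_classes <- function(spec, pos_idx, terr) {
  n_pos <- length(pos_idx)
  codes <- c(PIXEL_CLASS_LEVELS[["WEAK"]], PIXEL_CLASS_LEVELS[["MODERATE"]],
             PIXEL_CLASS_LEVELS[["STRONG"]])
  if (spec$pattern == "MIXED") {
    out <- integer(n_pos)
    in_terr <- terr[pos_idx]
    out[in_terr] <- PIXEL_CLASS_LEVELS[["STRONG"]]
    wm <- spec$class_mix[c("weak", "moderate")]
    if (sum(wm) <= 0) wm <- c(weak = 0.5, moderate = 0.5)
    n_out <- sum(!in_terr)
    out[!in_terr] <- sample(codes[1:2], n_out, replace = TRUE,
                            prob = wm / sum(wm))
    return(out)
  }
  p <- spec$class_mix / sum(spec$class_mix)
  counts <- floor(p * n_pos)
  rem <- n_pos - sum(counts)
  if (rem > 0) {
    ord <- order(p * n_pos - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  v <- rep(codes, times = counts)
  v[sample.int(length(v))]
}
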