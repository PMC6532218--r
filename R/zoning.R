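# Integer codes for spatial zones.  INTRACELLULAR + CAPSULAR + PARACAPSULAR
# together form the territorial zone; INTERTERRITORIAL is the matrix
# peripheral to it.
ZONE_LEVELS <- c(
  NON_TISSUE = 0L, INTRACELLULAR = 1L, CAPSULAR = 2L,
  PARACAPSULAR = 3L, INTERTERRITORIAL = 4L
)

#' Detect the tissue cylinder in a brightfield image
#'
#' Thresholds total optical density against `od_floor`, applies a
#' morphological closing and hole fill, and keeps the largest connected
#' component (the TMA cylinder).  The resulting area is the denominator of
#' every percent-stained-area measurement.
#'
#' @param image an [rgb_image].
#' @param od_floor minimum summed per-channel OD for a tissue pixel.
#' @param close_radius_um radius of the closing brush in micrometres.
#' @param i0,eps background intensity and log guard, as in [rgb_to_od()].
#' @return Object of class `tissue_mask`: list with logical `mask`,
#'   `tissue_area_mm2` and `um_per_px`.
#' @export
detect_tissue <- function(image, od_floor = 0.05, close_radius_um = 3,
                          i0 = 255, eps = 1) {
  stopifnot(inherits(image, "rgb_image"))
  od <- rgb_to_od(image, i0 = i0, eps = eps)
  tot <- od[, , 1] + od[, , 2] + od[, , 3]
  raw <- tot > od_floor
  if (!any(raw)) stop("empty core: no pixel exceeds the OD floor")
  m <- raw + 0
  r_px <- max(0L, round(close_radius_um / image$um_per_px))
  if (r_px > 0) m <- EBImage::closing(m, disc_brush(r_px))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0L])
    m <- (lab == which.max(sizes)) + 0
  }
  mask <- m > 0
  new_tissue_mask(mask, image$um_per_px)
}

new_tissue_mask <- function(mask, um_per_px) {
  structure(list(
    mask = mask,
    tissue_area_mm2 = sum(mask) * (um_per_px / 1000)^2,
    um_per_px = um_per_px
  ), class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d px, %.4f mm2 at %.3g um/px\n",
              sum(x$mask), x$tissue_area_mm2, x$um_per_px))
  invisible(x)
}

# Odd-sized disc brush of pixel radius r for EBImage morphology.
disc_brush <- function(r_px) EBImage::makeBrush(2L * as.integer(r_px) + 1L, "disc")

#' Segment nuclei from the hematoxylin channel
#'
#' Thresholds hematoxylin concentration inside tissue, splits touching
#' blobs by a watershed on the Euclidean distance transform, and discards
#' objects outside the plausible nuclear area range.
#'
#' @param hema numeric matrix of hematoxylin concentrations (from
#'   [unmix()]).
#' @param tissue a [tissue_mask].
#' @param min_area_um2,max_area_um2 retained object area bounds in square
#'   micrometres.
#' @param conc_threshold hematoxylin concentration above which a pixel is
#'   nuclear.
#' @param watershed_tolerance minimum peak-to-saddle height separating two
#'   objects in the distance map (pixels).
#' @return Object of class `nuclei_labels`: integer label matrix `labels`
#'   (0 = background, 1..n contiguous), `n_objects`, and `centroids`
#'   (n x 2 matrix of row/col centers).
#' @export
segment_nuclei <- function(hema, tissue, min_area_um2 = 15,
                           max_area_um2 = 400, conc_threshold = 0.4,
                           watershed_tolerance = 1) {
  stopifnot(inherits(tissue, "tissue_mask"))
  if (!all(is.finite(hema))) stop("hematoxylin field contains non-finite values")
  if (!(min_area_um2 > 0 && max_area_um2 > min_area_um2))
    stop("area bounds must be positive with min < max")
  if (!all(dim(hema) == dim(tissue$mask))) stop("field/mask shape mismatch")
  bw <- (hema > conc_threshold) & tissue$mask
  if (!any(bw)) return(new_nuclei_labels(matrix(0L, nrow(hema), ncol(hema))))
  d <- EBImage::distmap(bw + 0)
  lab <- EBImage::watershed(d, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(lab), nrow = nrow(hema))
  px_area_um2 <- tissue$um_per_px^2
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * px_area_um2 >= min_area_um2 &
                sizes * px_area_um2 <= max_area_um2)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- remap[lab[pos]]
  new_nuclei_labels(out)
}

new_nuclei_labels <- function(labels) {
  n <- max(labels)
  centroids <- if (n > 0) {
    idx <- which(labels > 0L, arr.ind = TRUE)
    lb <- labels[labels > 0L]
    cbind(row = tapply(idx[, 1], lb, mean), col = tapply(idx[, 2], lb, mean))
  } else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  structure(list(labels = labels, n_objects = as.integer(n),
                 centroids = centroids),
            class = "nuclei_labels")
}

#' @export
print.nuclei_labels <- function(x, ...) {
  cat(sprintf("<nuclei_labels> %d objects\n", x$n_objects))
  invisible(x)
}

#' Nuclei density in objects per square millimetre
#'
#' @param labels a `nuclei_labels` object.
#' @param tissue a [tissue_mask] with positive area.
#' @return objects / mm^2.
#' @export
nuclei_density <- function(labels, tissue) {
  stopifnot(inherits(labels, "nuclei_labels"), inherits(tissue, "tissue_mask"))
  if (tissue$tissue_area_mm2 <= 0) stop("tissue area is zero")
  labels$n_objects / tissue$tissue_area_mm2
}

#' Zoning parameters (physical band widths)
#'
#' Band widths, in micrometres, of the pericellular architecture: the cell
#' region is the nucleus grown by `cyto_dilation_um`; cells closer than
#' `nest_gap_um` merge into nests; the capsular band hugs the cell/nest
#' boundary and the paracapsular band surrounds it.
#'
#' @param cyto_dilation_um cytoplasmic growth beyond the nucleus.
#' @param capsular_width_um width of the capsular band.
#' @param paracapsular_width_um width of the paracapsular band.
#' @param nest_gap_um maximum gap closed between neighbouring cells.
#' @return list of class `zone_params`.
#' @export
zone_params <- function(cyto_dilation_um = 3, capsular_width_um = 2,
                        paracapsular_width_um = 3, nest_gap_um = 5) {
  p <- list(cyto_dilation_um = cyto_dilation_um,
            capsular_width_um = capsular_width_um,
            paracapsular_width_um = paracapsular_width_um,
            nest_gap_um = nest_gap_um)
  if (any(unlist(p) < 0)) stop("zone widths must be >= 0")
  structure(p, class = "zone_params")
}

#' Partition a core into territorial / interterritorial zones
#'
#' Cell regions are nuclei dilated by `cyto_dilation_um`; a morphological
#' closing with a `nest_gap_um`-diameter disc merges neighbouring cells
#' into nests.  Euclidean distance (in micrometres) from the nest boundary
#' then defines the CAPSULAR band (distance in `(0, capsular_width_um]`)
#' and PARACAPSULAR band (next `paracapsular_width_um`); remaining tissue
#' is INTERTERRITORIAL and everything outside tissue NON_TISSUE.
#'
#' @param labels a `nuclei_labels` object (empty set allowed: the whole
#'   tissue becomes INTERTERRITORIAL with a warning).
#' @param tissue a [tissue_mask].
#' @param params a [zone_params] object.
#' @return integer matrix of class `zone_map` with codes `ZONE_LEVELS`.
#' @export
build_zones <- function(labels, tissue, params = zone_params()) {
  stopifnot(inherits(labels, "nuclei_labels"), inherits(tissue, "tissue_mask"))
  if (!inherits(params, "zone_params"))
    params <- do.call(zone_params, as.list(params))
  upp <- tissue$um_per_px
  zm <- matrix(ZONE_LEVELS[["INTERTERRITORIAL"]],
               nrow(labels$labels), ncol(labels$labels))
  if (labels$n_objects == 0L) {
    warning("no nuclei: whole tissue labelled interterritorial")
    zm[!tissue$mask] <- ZONE_LEVELS[["NON_TISSUE"]]
    return(new_zone_map(zm))
  }
  cell <- cell_regions(labels, upp, params)
  dist_um <- EBImage::distmap((!cell) + 0) * upp
  cap <- !cell & dist_um <= params$capsular_width_um
  para <- !cell & !cap &
    dist_um <= params$capsular_width_um + params$paracapsular_width_um
  zm[cell] <- ZONE_LEVELS[["INTRACELLULAR"]]
  zm[cap] <- ZONE_LEVELS[["CAPSULAR"]]
  zm[para] <- ZONE_LEVELS[["PARACAPSULAR"]]
  zm[!tissue$mask] <- ZONE_LEVELS[["NON_TISSUE"]]
  new_zone_map(zm)
}

# Nucleus dilation + nest closing; shared by build_zones and the renderer.
cell_regions <- function(labels, um_per_px, params) {
  bw <- labels$labels > 0L
  r_cyto <- round(params$cyto_dilation_um / um_per_px)
  m <- bw + 0
  if (r_cyto > 0) m <- EBImage::dilate(m, disc_brush(r_cyto))
  r_nest <- round(params$nest_gap_um / (2 * um_per_px))
  if (r_nest > 0) m <- EBImage::closing(m, disc_brush(r_nest))
  m > 0
}

new_zone_map <- function(zm) {
  structure(zm, class = c("zone_map", class(zm)), levels = ZONE_LEVELS)
}

# Territorial-zone membership helper.
is_territorial <- function(zones) {
  zones == ZONE_LEVELS[["INTRACELLULAR"]] |
    zones == ZONE_LEVELS[["CAPSULAR"]] |
    zones == ZONE_LEVELS[["PARACAPSULAR"]]
}
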