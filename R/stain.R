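# Integer codes for per-pixel intensity classes.  NON_TISSUE pixels lie
# outside the detected tissue disc; the remaining four classes partition
# tissue pixels by DAB concentration.
PIXEL_CLASS_LEVELS <- c(
  NON_TISSUE = 0L, NEGATIVE = 1L, WEAK = 2L, MODERATE = 3L, STRONG = 4L
)

#' Construct a brightfield RGB core image
#'
#' Container for a digitized tissue-microarray cylinder: an H x W x 3 array
#' of channel intensities on the 0-255 scale plus the physical pixel size.
#'
#' @param pixels numeric H x W x 3 array, values in \[0, 255\].
#' @param um_per_px physical scale in micrometres per pixel (> 0).
#' @param core_id identifier string for the cylinder.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, um_per_px, core_id = "core") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (any(dim(pixels)[1:2] < 1L)) stop("image dimensions must be positive")
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || um_per_px <= 0)
    stop("`um_per_px` must be a single positive number")
  structure(list(pixels = pixels, um_per_px = um_per_px,
                 core_id = as.character(core_id)),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %s: %d x %d px, %.3g um/px\n",
              x$core_id, d[1], d[2], x$um_per_px))
  invisible(x)
}

#' Hematoxylin / DAB stain matrix
#'
#' Standard published optical-density vectors for hematoxylin and DAB
#' (Ruifrok-Johnston style), with a residual axis completing the basis as
#' the unit cross product of the two stain vectors.  Rows are unit length;
#' the hematoxylin and DAB rows are non-negative.
#'
#' @param hema,dab optional length-3 replacement vectors (will be
#'   normalized to unit length).
#' @return 3 x 3 matrix with rows `hema`, `dab`, `residual` and columns
#'   `R`, `G`, `B`.
#' @export
stain_matrix_hdab <- function(hema = c(0.650, 0.704, 0.286),
                              dab = c(0.268, 0.570, 0.776)) {
  unit <- function(v) v / sqrt(sum(v^2))
  if (length(hema) != 3L || length(dab) != 3L)
    stop("stain vectors must have length 3")
  if (any(hema < 0) || any(dab < 0))
    stop("hematoxylin and DAB stain vectors must be non-negative")
  h <- unit(hema); d <- unit(dab)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  if (sqrt(sum(r^2)) < 1e-6)
    stop("hematoxylin and DAB vectors are collinear")
  m <- rbind(hema = h, dab = d, residual = unit(r))
  colnames(m) <- c("R", "G", "B")
  validate_stain_matrix(m)
  m
}

validate_stain_matrix <- function(m) {
  if (!is.matrix(m) || any(dim(m) != 3L)) stop("stain matrix must be 3 x 3")
  norms <- sqrt(rowSums(m^2))
  if (any(abs(norms - 1) > 1e-6)) stop("stain matrix rows must be unit length")
  if (kappa(m) > 1e8) stop("stain matrix is ill-conditioned")
  invisible(m)
}

#' Convert an RGB image to per-channel optical density
#'
#' Beer-Lambert transform `OD = -log10((v + eps) / i0)` applied per channel.
#' The additive guard `eps` avoids infinite density at fully absorbed
#' (zero-intensity) pixels.
#'
#' @param image an [rgb_image] or a raw H x W x 3 array on the 0-255 scale.
#' @param i0 incident (background) intensity, default 255.
#' @param eps additive guard on the 0-255 scale, default 1.
#' @return H x W x 3 numeric array of optical densities.
#' @export
rgb_to_od <- function(image, i0 = 255, eps = 1) {
  px <- if (inherits(image, "rgb_image")) image$pixels else image
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("input must have 3 channels")
  if (i0 <= 0) stop("`i0` must be positive")
  -log10((px + eps) / i0)
}

#' Unmix optical densities into per-stain concentrations
#'
#' Solves the linear system `OD = concentrations %*% stains` per pixel and
#' clips negative solutions to zero.  Where concentrations are non-negative
#' the round trip `mix_stains(unmix(od))` reproduces `od`.
#'
#' @param od H x W x 3 optical-density array from [rgb_to_od()].
#' @param stains 3 x 3 stain matrix, rows `hema`/`dab`/`residual`
#'   (see [stain_matrix_hdab()]).
#' @return H x W x 3 array of stain concentrations, third dimension named
#'   `hema`, `dab`, `residual`.
#' @export
unmix <- function(od, stains = stain_matrix_hdab()) {
  validate_stain_matrix(stains)
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L) stop("`od` must be H x W x 3")
  if (any(!is.finite(od))) stop("`od` contains non-finite values")
  flat <- matrix(od, ncol = 3L)
  conc <- flat %*% solve(stains)
  conc[conc < 0] <- 0
  out <- array(conc, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(stains))
  out
}

#' Forward mix of stain concentrations into optical densities
#'
#' Inverse of [unmix()]: `OD = concentrations %*% stains`.  Used by the
#' synthetic renderer and by round-trip tests.
#'
#' @inheritParams unmix
#' @param conc H x W x 3 concentration array (hema, dab, residual).
#' @return H x W x 3 optical-density array.
#' @export
mix_stains <- function(conc, stains = stain_matrix_hdab()) {
  d <- dim(conc)
  if (length(d) != 3L || d[3] != 3L) stop("`conc` must be H x W x 3")
  array(matrix(conc, ncol = 3L) %*% stains, dim = d)
}

#' DAB intensity thresholds
#'
#' Cutpoints on the DAB-concentration axis separating negative, weak,
#' moderate and strong pixels.  The defaults are calibrated on the
#' synthetic renderer so that noise-free generated classes are recovered;
#' they play the role of the restrictive segmentation values a scanner
#' macro would be tuned to on control tissue.
#'
#' @param t_pos positive-vs-negative cutpoint.
#' @param t_weak_mod weak-vs-moderate cutpoint.
#' @param t_mod_strong moderate-vs-strong cutpoint.
#' @return list of class `intensity_thresholds`.
#' @export
intensity_thresholds <- function(t_pos = 0.10, t_weak_mod = 0.40,
                                 t_mod_strong = 0.75) {
  if (!(t_pos > 0 && t_pos < t_weak_mod && t_weak_mod < t_mod_strong))
    stop("thresholds must satisfy 0 < t_pos < t_weak_mod < t_mod_strong")
  structure(list(t_pos = t_pos, t_weak_mod = t_weak_mod,
                 t_mod_strong = t_mod_strong),
            class = "intensity_thresholds")
}

#' Classify pixels by DAB concentration
#'
#' Pixels outside the tissue mask are NON_TISSUE.  Tissue pixels fall into
#' half-open concentration intervals `[0, t_pos)` NEGATIVE,
#' `[t_pos, t_weak_mod)` WEAK, `[t_weak_mod, t_mod_strong)` MODERATE and
#' `[t_mod_strong, Inf)` STRONG; a value exactly on a cutpoint promotes to
#' the higher class.
#'
#' @param dab numeric matrix of DAB concentrations.
#' @param tissue logical matrix (or [tissue_mask]) of tissue pixels.
#' @param thresholds an [intensity_thresholds] object.
#' @return integer matrix of class `pixel_class_map` with codes
#'   `PIXEL_CLASS_LEVELS` (0 NON_TISSUE ... 4 STRONG).
#' @export
classify_pixels <- function(dab, tissue, thresholds = intensity_thresholds()) {
  tis <- as_tissue_logical(tissue)
  if (!all(dim(dab) == dim(tis)))
    stop("`dab` and `tissue` shapes differ")
  if (!inherits(thresholds, "intensity_thresholds"))
    thresholds <- do.call(intensity_thresholds, as.list(thresholds))
  cuts <- c(thresholds$t_pos, thresholds$t_weak_mod, thresholds$t_mod_strong)
  cls <- matrix(findInterval(dab, cuts) + 1L, nrow = nrow(dab))
  cls[!tis] <- PIXEL_CLASS_LEVELS[["NON_TISSUE"]]
  structure(cls, class = c("pixel_class_map", class(cls)),
            levels = PIXEL_CLASS_LEVELS)
}

#' Class fractions among tissue pixels
#'
#' Fractions of NEGATIVE / WEAK / MODERATE / STRONG pixels within tissue;
#' always sums to 1.
#'
#' @param classes a `pixel_class_map` from [classify_pixels()].
#' @return named numeric vector `c(negative, weak, moderate, strong)`.
#' @export
pixel_ratios <- function(classes) {
  counts <- tabulate(classes[classes >= 1L], nbins = 4L)
  n <- sum(counts)
  if (n == 0L) stop("no tissue pixels: cannot compute class ratios")
  stats::setNames(counts / n, c("negative", "weak", "moderate", "strong"))
}

# Accept either a plain logical matrix or a tissue_mask object.
as_tissue_logical <- function(tissue) {
  if (inherits(tissue, "tissue_mask")) tissue$mask
  else if (is.logical(tissue) && is.matrix(tissue)) tissue
  else if (is.matrix(tissue)) tissue > 0
  else stop("`tissue` must be a logical matrix or tissue_mask")
}
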