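test_that("tissue detection finds the cylinder and measures its area", {
  white <- rgb_image(array(255, c(32, 32, 3)), um_per_px = 1)
  expect_error(detect_tissue(white), "empty core")

  rc <- render_core(small_spec(seed = 2))
  tis <- detect_tissue(rc$image)
  truth <- rc$truth$tissue_mask
  jaccard <- sum(tis$mask & truth) / sum(tis$mask | truth)
  expect_gte(jaccard, 0.95)

  # area is definitionally pixel count times pixel area
  expect_equal(tis$tissue_area_mm2, sum(tis$mask) * (1 / 1000)^2)
})

test_that("nuclei segmentation recovers generated counts", {
  # no hematoxylin anywhere -> no nuclei
  tis <- tissue_of(matrix(TRUE, 64, 64))
  empty <- segment_nuclei(matrix(0, 64, 64), tis)
  expect_identical(empty$n_objects, 0L)
  expect_equal(nuclei_density(empty, tis), 0)

  # well-separated nuclei recovered exactly
  sp <- small_spec(seed = 5, width_px = 256, height_px = 256, n_nuclei = 50,
                   cluster_size = 1, cluster_sd_um = 60)
  rc <- render_core(sp)
  m <- core_metrics(rc$image, keep_maps = TRUE)
  expect_identical(attr(m, "maps")$nuclei$n_objects, 50L)

  # clustered (touching) nuclei within +/-5%
  for (seed in c(3, 9)) {
    rc <- render_core(core_spec(seed = seed, od_noise_sd = 0))
    m <- core_metrics(rc$image, keep_maps = TRUE)
    n <- attr(m, "maps")$nuclei$n_objects
    expect_lt(abs(n - rc$truth$n_nuclei_placed) /
                rc$truth$n_nuclei_placed, 0.05)
  }

  expect_error(segment_nuclei(matrix(NaN, 4, 4), tissue_of(matrix(TRUE, 4, 4))),
               "non-finite")
  expect_error(segment_nuclei(matrix(0, 4, 4), tissue_of(matrix(TRUE, 4, 4)),
                              min_area_um2 = 10, max_area_um2 = 5),
               "min < max")
})

test_that("nuclei density is objects per square millimetre", {
  lab <- matrix(0L, 50, 50)
  lab[cbind(seq(5, 45, by = 10), seq(5, 45, by = 10))] <- 1:5
  tis <- tissue_of(matrix(TRUE, 50, 50), um_per_px = 10)  # 0.25 mm2
  expect_equal(nuclei_density(labels_of(lab), tis), 5 / 0.25)
  expect_error(nuclei_density(labels_of(lab),
                              tissue_of(matrix(FALSE, 50, 50), 10)),
               "zero")
})

test_that("zone bands around a single nucleus match analytic annulus areas", {
  h <- w <- 251
  lab <- matrix(0L, h, w)
  r_nuc <- 40
  rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, TRUE)
  d2 <- (rows - 126)^2 + (cols - 126)^2
  lab[d2 <= r_nuc^2] <- 1L
  tis <- tissue_of(matrix(TRUE, h, w))
  zp <- zone_params(cyto_dilation_um = 10, capsular_width_um = 10,
                    paracapsular_width_um = 15, nest_gap_um = 0)
  zm <- build_zones(labels_of(lab), tis, zp)

  r_cell <- r_nuc + 10
  expected <- c(pi * (r_cell + 10)^2 - pi * r_cell^2,
                pi * (r_cell + 25)^2 - pi * (r_cell + 10)^2)
  got <- c(sum(zm == 2L), sum(zm == 3L))
  expect_lt(max(abs(got - expected) / expected), 0.02)
})

test_that("zero band widths leave only the cell region territorial", {
  lab <- matrix(0L, 40, 40); lab[18:22, 18:22] <- 1L
  tis <- tissue_of(matrix(TRUE, 40, 40))
  zm <- build_zones(labels_of(lab), tis,
                    zone_params(0, 0, 0, 0))
  expect_identical(sum(zm == 2L) + sum(zm == 3L), 0L)
  expect_identical(unname(which(zm == 1L)), unname(which(lab > 0L)))
})

test_that("zoning equals a brute-force nearest-cell-distance loop", {
  for (seed in 1:3) {
    set.seed(seed)
    lab <- matrix(0L, 64, 64)
    centers <- cbind(sample(8:56, 4), sample(8:56, 4))
    rows <- matrix(1:64, 64, 64); cols <- matrix(1:64, 64, 64, TRUE)
    for (k in 1:4) {
      disk <- (rows - centers[k, 1])^2 + (cols - centers[k, 2])^2 <= 3^2
      lab[disk] <- k
    }
    tis_mask <- matrix(TRUE, 64, 64); tis_mask[1:3, ] <- FALSE
    tis <- tissue_of(tis_mask, um_per_px = 2)
    zp <- zone_params(cyto_dilation_um = 0, capsular_width_um = 5,
                      paracapsular_width_um = 6, nest_gap_um = 0)
    zm <- build_zones(labels_of(lab), tis, zp)
    oracle <- brute_zone_map(lab > 0L, tis_mask, 5, 6, um_per_px = 2)
    expect_identical(as.integer(zm), as.integer(oracle))
  }
})

test_that("zone maps partition the image and grow monotonically with width", {
  rc <- render_core(small_spec(seed = 4))
  m <- core_metrics(rc$image, keep_maps = TRUE)
  maps <- attr(m, "maps")
  zm <- maps$zones
  expect_true(all(zm %in% 0:4))
  expect_identical(sum(zm == 0L), sum(!maps$tissue$mask))

  # intracellular covers every nucleus pixel
  expect_true(all(zm[maps$nuclei$labels > 0L] == 1L))

  cap_area <- vapply(c(1, 2, 4, 6), function(wd) {
    z <- build_zones(maps$nuclei, maps$tissue,
                     zone_params(3, wd, 3, 5))
    sum(z == 2L)
  }, numeric(1))
  expect_true(all(diff(cap_area) >= 0))
})

test_that("nest merging is idempotent and empty nuclei fall back gracefully", {
  rc <- render_core(small_spec(seed = 6))
  m <- core_metrics(rc$image, keep_maps = TRUE)
  nuc <- attr(m, "maps")$nuclei
  zp <- zone_params()
  once <- vitroquant:::cell_regions(nuc, 1, zp)
  # re-closing the merged region must change nothing
  again <- EBImage::closing(once + 0,
                            vitroquant:::disc_brush(round(zp$nest_gap_um / 2))) > 0
  expect_identical(once, again)

  tis <- tissue_of(matrix(TRUE, 32, 32))
  expect_warning(zm <- build_zones(labels_of(matrix(0L, 32, 32)), tis, zp),
                 "interterritorial")
  expect_true(all(zm == 4L))
})
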