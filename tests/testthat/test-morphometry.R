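test_that("percent stained area implements the x100 area ratio", {
  tis <- matrix(TRUE, 10, 10)
  expect_equal(percent_sa(tis, tis), 100)
  expect_equal(percent_sa(matrix(FALSE, 10, 10), tis), 0)

  set.seed(1)
  pos <- matrix(FALSE, 10, 10)
  pos[sample(100, 37)] <- TRUE
  expect_equal(percent_sa(pos, tis), 37)
  expect_equal(percent_sa(pos, tis), brute_percent_sa(pos, tis))

  expect_error(percent_sa(pos, matrix(FALSE, 10, 10)), "empty tissue")
  expect_error(percent_sa(pos, matrix(TRUE, 5, 5)), "differ")
})

test_that("territorial and interterritorial %SA follow the joint class-zone rule", {
  # all positivity confined to the interterritorial zone
  cls <- as_class_map(matrix(1L, 8, 8))
  zon <- as_zone_map(matrix(4L, 8, 8))
  cls[5:8, ] <- 3L
  tis <- matrix(TRUE, 8, 8)
  expect_equal(territorial_sa(cls, zon, tis), 0)
  expect_equal(interterritorial_sa(cls, zon, tis), 50)

  # all positivity inside cells
  zon2 <- as_zone_map(matrix(1L, 8, 8))
  expect_equal(interterritorial_sa(cls, zon2, tis), 0)
  expect_equal(territorial_sa(cls, zon2, tis), 50)

  # random 8x8 maps against a brute-force joint-condition count
  for (seed in 1:5) {
    set.seed(seed)
    cm <- as_class_map(matrix(sample(0:4, 64, TRUE), 8, 8))
    zm <- as_zone_map(matrix(sample(0:4, 64, TRUE), 8, 8))
    t8 <- matrix(sample(c(TRUE, TRUE, TRUE, FALSE), 64, TRUE), 8, 8)
    if (!any(t8)) t8[1, 1] <- TRUE
    brute_t <- brute_percent_sa(cm >= 2L & (zm == 1L | zm == 2L | zm == 3L), t8)
    brute_i <- brute_percent_sa(cm >= 2L & zm == 4L, t8)
    expect_equal(territorial_sa(cm, zm, t8), brute_t)
    expect_equal(interterritorial_sa(cm, zm, t8), brute_i)
  }
  expect_error(territorial_sa(cls, as_zone_map(matrix(1L, 4, 4)), tis),
               "differ")
})

test_that("H-score spans 0-300 and evaluates the weighted class formula", {
  expect_equal(hscore(c(negative = 0, weak = 0, moderate = 0, strong = 1)),
               300)
  expect_equal(hscore(c(negative = 1, weak = 0, moderate = 0, strong = 0)),
               0)
  expect_equal(hscore(c(negative = .25, weak = .25, moderate = .25,
                        strong = .25)), 150)
  expect_error(hscore(c(negative = .5, weak = .2, moderate = 0,
                        strong = 0)), "sum to 1")
  # scale invariance: depends on fractions only
  big <- as_class_map(matrix(rep(c(1L, 4L), each = 200), 20, 20))
  small <- as_class_map(matrix(rep(c(1L, 4L), each = 2), 2, 2))
  expect_equal(hscore(pixel_ratios(big)), hscore(pixel_ratios(small)))
})

test_that("zone-split %SA decomposes total positive %SA exactly", {
  for (seed in c(2, 7)) {
    rc <- render_core(small_spec(seed = seed))
    m <- core_metrics(rc$image, keep_maps = TRUE)
    maps <- attr(m, "maps")
    total <- percent_sa(maps$classes >= 2L, maps$tissue)
    expect_equal(m$terr_vn_sa + m$inter_vn_sa, total, tolerance = 1e-12)
  }
})

test_that("per-cylinder metrics recover synthetic ground truth deterministically", {
  rc <- render_core(small_spec(seed = 14, pattern = "MIXED"))
  m1 <- core_metrics(rc$image)
  m2 <- core_metrics(rc$image)
  expect_identical(m1, m2)
  expect_equal(m1$terr_vn_sa, rc$truth$true_terr_sa, tolerance = 2)
  expect_equal(m1$inter_vn_sa, rc$truth$true_inter_sa, tolerance = 2)
  expect_equal(m1$hscore, unname(rc$truth$true_hscore), tolerance = 10)

  blank <- render_core(small_spec(seed = 1, n_nuclei = 0,
                                  target_positive_fraction = 0))
  mb <- core_metrics(blank$image)
  expect_equal(mb$terr_vn_sa, 0)
  expect_equal(mb$inter_vn_sa, 0)
  expect_equal(mb$hscore, 0)
  expect_equal(mb$nuclei_density, 0)
})

test_that("case aggregation averages cylinders and flags no immunoreactivity", {
  rc <- render_core(small_spec(seed = 15))
  m <- core_metrics(rc$image)

  # idempotence on identical cylinders
  agg <- aggregate_case(rbind(m, m), case_id = "c1")
  for (col in c("terr_vn_sa", "inter_vn_sa", "hscore", "nuclei_density"))
    expect_equal(agg[[col]], m[[col]])

  # arithmetic mean
  a <- m; a$terr_vn_sa <- 2; b <- m; b$terr_vn_sa <- 4
  expect_equal(aggregate_case(rbind(a, b))$terr_vn_sa, 3)

  # three cylinders: brute-force sum / 3 per numeric field
  set.seed(3)
  three <- do.call(rbind, lapply(1:3, function(i) {
    x <- m
    for (col in names(m)[sapply(m, is.numeric)]) x[[col]] <- runif(1, 0, 50)
    x
  }))
  agg3 <- aggregate_case(three)
  for (col in names(m)[sapply(m, is.numeric)])
    expect_equal(agg3[[col]], sum(three[[col]]) / 3)

  empty_m <- m; empty_m$inter_vn_sa <- 0; empty_m$terr_vn_sa <- 0
  empty_m$hscore <- 0
  expect_true(aggregate_case(empty_m)$no_immunoreactivity)
  expect_false(aggregate_case(m)$no_immunoreactivity)
  expect_error(aggregate_case(m[0, ]), "at least one")

  meta <- data.frame(mycn_mna = 1L, efs_time = 3.2, efs_event = 1L)
  with_meta <- aggregate_case(m, meta = meta, case_id = "c9")
  expect_identical(with_meta$mycn_mna, 1L)
  expect_identical(with_meta$case_id, "c9")
})
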