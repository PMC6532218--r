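test_that("Q3 dichotomization uses the interpolated quartile with >= ties high", {
  d <- q3_dichotomize(1:8)
  expect_equal(d$threshold, 6.25)
  expect_identical(which(d$high), c(7L, 8L))

  # permutation invariance
  set.seed(9)
  v <- rlnorm(40)
  perm <- sample(40)
  d1 <- q3_dichotomize(v)
  d2 <- q3_dichotomize(v[perm])
  expect_equal(d1$threshold, d2$threshold)
  expect_identical(d1$high[perm], d2$high)

  expect_warning(dt <- q3_dichotomize(rep(3, 10)), "degenerate")
  expect_true(all(dt$high))
  expect_error(q3_dichotomize(c(1, 2, 3)), "at least 4")
})

test_that("Mann-Whitney U equals the pairwise counting oracle", {
  # complete separation: maximal U
  expect_equal(mann_whitney(c(5, 6, 7, 1, 2, 3),
                            rep(c("a", "b"), each = 3))$u, 9)
  # identical samples: U = n1 n2 / 2
  expect_equal(mann_whitney(rep(c(1, 2, 3), 2),
                            rep(c("a", "b"), each = 3))$u, 4.5)

  for (seed in 1:5) {
    set.seed(seed)
    a <- sample(1:6, 5, replace = TRUE)  # heavy ties
    b <- sample(1:6, 5, replace = TRUE)
    got <- mann_whitney(c(a, b), rep(c("a", "b"), each = 5))
    expect_equal(got$u, brute_mw_u(a, b))
    expect_gte(got$p_value, 0); expect_lte(got$p_value, 1)
  }
  expect_error(mann_whitney(1:4, rep("a", 4)), "two non-empty")
})

test_that("Kruskal-Wallis H matches the rank formula and the two-group case", {
  # hand-computable data
  v <- c(2.1, 3.5, 3.5, 1.0, 7.2, 6.6, 3.5, 8.8, 5.0)
  g <- rep(c("x", "y", "z"), each = 3)
  got <- kruskal_wallis(v, g)
  expect_equal(got$h, brute_kw_h(v, g), tolerance = 1e-9)
  expect_identical(got$df, 2L)

  expect_warning(flat <- kruskal_wallis(rep(4, 6), rep(c("a", "b"), 3)),
                 "identical")
  expect_equal(flat$h, 0)
  expect_equal(flat$p_value, 1)

  # k = 2 agrees with the Mann-Whitney normal approximation
  for (seed in 1:4) {
    set.seed(seed)
    v2 <- sample(1:10, 14, replace = TRUE)
    g2 <- rep(c("a", "b"), each = 7)
    expect_equal(kruskal_wallis(v2, g2)$p_value,
                 mann_whitney(v2, g2)$p_value, tolerance = 0.01)
  }
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "two")
})

test_that("Kaplan-Meier product-limit matches hand tabulation", {
  # no censoring: steps are the empirical survival function
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km_surv_at(km, c(1, 2, 3, 4)), c(0.75, 0.5, 0.25, 0))
  expect_equal(km_surv_at(km, 0.5), 1)

  # all censored: S identically one
  kc <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km_surv_at(kc, c(1, 3, 5, 7)) == 1))

  # mixed toy set with tied event/censoring times
  tt <- c(1, 1, 2, 2, 3, 4, 4, 5, 6, 6)
  ee <- c(1, 0, 1, 1, 0, 1, 1, 0, 1, 0)
  km2 <- km_estimate(tt, ee)
  grid <- c(0.5, 1, 2, 3, 4, 5, 6, 7)
  expect_equal(km_surv_at(km2, grid), brute_km(tt, ee, grid),
               tolerance = 1e-9)

  # KM with no censoring equals 1 - ECDF exactly
  set.seed(2)
  t3 <- rexp(30)
  km3 <- km_estimate(t3, rep(1, 30))
  expect_equal(km_surv_at(km3, sort(t3)), 1 - ecdf(t3)(sort(t3)),
               tolerance = 1e-12)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank statistic matches the O/E/V tabulation oracle", {
  # duplicated groups: statistic zero
  tt <- c(1, 2, 3, 4, 5); ee <- c(1, 1, 0, 1, 1)
  z <- logrank_test(c(tt, tt), c(ee, ee), rep(c("a", "b"), each = 5))
  expect_equal(z$chisq, 0, tolerance = 1e-9)

  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    times <- round(rexp(n, 0.3), 1)
    events <- rbinom(n, 1, 0.7)
    groups <- rep(c("a", "b"), each = n / 2)
    if (sum(events) == 0) events[1] <- 1
    got <- logrank_test(times, events, groups)
    expect_equal(got$chisq, brute_logrank(times, events, groups),
                 tolerance = 1e-9)
  }

  # symmetric under group relabelling
  set.seed(6)
  times <- rexp(16); events <- rbinom(16, 1, 0.8)
  g <- rep(c("a", "b"), 8)
  g2 <- ifelse(g == "a", "b", "a")
  expect_equal(logrank_test(times, events, g)$chisq,
               logrank_test(times, events, g2)$chisq, tolerance = 1e-12)

  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("Cox output satisfies the Exp(B)/CI identities", {
  d <- simulate_cohort(null_sim_params(n_cases = 300, seed = 51,
                                       hr_terr_vn = 2.5))
  res <- cox_backward(d, "efs_time", "efs_event",
                      c("high_terr_vn", "mycn_mna"), alpha_stay = 1)
  expect_equal(res$table$ExpB, exp(res$table$B), tolerance = 1e-12)
  expect_equal(res$table$CI_lower, exp(res$table$B - 1.96 * res$table$SE))
  expect_equal(res$table$CI_upper, exp(res$table$B + 1.96 * res$table$SE))
  expect_true(all(res$table$CI_lower <= res$table$ExpB &
                  res$table$ExpB <= res$table$CI_upper))
  expect_equal(res$table$Wald, (res$table$B / res$table$SE)^2)
})

test_that("duplicating every subject leaves the Cox estimate unchanged", {
  d <- simulate_cohort(null_sim_params(n_cases = 120, seed = 61,
                                       hr_terr_vn = 2))
  dd <- rbind(d, d)
  # exact score-equation identity under Breslow tie handling
  b1 <- cox_backward(d, "efs_time", "efs_event", "high_terr_vn",
                     alpha_stay = 1, ties = "breslow")$table
  b2 <- cox_backward(dd, "efs_time", "efs_event", "high_terr_vn",
                     alpha_stay = 1, ties = "breslow")$table
  expect_equal(b2$B, b1$B, tolerance = 1e-6)
  expect_lt(b2$SE, b1$SE)
  # Efron differs only through the duplication-induced ties
  e2 <- cox_backward(dd, "efs_time", "efs_event", "high_terr_vn",
                     alpha_stay = 1, ties = "efron")$table
  expect_equal(e2$B, b1$B, tolerance = 0.05)
})

test_that("backward Wald elimination drops pure-noise covariates", {
  dropped <- 0L
  for (k in 1:200) {
    d <- simulate_cohort(null_sim_params(n_cases = 120, seed = 1000 + k,
                                         hr_terr_vn = 3))
    set.seed(2000 + k)
    d$noise <- rbinom(nrow(d), 1, 0.5)
    res <- cox_backward(d, "efs_time", "efs_event",
                        c("high_terr_vn", "noise"), alpha_stay = 0.1)
    if (!"noise" %in% res$retained) dropped <- dropped + 1L
    if (k == 1) {
      expect_true(nrow(res$trace) == 0 ||
                  all(res$trace$p_drop > 0.1))
    }
  }
  expect_gte(dropped / 200, 0.85)
})
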