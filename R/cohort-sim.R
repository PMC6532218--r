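# Default marginal distributions of the per-cylinder morphometric metrics,
# loosely matched to the median / third-quartile summaries reported for
# primary neuroblastoma cores (lognormal with sdlog = log(Q3/median)/z0.75,
# truncated to the metric's natural range).  These are plausibility
# defaults, not calibrated claims.
default_metric_distributions <- function() {
  q75 <- stats::qnorm(0.75)
  mk <- function(median, q3, upper) {
    list(meanlog = log(median), sdlog = log(q3 / median) / q75, upper = upper)
  }
  list(
    nuclei_density = mk(560, 739, 1e4),
    nuclei_sa      = mk(11.75, 15.50, 100),
    inter_vn_sa    = mk(9.35, 18.20, 100),
    terr_vn_sa     = mk(0.71, 4.50, 100),
    ratio_weak     = mk(0.80, 2.10, 100),
    ratio_moderate = mk(35.00, 56.75, 100),
    ratio_strong   = mk(3.55, 20.40, 100),
    hscore         = mk(110.91, 183.80, 300)
  )
}

# Default multiplicative stratum effects: territorial-pattern metrics run
# higher in the poor-prognosis strata (the association the downstream rank
# tests are designed to detect); interterritorial VN carries none.
default_stratum_effects <- function() {
  poor <- c(stage_m = 2.0, hist_unb_pdnb = 2.0, mycn_mna = 2.0,
            profile_sca = 2.0, del_11q = 2.0, high_risk = 2.0,
            high_instability = 2.0)
  list(terr_vn_sa = poor, ratio_strong = poor,
       hscore = poor[setdiff(names(poor), c("stage_m", "del_11q"))],
       nuclei_density = c(age_ge18m = 1.8, stage_m = 1.8,
                          hist_unb_pdnb = 1.8, mycn_mna = 1.8,
                          high_risk = 1.8, high_instability = 1.8))
}

# Default prevalence of each binary clinicobiological covariate.
default_covariate_freqs <- function() {
  c(age_ge18m = 0.55, stage_m = 0.45, hist_unb_pdnb = 0.60,
    mycn_mna = 0.20, profile_sca = 0.50, del_11q = 0.25,
    high_risk = 0.45, high_instability = 0.45)
}

#' Parameters of the survival-cohort simulator
#'
#' The simulator draws per-case clinicobiological covariates, per-cylinder
#' morphometric metrics (averaged into the case record), and event-free /
#' overall survival times from an exponential model whose log hazard is
#' linear in the covariates and in a high-territorial-VN indicator
#' (territorial %SA at or above the cohort third quartile).  Default
#' hazard ratios follow the magnitudes reported for INRG factors in
#' neuroblastoma multivariate models.
#'
#' @param n_cases number of simulated patients (>= 2).
#' @param cylinders_per_case TMA cylinders averaged per case.
#' @param metric_distributions per-metric list of
#'   `list(meanlog, sdlog, upper)` lognormal parameters.
#' @param stratum_effects per-metric named vectors of multiplicative
#'   shifts applied when the corresponding binary covariate is 1, giving
#'   the per-stratum locations (e.g. higher territorial VN in
#'   MYCN-amplified cases).  Empty list removes all metric-covariate
#'   association.
#' @param hr_terr_vn hazard ratio of high vs low territorial VN.
#' @param hr_covariates named hazard ratios for the binary covariates
#'   (entries for `age_ge18m`, `mycn_mna`, `del_11q`, `hist_unb_pdnb`).
#' @param covariate_freqs named prevalence of each binary covariate.
#' @param baseline_hazard events per year at covariate zero.
#' @param censoring_rate probability of random censoring before followup.
#' @param followup_years administrative censoring horizon (may be `Inf`
#'   only when `censoring_rate` is 0).
#' @param os_hazard_scale multiplier turning the EFS baseline hazard into
#'   the overall-survival baseline.
#' @param seed RNG seed.
#' @return list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_cases = 91, cylinders_per_case = 2,
                              metric_distributions =
                                default_metric_distributions(),
                              stratum_effects = default_stratum_effects(),
                              hr_terr_vn = 2.344,
                              hr_covariates = c(age_ge18m = 3.745,
                                                mycn_mna = 2.357,
                                                del_11q = 3.702,
                                                hist_unb_pdnb = 2.924),
                              covariate_freqs = default_covariate_freqs(),
                              baseline_hazard = 0.10,
                              censoring_rate = 0.20, followup_years = 15,
                              os_hazard_scale = 0.6, seed = 1L) {
  p <- structure(list(n_cases = as.integer(n_cases),
                      cylinders_per_case = as.integer(cylinders_per_case),
                      metric_distributions = metric_distributions,
                      stratum_effects = stratum_effects,
                      hr_terr_vn = hr_terr_vn,
                      hr_covariates = hr_covariates,
                      covariate_freqs = covariate_freqs,
                      baseline_hazard = baseline_hazard,
                      censoring_rate = censoring_rate,
                      followup_years = followup_years,
                      os_hazard_scale = os_hazard_scale,
                      seed = as.integer(seed)),
                 class = "cohort_sim_params")
  validate_cohort_sim_params(p)
  p
}

validate_cohort_sim_params <- function(p) {
  stopifnot(p$n_cases >= 2, p$cylinders_per_case >= 1,
            p$baseline_hazard > 0, p$os_hazard_scale > 0)
  if (p$hr_terr_vn <= 0 || any(p$hr_covariates <= 0))
    stop("hazard ratios must be positive")
  if (p$censoring_rate < 0 || p$censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  if (p$censoring_rate > 0 && !is.finite(p$followup_years))
    stop("finite followup_years required when censoring_rate > 0")
  for (nm in names(p$metric_distributions)) {
    d <- p$metric_distributions[[nm]]
    if (d$sdlog < 0) stop("degenerate distribution for ", nm,
                          ": negative scale")
  }
  for (nm in names(p$stratum_effects)) {
    if (any(unlist(p$stratum_effects[[nm]]) <= 0))
      stop("stratum effects must be positive multipliers")
  }
  invisible(p)
}

#' Simulate a survival cohort with covariate-linked hazards
#'
#' @param params a [cohort_sim_params].
#' @return data.frame (one row per case) with case id, averaged
#'   morphometric metrics, binary covariates, the `high_terr_vn` indicator
#'   used in the hazard, and `efs_time`/`efs_event`/`os_time`/`os_event`.
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  validate_cohort_sim_params(params)
  withr::with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(p) {
  n <- p$n_cases
  cov <- sapply(p$covariate_freqs,
                function(f) stats::rbinom(n, 1L, f))
  cov <- as.data.frame(cov)

  draw_metric <- function(nm) {
    d <- p$metric_distributions[[nm]]
    meanlog <- rep(d$meanlog, n)
    eff <- p$stratum_effects[[nm]]
    for (cv in names(eff)) {
      if (!cv %in% names(cov)) next
      meanlog <- meanlog + log(eff[[cv]]) * cov[[cv]]
    }
    per_cyl <- matrix(stats::rlnorm(n * p$cylinders_per_case,
                                    rep(meanlog, p$cylinders_per_case),
                                    d$sdlog),
                      nrow = n)
    per_cyl <- pmin(per_cyl, d$upper)
    rowMeans(per_cyl)
  }
  metrics <- as.data.frame(
    stats::setNames(lapply(names(p$metric_distributions), draw_metric),
                    names(p$metric_distributions)))

  q3 <- stats::quantile(metrics$terr_vn_sa, 0.75, type = 7, names = FALSE)
  high_terr <- as.integer(metrics$terr_vn_sa >= q3)

  lp <- log(p$hr_terr_vn) * high_terr
  for (nm in names(p$hr_covariates)) {
    if (!nm %in% names(cov)) stop("hazard covariate not simulated: ", nm)
    lp <- lp + log(p$hr_covariates[[nm]]) * cov[[nm]]
  }

  draw_endpoint <- function(base) {
    t_event <- stats::rexp(n, rate = base * exp(lp))
    c_rand <- rep(Inf, n)
    if (p$censoring_rate > 0) {
      censored <- stats::runif(n) < p$censoring_rate
      c_rand[censored] <- stats::runif(sum(censored), 0, p$followup_years)
    }
    c_all <- pmin(p$followup_years, c_rand)
    list(time = pmin(t_event, c_all), event = as.integer(t_event <= c_all))
  }
  efs <- draw_endpoint(p$baseline_hazard)
  os <- draw_endpoint(p$baseline_hazard * p$os_hazard_scale)

  out <- cbind(data.frame(case_id = sprintf("case-%03d", seq_len(n))),
               metrics, cov,
               data.frame(high_terr_vn = high_terr,
                          efs_time = efs$time, efs_event = efs$event,
                          os_time = os$time, os_event = os$event))
  attr(out, "terr_vn_q3") <- q3
  attr(out, "params") <- p
  out
}
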