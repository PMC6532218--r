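#' Third-quartile dichotomization
#'
#' Splits a biomarker at its third quartile (linear-interpolation, type-7
#' quantile convention) into `high` (value >= Q3) versus `low` groups, the
#' convention used before survival analysis.
#'
#' @param values numeric vector (>= 4 finite values).
#' @return list of class `dichotomy_result`: `threshold` (the Q3 value)
#'   and logical `high` per case.
#' @export
q3_dichotomize <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4L) stop("need at least 4 finite values to dichotomize")
  q3 <- stats::quantile(values, 0.75, type = 7, names = FALSE, na.rm = TRUE)
  high <- values >= q3
  if (all(high, na.rm = TRUE) || !any(high, na.rm = TRUE))
    warning("degenerate split: all cases fall on one side of Q3")
  structure(list(threshold = q3, high = high), class = "dichotomy_result")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of a metric between two groups; U counts the pairs
#' where an observation of the first group exceeds one of the second
#' (ties counted half).  The p-value uses the normal approximation with
#' tie correction, two-sided, without continuity correction (so that the
#' two-group Kruskal-Wallis test gives the same p on identical data).
#'
#' @param values numeric metric per case.
#' @param groups two-level grouping (logical, factor or vector).
#' @return list with `u` (U of the first level), `p_value`, and the two
#'   group sizes.
#' @export
mann_whitney <- function(values, groups) {
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2L)
    stop("exactly two non-empty groups are required")
  g <- droplevels(g)
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  ht <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  list(u = unname(ht$statistic), p_value = ht$p.value,
       n = c(length(x), length(y)))
}

#' Kruskal-Wallis H test
#'
#' Rank-based k-group comparison with tie correction; p from the
#' chi-square distribution on k - 1 degrees of freedom.  A metric with no
#' variation at all yields H = 0, p = 1 (with a warning) rather than the
#' 0/0 the tie-corrected formula would produce.
#'
#' @param values numeric metric per case.
#' @param groups k-level grouping, every level non-empty.
#' @return list with `h`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L) stop("at least two non-empty groups are required")
  if (any(table(g) == 0L)) stop("empty group")
  if (length(unique(values)) == 1L) {
    warning("all values identical: H = 0 by convention")
    return(list(h = 0, df = nlevels(g) - 1L, p_value = 1))
  }
  ht <- stats::kruskal.test(values, g)
  list(h = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (1/TRUE = event, 0/FALSE = censored);
#'   events precede censorings at tied times (risk-set convention).
#' @param horizon time at which the landmark survival rate is read off
#'   (default 5, the five-year rate).
#' @return list of class `km_fit`: `time`/`surv` step function
#'   coordinates, `rate_at_horizon` (S(horizon); NA if follow-up ends
#'   before the horizon with subjects still at risk), `horizon`, `n`,
#'   `n_events`, and `survfit` (the underlying fit).
#' @export
km_estimate <- function(times, events, horizon = 5) {
  if (any(times < 0)) stop("negative follow-up times")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  s <- summary(fit, times = horizon, extend = TRUE)
  rate <- if (max(times) < horizon && any(events == 0L) &&
              utils::tail(fit$surv, 1) > 0) NA_real_ else s$surv
  structure(list(time = fit$time, surv = fit$surv,
                 rate_at_horizon = rate, horizon = horizon,
                 n = length(times), n_events = sum(events),
                 survfit = fit),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier fit at arbitrary times
#'
#' @param fit a `km_fit`.
#' @param t times at which to evaluate the right-continuous step function.
#' @return survival probabilities S(t).
#' @export
km_surv_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  vapply(t, function(tt) {
    i <- which(fit$time <= tt)
    if (length(i) == 0L) 1 else fit$surv[max(i)]
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n=%d, events=%d, S(%g)=%s\n", x$n, x$n_events,
              x$horizon,
              ifelse(is.na(x$rate_at_horizon), "NA",
                     sprintf("%.3f", x$rate_at_horizon))))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected sum over event times with
#' hypergeometric variance; p from chi-square with 1 df.
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @param groups two-level group labels.
#' @return list with `chisq`, `p_value`, per-group observed and expected
#'   event counts.
#' @export
logrank_test <- function(times, events, groups) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) != 2L) stop("two non-empty groups are required")
  events <- as.integer(as.logical(events))
  if (sum(events) == 0L) stop("no events: log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Cox regression with backward Wald elimination
#'
#' Fits a proportional-hazards model by partial likelihood (Efron tie
#' handling by default), then iteratively removes the covariate with the
#' largest Wald p-value exceeding `alpha_stay` and refits, until every
#' retained covariate satisfies p <= `alpha_stay`.
#'
#' @param data data.frame of cases.
#' @param time_col,event_col names of the time and event columns.
#' @param covariates character vector (>= 1) of covariate column names.
#' @param alpha_stay retention threshold on the Wald p-value
#'   (default 0.1, the relaxed band used when reporting borderline
#'   prognostic factors; 0.05 is the strict significance convention).
#' @param ties tie-handling method passed to the partial likelihood
#'   ("efron" or "breslow").
#' @return list of class `cox_result`: `table` (one row per retained
#'   covariate with B, SE, Wald, Exp(B), 95% CI and p), `trace`
#'   (elimination steps), `retained`, `separation_flag`, `fit`.
#' @export
cox_backward <- function(data, time_col, event_col, covariates,
                         alpha_stay = 0.1, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(covariates) < 1L) stop("at least one covariate is required")
  missing_cols <- setdiff(c(time_col, event_col, covariates), names(data))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (sum(data[[event_col]]) == 0) stop("no events: Cox model undefined")

  current <- covariates
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p_drop = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- fit_cox(data, time_col, event_col, current, ties)
    if (length(current) == 0L) break
    p <- cox_wald_p(fit)
    p[!is.finite(p)] <- Inf  # unestimable (e.g. constant) covariates drop first
    worst <- which.max(p)
    if (p[worst] <= alpha_stay) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     dropped = current[worst],
                                     p_drop = unname(p[worst]),
                                     stringsAsFactors = FALSE))
    current <- current[-worst]
  }

  tab <- cox_table(fit)
  structure(list(table = tab, trace = trace, retained = current,
                 alpha_stay = alpha_stay, ties = ties,
                 separation_flag = any(abs(tab$B) > 15),
                 fit = fit),
            class = "cox_result")
}

fit_cox <- function(data, time_col, event_col, covariates, ties) {
  if (length(covariates) == 0L) return(NULL)
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  warns <- character(0)
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(fml, data = data, ties = ties),
             error = function(e)
               stop("Cox fit failed (", paste(covariates, collapse = "+"),
                    "): ", conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("Ran out of iterations", warns)))
    stop("Cox fit did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  attr(fit, "fit_warnings") <- warns
  fit
}

cox_wald_p <- function(fit) {
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  stats::pchisq((b / se)^2, df = 1, lower.tail = FALSE)
}

cox_table <- function(fit) {
  if (is.null(fit))
    return(data.frame(covariate = character(0), B = numeric(0),
                      SE = numeric(0), Wald = numeric(0),
                      ExpB = numeric(0), CI_lower = numeric(0),
                      CI_upper = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  data.frame(covariate = names(b), B = unname(b), SE = unname(se),
             Wald = unname((b / se)^2), ExpB = unname(exp(b)),
             CI_lower = unname(exp(b - 1.96 * se)),
             CI_upper = unname(exp(b + 1.96 * se)),
             p_value = unname(stats::pchisq((b / se)^2, 1,
                                            lower.tail = FALSE)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %d covariate(s) retained (alpha_stay=%g, %s ties)\n",
              length(x$retained), x$alpha_stay, x$ties))
  if (nrow(x$table) > 0) print(x$table, digits = 3)
  if (nrow(x$trace) > 0) {
    cat("eliminated:\n")
    print(x$trace, digits = 3)
  }
  invisible(x)
}
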