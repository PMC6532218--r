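# Independent brute-force oracles: deliberately naive per-pixel /
# per-pair computations against which the vectorized implementations are
# checked.

brute_classify <- function(dab, tissue, thr) {
  out <- matrix(0L, nrow(dab), ncol(dab))
  for (i in seq_len(nrow(dab))) {
    for (j in seq_len(ncol(dab))) {
      if (!tissue[i, j]) { out[i, j] <- 0L; next }
      v <- dab[i, j]
      out[i, j] <- if (v >= thr$t_mod_strong) 4L
        else if (v >= thr$t_weak_mod) 3L
        else if (v >= thr$t_pos) 2L
        else 1L
    }
  }
  out
}

brute_percent_sa <- function(positive, tissue) {
  num <- 0L; den <- 0L
  for (k in seq_along(tissue)) {
    if (tissue[k]) {
      den <- den + 1L
      if (positive[k]) num <- num + 1L
    }
  }
  100 * num / den
}

# Per-pixel nearest-cell-distance zoning (no nest closing: use with
# nest_gap_um = 0).
brute_zone_map <- function(cell, tissue, cap_um, para_um, um_per_px) {
  idx <- which(cell, arr.ind = TRUE)
  out <- matrix(4L, nrow(cell), ncol(cell))
  for (i in seq_len(nrow(cell))) {
    for (j in seq_len(ncol(cell))) {
      if (cell[i, j]) { out[i, j] <- 1L; next }
      d <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2)) * um_per_px
      out[i, j] <- if (d <= cap_um) 2L
        else if (d <= cap_um + para_um) 3L
        else 4L
    }
  }
  out[!tissue] <- 0L
  out
}

# U = #(a > b) + 0.5 #(a == b) over all cross pairs.
brute_mw_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Tie-corrected Kruskal-Wallis H from the rank-sum formula.
brute_kw_h <- function(values, groups) {
  g <- as.factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Product-limit estimator by explicit risk-set tabulation.
brute_km <- function(times, events, at) {
  ev_times <- sort(unique(times[events == 1]))
  vapply(at, function(tt) {
    s <- 1
    for (t in ev_times[ev_times <= tt]) {
      n_risk <- sum(times >= t)
      d <- sum(times == t & events == 1)
      s <- s * (1 - d / n_risk)
    }
    s
  }, numeric(1))
}

# Two-group log-rank chi-square by per-event-time O/E/V tabulation.
brute_logrank <- function(times, events, groups) {
  g <- as.integer(as.factor(groups))
  ev_times <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}
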