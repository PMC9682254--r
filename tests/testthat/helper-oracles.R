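`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used across the suite. Each re-derives its quantity by
# direct enumeration / hand computation, not by calling package internals.

# Step-by-step ssGSEA enrichment score: materializes both running fractions
# position by position down the decreasing-expression walk.
naive_ssgsea_es <- function(x, set_genes, alpha) {
  genes <- names(x)
  r <- rank(x, ties.method = "average")        # ascending midranks
  walk <- order(-x, genes, method = "radix")   # decreasing expression
  in_set <- genes %in% set_genes
  denom_in <- sum(r[in_set]^alpha)
  n_out <- sum(!in_set)
  es <- 0; cum_in <- 0; cum_out <- 0
  for (i in walk) {
    if (in_set[i]) cum_in <- cum_in + r[i]^alpha else cum_out <- cum_out + 1
    es <- es + cum_in / denom_in - cum_out / n_out
  }
  unname(es)
}

# Hand product-limit table: loops over distinct times.
naive_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), n_risk = numeric(0),
                    n_event = numeric(0), surv = numeric(0))
  for (t in ut) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, n_risk = n_risk, n_event = d,
                                 surv = s))
  }
  out
}

# Hand two-group log-rank: O/E/V accumulated over distinct event times.
naive_logrank2 <- function(time, event, group) {
  g <- as.integer(as.factor(group)) == 1L
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(chisq = (O - E)^2 / V, O = O, E = E, V = V)
}

# Efron log partial likelihood for a single numeric covariate.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_risk <- sum(exp(beta * x[R]))
    sum_tied <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_risk - (l / d) * sum_tied)
  }
  ll
}

# Exhaustive maximally-selected scan: recomputes, per candidate, the
# standardized log-rank-score statistic from scratch (no cumulative sums).
scan_cutpoint_oracle <- function(marker, time, event, min_prop = 0.1,
                                 range = c(0.1, 0.9)) {
  n <- length(marker)
  # log-rank scores by direct Nelson-Aalen lookup
  a <- vapply(seq_len(n), function(i) {
    ch <- 0
    for (t in sort(unique(time[time <= time[i] & event == 1])))
      ch <- ch + sum(time == t & event == 1) / sum(time >= t)
    event[i] - ch
  }, numeric(1))
  abar <- mean(a); ss <- sum((a - abar)^2)
  lo <- max(min_prop, range[1]); hi <- min(1 - min_prop, range[2])
  cands <- sort(unique(marker))
  cands <- cands[-length(cands)]
  best_val <- NA; best_stat <- -Inf
  for (c0 in cands) {
    m <- sum(marker <= c0)
    if (m / n < lo || m / n > hi) next
    L <- sum(a[marker <= c0])
    s <- abs(L - m * abar) / sqrt(m * (n - m) / (n * (n - 1)) * ss)
    if (s > best_stat + 1e-12) { best_stat <- s; best_val <- c0 }
  }
  list(value = best_val, statistic = best_stat)
}

# Spearman rho by the no-ties sum-of-squared-rank-differences formula.
spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# AUC by exhaustive pairwise comparison.
auc_pairs <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher p for a 2x2 by hypergeometric tail enumeration.
fisher_enum_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small random expression matrix with distinct-ish values and named rows.
random_expression <- function(G, n, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(G * n, rate = 0.2), G, n,
              dimnames = list(sprintf("g%03d", seq_len(G)),
                              sprintf("s%02d", seq_len(n))))
  m
}
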