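score_table_from <- function(mat) {
  structure(list(scores = mat, alpha = 0.25, normalized = "none",
                 coverage = NULL), class = "ScoreTable")
}

sim_surv <- function(n, seed, beta_fun = function(m) rep(0, length(m))) {
  set.seed(seed)
  marker <- stats::rnorm(n)
  t_ev <- stats::rexp(n, rate = exp(beta_fun(marker)))
  cens <- stats::runif(n, 0, stats::quantile(t_ev, 0.9) * 1.5)
  list(marker = marker, time = pmin(t_ev, cens),
       event = as.integer(t_ev <= cens))
}

test_that("ICFR is the score difference and is antisymmetric", {
  m <- matrix(c(0.5, 0.2, 0.9, 0.5, 0.2, 0.3), 3, 2,
              dimnames = list(paste0("p", 1:3), c("CD8 T cells", "CAF")))
  st <- score_table_from(m)
  r <- compute_icfr(st, "CD8 T cells", "CAF")
  expect_equal(r$cfr, m[, 1] - m[, 2], ignore_attr = TRUE)
  expect_equal(r$cfr[1], 0)   # equal components
  r_rev <- compute_icfr(st, "CAF", "CD8 T cells")
  expect_equal(r_rev$cfr, -r$cfr)
  expect_identical(attr(r, "form"), "score-difference")
  expect_error(compute_icfr(st, "nope"), "nope")
})

test_that("IHC CFR sums regions before taking the area ratio", {
  a <- data.frame(sample_id = "p1", cd8_area = 2, caf_area = 4,
                  total_area = 100)
  expect_equal(compute_ihc_cfr(a)$cfr, 0.5)
  a2 <- data.frame(sample_id = "p2", cd8_area = 3, caf_area = 3,
                   total_area = 10)
  expect_equal(compute_ihc_cfr(a2)$cfr, 1)

  # two regions: spec example sums to (4, 4, 20) -> 1.0
  reg2 <- data.frame(sample_id = c("p", "p"), cd8_area = c(1, 3),
                     caf_area = c(2, 2), total_area = c(10, 10))
  expect_equal(compute_ihc_cfr(reg2)$cfr, 1)
  # sum-then-ratio, not the mean of per-region ratios
  reg3 <- data.frame(sample_id = c("q", "q"), cd8_area = c(1, 3),
                     caf_area = c(4, 2), total_area = c(10, 10))
  expect_equal(compute_ihc_cfr(reg3)$cfr, 4 / 6)
  mean_of_ratios <- mean(c(1 / 4, 3 / 2))
  expect_false(isTRUE(all.equal(compute_ihc_cfr(reg3)$cfr, mean_of_ratios)))

  # zero fibroblast area: unevaluable, not infinite
  z <- data.frame(sample_id = "r", cd8_area = 2, caf_area = 0,
                  total_area = 10)
  expect_warning(rz <- compute_ihc_cfr(z), "unevaluable")
  expect_true(is.na(rz$cfr))
  expect_error(compute_ihc_cfr(transform(z, total_area = 0)), "positive")
})

test_that("optimal cutpoint equals the exhaustive per-candidate scan", {
  for (seed in 1:25) {
    n <- sample(20:50, 1)
    d <- sim_surv(n, seed = 100 + seed)
    if (sum(d$event) < 2) next
    fit <- optimal_cutpoint(d$marker, d$time, d$event)
    orc <- scan_cutpoint_oracle(d$marker, d$time, d$event)
    expect_equal(fit$value, orc$value, tolerance = 1e-12)
    expect_equal(abs(fit$statistic), orc$statistic, tolerance = 1e-9)
  }
})

test_that("cutpoint optimum is invariant under monotone marker transforms", {
  d <- sim_surv(80, seed = 31)
  fit <- optimal_cutpoint(d$marker, d$time, d$event)
  fit2 <- optimal_cutpoint(exp(d$marker), d$time, d$event)
  expect_equal(fit2$value, exp(fit$value), tolerance = 1e-12)
  expect_equal(fit2$statistic, fit$statistic, tolerance = 1e-12)
  expect_equal(fit2$p_approx, fit$p_approx, tolerance = 1e-12)
})

test_that("cutpoint enforces feasibility and degenerate-input errors", {
  d <- sim_surv(100, seed = 17)
  expect_error(optimal_cutpoint(rep(1, 100), d$time, d$event), "constant")
  expect_error(optimal_cutpoint(d$marker, d$time, rep(0, 100)), "2 events")
  fit <- optimal_cutpoint(d$marker, d$time, d$event, min_prop = 0.2)
  expect_gte(min(fit$group_sizes), 20)
  expect_gte(fit$value, fit$candidate_range[["low"]])
  expect_lte(fit$value, fit$candidate_range[["high"]])
  # permutation p is seeded and reproducible
  p1 <- optimal_cutpoint(d$marker, d$time, d$event, permutation_B = 50,
                         seed = 3)$p_permutation
  p2 <- optimal_cutpoint(d$marker, d$time, d$event, permutation_B = 50,
                         seed = 3)$p_permutation
  expect_equal(p1, p2)
})

test_that("dichotomize uses the documented boundary and matches group sizes", {
  d <- sim_surv(120, seed = 5)
  fit <- optimal_cutpoint(d$marker, d$time, d$event)
  grp <- dichotomize(d$marker, fit)
  expect_equal(sum(grp$label == "low"), unname(fit$group_sizes["n_low"]))
  expect_equal(sum(grp$label == "high"), unname(fit$group_sizes["n_high"]))
  # never smaller than the configured minimum proportion
  expect_gte(min(table(grp$label)) / 120, 0.1)

  # boundary: value exactly at the cutpoint is "low"
  g <- dichotomize(c(a = 1, b = 2, c = 3), 2)
  expect_equal(as.character(g$label), c("low", "low", "high"))
  expect_warning(dichotomize(c(a = 5, b = 6), 1), "degenerate")
})

test_that("four-class labels cross-classify and partition the cohort", {
  cd8 <- c(a = 1, b = 1, c = -1, d = -1)
  caf <- c(a = 1, b = -1, c = 1, d = -1)
  fc <- four_class(cd8, caf, 0, 0)
  expect_equal(as.character(fc$label),
               c("CD8hiCAFhi", "CD8hiCAFlo", "CD8loCAFhi", "CD8loCAFlo"))
  expect_false(anyNA(fc$label))
  expect_equal(sum(table(fc$label)), 4L)

  # independent markers at median cuts occupy ~25% per class
  set.seed(77)
  x <- stats::rnorm(4000); y <- stats::rnorm(4000)
  fc2 <- four_class(x, y, stats::median(x), stats::median(y))
  expect_true(all(abs(table(fc2$label) / 4000 - 0.25) < 0.03))
})

test_that("k-means infiltration clusters recover separated blobs deterministically", {
  set.seed(9)
  centers <- c(0, 6, 12)
  blob <- rep(1:3, each = 30)
  mat <- sapply(1:5, function(j) centers[blob] + stats::rnorm(90, sd = 0.3))
  colnames(mat) <- paste0("sig", 1:5)
  rownames(mat) <- sprintf("s%03d", 1:90)
  st <- score_table_from(mat)
  cl <- infiltration_clusters(st, k = 3, seed = 42)
  # perfect recovery: labels ordered by immune score -> blob 3 is "high"
  expect_equal(as.character(cl$label),
               c("low", "medium", "high")[blob])
  cl2 <- infiltration_clusters(st, k = 3, seed = 42)
  expect_identical(cl$label, cl2$label)

  one <- infiltration_clusters(st, k = 1, seed = 1)
  expect_equal(nlevels(one$label), 1L)
  expect_error(infiltration_clusters(st, k = 99, seed = 1), "exceeds")
})
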