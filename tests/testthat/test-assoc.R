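test_that("Spearman correlation matches closed forms and the d^2 oracle", {
  x <- c(0.3, 1.2, 2.7, 3.1, 5.0, 6.2)
  expect_equal(spearman_cor(x, x^3 + 1)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)

  set.seed(3)
  for (i in 1:10) {
    a <- sample(1:100, 10)  # no ties
    b <- sample(1:100, 10)
    sp <- spearman_cor(a, b)
    expect_equal(sp$rho, spearman_d2(a, b), tolerance = 1e-12)
    expect_true(sp$ci[1] <= sp$rho && sp$rho <= sp$ci[2])
  }
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:3, 3:1), "4 complete pairs")
})

test_that("group differences dispatch to the documented tests", {
  # identical groups: two-sided p ~ 1 under the normal approximation
  v <- c(1, 2, 3, 4, 5)
  gd <- group_difference(c(v, v), rep(c("a", "b"), each = 5))
  expect_gt(gd$p_value, 0.9)
  expect_identical(gd$method, "mann-whitney-u")

  # complete separation: U = 0; exhaustive allocation oracle gives
  # one-sided exact p = 1/choose(6, 3) = 0.05
  gd2 <- group_difference(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  combs <- utils::combn(6, 3)
  vals <- c(1, 2, 3, 4, 5, 6)
  u_obs <- sum(outer(c(1, 2, 3), c(4, 5, 6), ">"))
  u_all <- apply(combs, 2, function(ix)
    sum(outer(vals[ix], vals[-ix], ">")))
  expect_equal(u_obs, 0)
  expect_equal(mean(u_all <= u_obs), 0.05)  # enumeration oracle
  expect_identical(gd2$method, "mann-whitney-u")

  # three identical groups: Kruskal-Wallis statistic 0
  kw <- group_difference(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_identical(kw$method, "kruskal-wallis")
  expect_equal(kw$statistic, 0, tolerance = 1e-12)

  expect_error(group_difference(1:5, c("a", "a", "a", "b", "b"),
                                paired = TRUE), "equal group lengths")
  p <- group_difference(c(1, 2, 3, 2, 3, 4), rep(c("pre", "post"), each = 3),
                        paired = TRUE)
  expect_identical(p$method, "wilcoxon-signed-rank")
})

test_that("response rates reproduce the printed cohort statistics", {
  # printed counts: PD 11, PR 17, SD 33, CR 0 in n = 61
  cat61 <- c(rep("PD", 11), rep("PR", 17), rep("SD", 33))
  rr <- response_rates(cat61)
  expect_equal(rr$n, 61)
  expect_equal(round(100 * rr$orr, 1), 27.9)
  expect_equal(round(100 * rr$dcr, 1), 82.0)
  expect_true(all(rr$orr <= rr$dcr))

  expect_equal(response_rates(c("SD", "PD"))$orr, 0)
  expect_error(response_rates(character(0)), "empty")
  expect_error(response_rates(c("PR", "XX")), "invalid")
})

test_that("the printed per-group percentages identify a unique 34/27 split", {
  # brute-force: all splits of (PD 11, PR 17, SD 33) into high/low groups
  # whose rounded percentages match PR/SD/PD = 41/56/3 and 11/52/37
  hits <- list()
  for (pd_hi in 0:11) for (pr_hi in 0:17) for (sd_hi in 0:33) {
    n_hi <- pd_hi + pr_hi + sd_hi
    n_lo <- 61 - n_hi
    if (n_hi == 0 || n_lo == 0) next
    pct_hi <- round(100 * c(pr_hi, sd_hi, pd_hi) / n_hi)
    pct_lo <- round(100 * c(17 - pr_hi, 33 - sd_hi, 11 - pd_hi) / n_lo)
    if (all(pct_hi == c(41, 56, 3)) && all(pct_lo == c(11, 52, 37)))
      hits[[length(hits) + 1]] <- c(n_hi = n_hi, n_lo = n_lo,
                                    pr_hi = pr_hi, sd_hi = sd_hi,
                                    pd_hi = pd_hi)
  }
  expect_equal(length(hits), 1L)
  split <- hits[[1]]
  expect_equal(unname(split[c("n_hi", "n_lo")]), c(34, 27))

  # and the reconstructed groups reproduce the printed ORR/DCR
  cat_hi <- c(rep("PR", split[["pr_hi"]]), rep("SD", split[["sd_hi"]]),
              rep("PD", split[["pd_hi"]]))
  cat_lo <- c(rep("PR", 17 - split[["pr_hi"]]),
              rep("SD", 33 - split[["sd_hi"]]),
              rep("PD", 11 - split[["pd_hi"]]))
  rr <- response_rates(c(cat_hi, cat_lo),
                       rep(c("high", "low"), c(34, 27)))
  expect_equal(round(100 * rr$orr[rr$group == "high"]), 41)
  expect_equal(round(100 * rr$orr[rr$group == "low"]), 11)
  expect_equal(round(100 * rr$dcr[rr$group == "high"]), 97)
  expect_equal(round(100 * rr$dcr[rr$group == "low"]), 63)
})

test_that("contingency test follows its decision tree and Fisher enumeration", {
  # proportional table: no association, Fisher p = 1 (n < 20 -> Fisher)
  t0 <- matrix(c(5, 5, 10, 10), 2, 2)
  r0 <- contingency_test(t0)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)

  set.seed(8)
  for (i in 1:10) {
    tab <- matrix(stats::rpois(4, 3), 2, 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    r <- contingency_test(tab)
    if (r$method == "fisher-exact")
      expect_equal(r$p_value, fisher_enum_2x2(tab), tolerance = 1e-9)
  }

  # doubling all cells leaves the odds ratio unchanged
  t1 <- matrix(c(12, 8, 30, 11), 2, 2)
  expect_equal(contingency_test(t1)$odds_ratio,
               contingency_test(2 * t1)$odds_ratio)

  # large balanced table: plain chi-square; small expected cell: Yates
  big <- matrix(c(30, 25, 28, 33), 2, 2)
  expect_identical(contingency_test(big)$method, "chi-square")
  yates <- matrix(c(3, 17, 5, 20), 2, 2)  # min expected 3.6, n = 45
  expect_identical(contingency_test(yates)$method, "chi-square-yates")
  expect_error(contingency_test(matrix(0, 2, 2)), "all-zero")
})

test_that("logistic combiner estimates, nests and flags separation", {
  # uninformative predictor: slope ~ 0, intercept = logit(prevalence)
  set.seed(4)
  y <- rep(c(0, 1), c(30, 20))
  x <- rep(1:5, 10)
  fit <- logistic_combiner(y, data.frame(x = x))
  expect_lt(abs(fit$coefficients$estimate[2]), 0.2)
  expect_equal(fit$coefficients$estimate[1],
               stats::qlogis(mean(y)), tolerance = 0.3)
  expect_lte(fit$deviance, fit$null_deviance + 1e-9)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))

  # parameter recovery at n = 2000
  set.seed(5)
  x2 <- stats::rnorm(2000)
  y2 <- stats::rbinom(2000, 1, stats::plogis(-1 + 2 * x2))
  fit2 <- logistic_combiner(y2, data.frame(x = x2))
  expect_lt(abs(fit2$coefficients$estimate[1] + 1), 0.15)
  expect_lt(abs(fit2$coefficients$estimate[2] - 2), 0.15)

  expect_error(logistic_combiner(c(0, 0, 1, 1), data.frame(x = c(1, 2, 9, 10))),
               "separation")
  expect_error(logistic_combiner(rep(1, 5), data.frame(x = 1:5)), "classes")
})

test_that("ROC AUC equals the all-pairs oracle with half-credit ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(6)
  for (i in 1:10) {
    s <- sample(1:8, 30, replace = TRUE)   # ties present
    l <- stats::rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l), auc_pairs(s, l), tolerance = 1e-12)
    expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("mutation enrichment is Fisher per gene with BH adjustment", {
  set.seed(10)
  mm <- matrix(stats::rbinom(8 * 40, 1, 0.3), 8, 40,
               dimnames = list(paste0("gene", 1:8), NULL))
  mm[1, ] <- 0                       # never mutated -> skipped
  mm[2, ] <- rep(c(1, 0), c(20, 20)) # perfectly split
  labels <- rep(c("hi", "lo"), each = 20)
  expect_message(res <- mutation_enrichment(mm, labels), "skipped")
  expect_false("gene1" %in% res$gene)
  expect_equal(res$gene[1], "gene2")

  # equal mutation fractions: p = 1
  mm2 <- rbind(flat = rep(c(1, 0), 20))
  res2 <- mutation_enrichment(mm2, labels)
  expect_equal(res2$p_value, 1, tolerance = 1e-12)

  # per-gene p equals the contingency_test Fisher path on the same 2x2
  g <- "gene3"
  tab <- table(factor(mm[g, ], levels = c(1, 0)), labels)
  expect_equal(res$p_value[res$gene == g],
               stats::fisher.test(tab)$p.value, tolerance = 1e-12)

  # BH step-up closed form and monotonicity
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_true(!is.unsorted(res$q_value))
  expect_equal(nrow(mutation_enrichment(mm, labels, top_k = 3)), 3L)
})

test_that("tumor-type CFR/ORR correlation joins then delegates to Spearman", {
  cfr <- data.frame(tumor_type = c("A", "B", "C", "D", "E"),
                    cfr = c(1, 2, 3, 4, 5))
  orr <- data.frame(tumor_type = c("A", "B", "C", "D", "E"),
                    orr = c(0.1, 0.2, 0.3, 0.4, 0.5))
  r <- cfr_orr_correlation(cfr, orr)
  expect_equal(r$rho, 1)

  # dropping an unmatched key leaves the statistic unchanged
  orr2 <- rbind(orr, data.frame(tumor_type = "Z", orr = 0.9))
  r2 <- cfr_orr_correlation(cfr, orr2)
  expect_equal(r2$rho, r$rho)
  expect_false(r2$join$matched[r2$join$tumor_type == "Z"])

  expect_error(cfr_orr_correlation(cfr[1:3, ], orr), "4 matched")

  # shuffled ORR decorrelates on average across seeds
  rhos <- vapply(1:40, function(s) {
    set.seed(s)
    cfr_orr_correlation(cfr, transform(orr, orr = sample(orr)))$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.25)
})
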