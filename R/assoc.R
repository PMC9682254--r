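#' Spearman rank correlation with confidence interval
#'
#' Rho is the Pearson correlation of midranks. The p-value uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom; the confidence interval uses the Fisher z-transform with the
#' rank-correlation variance correction `sqrt((1 + rho^2 / 2) / (n - 3))`
#' (Bonett-Wright / Fieller-type), the standard choice when no method is
#' otherwise prescribed.
#'
#' @param x,y Numeric vectors, `n >= 4`, finite.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `rho`, `ci` (length 2), `p_value`, `n`.
#' @export
spearman_cor <- function(x, y, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("Spearman correlation undefined for a constant vector",
         call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
    ci <- c(rho, rho)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    z <- atanh(rho)
    se <- sqrt((1 + rho^2 / 2) / (n - 3))
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(c(z - q * se, z + q * se))
  }
  list(rho = rho, ci = ci, p_value = p, n = n)
}

#' Nonparametric group-difference test
#'
#' Two unpaired groups: Mann-Whitney U with normal approximation and tie
#' correction. Two paired groups: Wilcoxon signed-rank. Three or more groups:
#' Kruskal-Wallis.
#'
#' @param values Numeric vector.
#' @param labels Group labels (2+ non-empty groups).
#' @param paired Paired two-group comparison (equal lengths required).
#' @return List with `statistic`, `p_value`, `method`.
#' @export
group_difference <- function(values, labels, paired = FALSE) {
  labels <- droplevels(as.factor(labels))
  k <- nlevels(labels)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(labels) == 0L)) stop("empty group", call. = FALSE)
  if (k == 2L) {
    g <- split(values, labels)
    if (paired) {
      if (length(g[[1L]]) != length(g[[2L]]))
        stop("paired comparison requires equal group lengths", call. = FALSE)
      wt <- stats::wilcox.test(g[[1L]], g[[2L]], paired = TRUE, exact = FALSE,
                               correct = TRUE)
      list(statistic = unname(wt$statistic), p_value = wt$p.value,
           method = "wilcoxon-signed-rank")
    } else {
      wt <- stats::wilcox.test(g[[1L]], g[[2L]], exact = FALSE,
                               correct = TRUE)
      list(statistic = unname(wt$statistic), p_value = wt$p.value,
           method = "mann-whitney-u")
    }
  } else {
    if (paired) stop("paired comparison supports exactly two groups",
                     call. = FALSE)
    kt <- stats::kruskal.test(values, labels)
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         method = "kruskal-wallis")
  }
}

#' Objective response and disease-control rates
#'
#' RECIST bookkeeping: ORR = (CR + PR) / n, DCR = (CR + PR + SD) / n, per
#' group and overall. Rates are returned unrounded; rounding (one decimal of
#' percent) is a reporting-layer concern.
#'
#' @param category Per-sample RECIST category in `{CR, PR, SD, PD}`.
#' @param group Optional group labels; when `NULL` only the overall row is
#'   returned.
#' @return Data frame with columns `group`, `n`, `CR`, `PR`, `SD`, `PD`,
#'   `orr`, `dcr` (rates in `[0, 1]`).
#' @export
response_rates <- function(category, group = NULL) {
  if (length(category) == 0L) stop("empty response table", call. = FALSE)
  valid <- c("CR", "PR", "SD", "PD")
  category <- as.character(category)
  if (!all(category %in% valid))
    stop("invalid RECIST categories: ",
         paste(setdiff(unique(category), valid), collapse = ", "),
         call. = FALSE)
  one <- function(cat, label) {
    n <- length(cat)
    cnt <- vapply(valid, function(v) sum(cat == v), integer(1))
    data.frame(group = label, n = n, CR = cnt[["CR"]], PR = cnt[["PR"]],
               SD = cnt[["SD"]], PD = cnt[["PD"]],
               orr = (cnt[["CR"]] + cnt[["PR"]]) / n,
               dcr = (cnt[["CR"]] + cnt[["PR"]] + cnt[["SD"]]) / n,
               stringsAsFactors = FALSE)
  }
  out <- one(category, "overall")
  if (!is.null(group)) {
    group <- droplevels(as.factor(group))
    per <- do.call(rbind, lapply(levels(group),
                                 function(g) one(category[group == g], g)))
    out <- rbind(per, out)
  }
  rownames(out) <- NULL
  out
}

#' Contingency-table test with a fixed method decision tree
#'
#' Pure function of the count table: Fisher's exact test when any expected
#' count is below 1 or the total is below 20; otherwise the chi-square test,
#' with Yates continuity correction when the table is 2x2 and any expected
#' count is below 5. The method actually used is recorded.
#'
#' @param tab Matrix of non-negative integer counts (2 x C).
#' @return List with `statistic` (`NA` for Fisher), `p_value`, `method`,
#'   `odds_ratio` (2x2 only, sample odds ratio).
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(tab) == 0) stop("all-zero table", call. = FALSE)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  is2x2 <- all(dim(tab) == c(2L, 2L))
  or <- if (is2x2) (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]) else NA_real_
  if (any(expected < 1) || n < 20) {
    ft <- stats::fisher.test(tab)
    list(statistic = NA_real_, p_value = ft$p.value, method = "fisher-exact",
         odds_ratio = or)
  } else {
    correct <- is2x2 && any(expected < 5)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(statistic = unname(ct$statistic), p_value = ct$p.value,
         method = if (correct) "chi-square-yates" else "chi-square",
         odds_ratio = or)
  }
}

#' Logistic biomarker combiner
#'
#' Maximum-likelihood logistic regression (IRLS) of a binary response on one
#' or more predictors (e.g. CFR and PD-L1 TPS), with per-sample predicted
#' probabilities. Perfect separation is an error with a diagnostic.
#'
#' @param response 0/1 outcome (both classes present).
#' @param predictors Data frame (or vector) of predictors.
#' @return List with `coefficients` (data frame: term, estimate, se, z,
#'   p_value), `fitted` (per-sample probabilities), `deviance`,
#'   `null_deviance`, `model` (the `glm` object).
#' @export
logistic_combiner <- function(response, predictors) {
  if (!all(response %in% c(0, 1))) stop("response must be 0/1", call. = FALSE)
  if (length(unique(response)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  if (!is.data.frame(predictors)) predictors <- data.frame(x = predictors)
  dat <- cbind(data.frame(.y = response), predictors)
  fml <- stats::as.formula(paste(".y ~",
                                 paste(sprintf("`%s`", names(predictors)),
                                       collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        stop("perfect separation in logistic fit", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || any(abs(stats::coef(fit)) > 1e3))
    stop("perfect separation / non-convergence in logistic fit",
         call. = FALSE)
  cs <- summary(fit)$coefficients
  co <- data.frame(term = rownames(cs), estimate = cs[, 1L], se = cs[, 2L],
                   z = cs[, 3L], p_value = cs[, 4L], row.names = NULL,
                   stringsAsFactors = FALSE)
  list(coefficients = co, fitted = as.numeric(stats::fitted(fit)),
       deviance = fit$deviance, null_deviance = fit$null.deviance,
       model = fit)
}

#' Nonparametric ROC AUC
#'
#' `AUC = U / (n1 * n0)` where U is the Mann-Whitney statistic of the scores
#' of the positive class against the negative class, ties counted one half —
#' the probability that a random positive outscores a random negative.
#'
#' @param score Numeric scores.
#' @param label 0/1 class labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, label) {
  if (!all(label %in% c(0, 1))) stop("label must be 0/1", call. = FALSE)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-gene mutation enrichment between two groups
#'
#' For each gene, a 2x2 Fisher exact test of mutated/wild-type against the two
#' groups, Benjamini-Hochberg adjusted across tested genes, sorted by p.
#' Genes mutated in no sample are skipped with a note.
#'
#' @param mm Binary mutation matrix, genes x samples (0/1).
#' @param labels Two-level group labels, one per sample.
#' @param top_k Optionally keep only the k most significant genes.
#' @return Data frame: gene, counts per group, `odds_ratio`, `p_value`, `q_value`.
#' @export
mutation_enrichment <- function(mm, labels, top_k = NULL) {
  mm <- as.matrix(mm)
  if (!all(mm %in% c(0, 1))) stop("mutation matrix must be 0/1", call. = FALSE)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("exactly two groups required", call. = FALSE)
  if (ncol(mm) != length(labels))
    stop("labels must match mutation-matrix columns", call. = FALSE)
  never <- rowSums(mm) == 0
  if (any(never))
    message(sum(never), " gene(s) mutated in no sample skipped")
  mm <- mm[!never, , drop = FALSE]
  g1 <- labels == levels(labels)[1L]
  res <- do.call(rbind, lapply(seq_len(nrow(mm)), function(i) {
    tab <- matrix(c(sum(mm[i, g1] == 1), sum(mm[i, g1] == 0),
                    sum(mm[i, !g1] == 1), sum(mm[i, !g1] == 0)), 2, 2)
    ft <- stats::fisher.test(tab)
    data.frame(gene = rownames(mm)[i],
               mut_g1 = tab[1, 1], n_g1 = sum(g1),
               mut_g2 = tab[1, 2], n_g2 = sum(!g1),
               odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2]),
               p_value = ft$p.value, stringsAsFactors = FALSE)
  }))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(top_k)) res <- utils::head(res, top_k)
  res
}

#' Correlation between per-tumor-type CFR and response rate
#'
#' Inner-joins two per-tumor-type tables (mean CFR, ORR) on tumor type and
#' delegates to [spearman_cor()]; a join report names dropped keys.
#'
#' @param cfr_by_tumor Data frame with columns `tumor_type`, `cfr`.
#' @param orr_by_tumor Data frame with columns `tumor_type`, `orr`.
#' @return List with `rho`, `ci`, `p_value`, `n`, and `join` (data frame of
#'   keys with a `matched` flag).
#' @export
cfr_orr_correlation <- function(cfr_by_tumor, orr_by_tumor) {
  stopifnot(all(c("tumor_type", "cfr") %in% names(cfr_by_tumor)),
            all(c("tumor_type", "orr") %in% names(orr_by_tumor)))
  merged <- merge(cfr_by_tumor[c("tumor_type", "cfr")],
                  orr_by_tumor[c("tumor_type", "orr")], by = "tumor_type")
  all_keys <- union(cfr_by_tumor$tumor_type, orr_by_tumor$tumor_type)
  join <- data.frame(tumor_type = all_keys,
                     matched = all_keys %in% merged$tumor_type,
                     stringsAsFactors = FALSE)
  if (nrow(merged) < 4L)
    stop("fewer than 4 matched tumor types", call. = FALSE)
  sp <- spearman_cor(merged$cfr, merged$orr)
  c(sp, list(join = join))
}
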