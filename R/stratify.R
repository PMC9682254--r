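#' Immune cell / CAF ratio (ICFR) in score space
#'
#' In score space the "ratio" is the numerical difference between the ssGSEA
#' score of an immune-cell signature and the CAF signature score: per sample,
#' `icfr = score(immune_cell) - score(caf)`. With `immune_cell = "CD8 T
#' cells"` this is the CFR. The construction is antisymmetric in its two
#' signature arguments.
#'
#' @param scores A `ScoreTable` from [ssgsea_score()].
#' @param immune_cell Name of the immune-cell signature column.
#' @param caf Name of the fibroblast signature column (default `"CAF"`).
#' @return A `CfrResult`: data frame with columns `sample_id`, `cfr`,
#'   `component_immune`, `component_caf`; attribute `form =
#'   "score-difference"`.
#' @export
compute_icfr <- function(scores, immune_cell, caf = "CAF") {
  stopifnot(inherits(scores, "ScoreTable"))
  for (nm in c(immune_cell, caf)) {
    if (!nm %in% colnames(scores$scores))
      stop("signature column not present in score table: ", nm, call. = FALSE)
    if (anyNA(scores$scores[, nm]))
      stop("signature column contains missing scores: ", nm, call. = FALSE)
  }
  res <- data.frame(sample_id = rownames(scores$scores),
                    cfr = scores$scores[, immune_cell] - scores$scores[, caf],
                    component_immune = scores$scores[, immune_cell],
                    component_caf = scores$scores[, caf],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "form") <- "score-difference"
  attr(res, "signatures") <- c(immune = immune_cell, caf = caf)
  class(res) <- c("CfrResult", "data.frame")
  res
}

#' CFR from immunohistochemistry areas
#'
#' For stained-slide data the CFR is a true ratio: the CD8-positive area over
#' the fibroblast (alpha-SMA-positive) area. Multiple evaluated regions per
#' sample are summed before the ratio is taken (sum-then-ratio, not the
#' average of per-region ratios). Each area fraction is normalized against the
#' total evaluated area, which cancels in the ratio but is retained as the
#' components. Samples with zero fibroblast area are flagged unevaluable
#' (missing CFR), not infinite.
#'
#' @param areas Data frame with columns `sample_id`, `cd8_area`, `caf_area`,
#'   `total_area`; one or more rows (regions) per sample.
#' @return A `CfrResult` with attribute `form = "area-ratio"`.
#' @export
compute_ihc_cfr <- function(areas) {
  need <- c("sample_id", "cd8_area", "caf_area", "total_area")
  if (!is.data.frame(areas) || !all(need %in% names(areas)))
    stop("areas must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(areas$total_area <= 0))
    stop("total_area must be positive", call. = FALSE)
  if (any(areas$cd8_area < 0 | areas$caf_area < 0 |
          areas$cd8_area > areas$total_area |
          areas$caf_area > areas$total_area))
    stop("areas must satisfy 0 <= cd8_area, caf_area <= total_area",
         call. = FALSE)
  agg <- stats::aggregate(areas[c("cd8_area", "caf_area", "total_area")],
                          by = list(sample_id = areas$sample_id), FUN = sum)
  cfr <- ifelse(agg$caf_area > 0, agg$cd8_area / agg$caf_area, NA_real_)
  if (anyNA(cfr))
    warning(sum(is.na(cfr)),
            " sample(s) with zero fibroblast area flagged unevaluable",
            call. = FALSE)
  res <- data.frame(sample_id = agg$sample_id, cfr = cfr,
                    component_immune = agg$cd8_area / agg$total_area,
                    component_caf = agg$caf_area / agg$total_area,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "form") <- "area-ratio"
  class(res) <- c("CfrResult", "data.frame")
  res
}

# Log-rank (Savage/Peto) scores: a_i = event_i - NelsonAalen(time_i).
# These are the per-observation scores whose two-group linear statistic is the
# log-rank statistic; used by the maximally selected rank statistic. Ties in
# time share the cumulative hazard evaluated at their common time.
.logrank_scores <- function(time, event) {
  n <- length(time)
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]
  grp <- match(t_s, unique(t_s))          # distinct-time index, ascending
  first_idx <- which(!duplicated(grp))
  n_risk <- n - first_idx + 1L            # at risk at each distinct time
  d <- as.numeric(tapply(e_s, grp, sum))  # events at each distinct time
  ch <- cumsum(d / n_risk)                # Nelson-Aalen
  a <- numeric(n)
  a[o] <- e_s - ch[grp]
  a
}

#' Survival-optimal cutpoint by maximally selected rank statistics
#'
#' Scans candidate cutpoints over the observed marker values and returns the
#' one maximizing the absolute standardized two-group log-rank statistic for
#' the split `{marker <= c}` vs `{marker > c}`. The statistic uses log-rank
#' scores with the permutation (rank-statistic) variance, so the optimum is
#' invariant under strictly increasing transforms of the marker. Candidates
#' are restricted to splits whose low-group proportion lies in
#' `[max(min_prop, range[1]), min(1 - min_prop, range[2])]`, preventing
#' degenerate groups. Ties in the maximal statistic are broken toward the
#' candidate nearest the marker median.
#'
#' The approximate p-value is the Lausen-Schumacher improved-Bonferroni bound
#' for the maximum of the selection process; because that approximation is
#' anticonservative at small n, a seeded permutation p-value (marker permuted
#' `B` times) is available via `permutation_B`.
#'
#' @param marker Numeric marker per sample (non-constant).
#' @param time,event Survival time (>= 0) and status (1 = event).
#' @param min_prop Minimum group proportion, default 0.1.
#' @param range Candidate quantile range, default `c(0.1, 0.9)`.
#' @param permutation_B Number of marker permutations for the optional
#'   permutation p-value (0 = skip).
#' @param seed Seed for the permutation p-value.
#' @return An object of class `Cutpoint`: `value`, `statistic` (signed
#'   standardized statistic at the optimum), `p_approx`, `p_permutation`
#'   (or `NA`), `candidate_range` (marker values at the feasibility bounds),
#'   `group_sizes` (n_low, n_high), `n_candidates`.
#' @export
optimal_cutpoint <- function(marker, time, event, min_prop = 0.1,
                             range = c(0.1, 0.9), permutation_B = 0,
                             seed = 1L) {
  n <- length(marker)
  stopifnot(length(time) == n, length(event) == n)
  if (anyNA(marker) || anyNA(time) || anyNA(event))
    stop("missing values in marker or survival data", call. = FALSE)
  if (any(time < 0)) stop("negative survival times", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  if (length(unique(marker)) < 2L)
    stop("no admissible cutpoint: marker is constant", call. = FALSE)

  a <- .logrank_scores(time, event)
  abar <- mean(a)
  ss <- sum((a - abar)^2)

  o <- order(marker)
  m_sorted <- marker[o]
  cum_a <- cumsum(a[o])
  # candidate thresholds at distinct marker values (excluding the largest)
  distinct_last <- which(diff(m_sorted) > 0)   # index of last obs <= candidate
  lo_p <- max(min_prop, range[1L])
  hi_p <- min(1 - min_prop, range[2L])
  m_low <- distinct_last
  feasible <- (m_low / n >= lo_p) & (m_low / n <= hi_p)
  if (!any(feasible))
    stop("no admissible cutpoint inside the candidate range", call. = FALSE)
  idx <- distinct_last[feasible]
  mlow <- idx
  stat <- (cum_a[idx] - mlow * abar) /
    sqrt(mlow * (n - mlow) / (n * (n - 1)) * ss)
  values <- m_sorted[idx]

  amax <- max(abs(stat))
  best <- which(abs(stat) >= amax - 1e-12)
  if (length(best) > 1L) {
    med <- stats::median(marker)
    best <- best[which.min(abs(values[best] - med))]
  }
  eps1 <- min(mlow) / n
  eps2 <- max(mlow) / n
  b <- amax
  p_approx <- stats::dnorm(b) * ((b - 1 / b) *
      log((eps2 * (1 - eps1)) / (eps1 * (1 - eps2))) + 4 / b)
  p_approx <- min(1, max(0, p_approx))

  p_perm <- NA_real_
  if (permutation_B > 0) {
    set.seed(seed)
    exceed <- 0L
    for (bb in seq_len(permutation_B)) {
      mp <- sample(marker)
      op <- order(mp)
      ca <- cumsum(a[op])
      sp <- (ca[idx] - mlow * abar) /
        sqrt(mlow * (n - mlow) / (n * (n - 1)) * ss)
      if (max(abs(sp)) >= amax) exceed <- exceed + 1L
    }
    p_perm <- (1 + exceed) / (permutation_B + 1)
  }

  structure(list(value = values[best], statistic = stat[best],
                 p_approx = p_approx, p_permutation = p_perm,
                 candidate_range = c(low = min(values), high = max(values)),
                 quantile_range = c(lo_p, hi_p),
                 group_sizes = c(n_low = mlow[best], n_high = n - mlow[best]),
                 n_candidates = length(values)),
            class = "Cutpoint")
}

#' @export
print.Cutpoint <- function(x, ...) {
  cat(sprintf("<Cutpoint> value = %.6g, |S| = %.3f, p_approx = %.4g, groups = %d/%d\n",
              x$value, abs(x$statistic), x$p_approx,
              x$group_sizes[1L], x$group_sizes[2L]))
  invisible(x)
}

#' Write a cutpoint as JSON
#'
#' @param cut A `Cutpoint`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
cutpoint_to_json <- function(cut, path) {
  stopifnot(inherits(cut, "Cutpoint"))
  writeLines(jsonlite::toJSON(unclass(cut), auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' Dichotomize a CFR into high/low groups
#'
#' Label `"high"` iff `cfr > cut$value`, else `"low"` (values exactly at the
#' cutpoint are "low"; a fixed, documented boundary convention). Samples with
#' missing CFR get `NA` labels.
#'
#' @param cfr A `CfrResult` (or numeric vector named by sample).
#' @param cut A `Cutpoint` (or a single numeric cutpoint value).
#' @return A `StratifiedCohort`: data frame `sample_id`, `label`; attributes
#'   `scheme` and `cutpoint`.
#' @export
dichotomize <- function(cfr, cut) {
  if (inherits(cfr, "CfrResult")) {
    ids <- cfr$sample_id; v <- cfr$cfr
  } else {
    v <- as.numeric(cfr)
    ids <- if (!is.null(names(cfr))) names(cfr) else as.character(seq_along(v))
  }
  cval <- if (inherits(cut, "Cutpoint")) cut$value else as.numeric(cut)
  lab <- ifelse(is.na(v), NA_character_, ifelse(v > cval, "high", "low"))
  tab <- table(factor(lab, levels = c("low", "high")))
  if (any(tab == 0L))
    warning("degenerate split: all samples on one side of the cutpoint",
            call. = FALSE)
  res <- data.frame(sample_id = ids,
                    label = factor(lab, levels = c("low", "high")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "scheme") <- "cfr-dichotomy"
  attr(res, "cutpoint") <- cval
  class(res) <- c("StratifiedCohort", "data.frame")
  res
}

#' Four-class CD8 x CAF stratification
#'
#' Cross-classifies samples by independent CD8 and CAF cutpoints into
#' `CD8hiCAFhi`, `CD8loCAFhi`, `CD8hiCAFlo`, `CD8loCAFlo` — the categorical
#' comparator model to the CFR dichotomy.
#'
#' @param cd8_scores,caf_scores Named (or parallel) numeric score vectors.
#' @param cd8_cut,caf_cut `Cutpoint`s (or numeric values), each fit on its own
#'   marker.
#' @param sample_ids Optional sample identifiers.
#' @return A `StratifiedCohort` with the four labels.
#' @export
four_class <- function(cd8_scores, caf_scores, cd8_cut, caf_cut,
                       sample_ids = NULL) {
  stopifnot(length(cd8_scores) == length(caf_scores))
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(names(cd8_scores))) names(cd8_scores)
                  else as.character(seq_along(cd8_scores))
  c8 <- if (inherits(cd8_cut, "Cutpoint")) cd8_cut$value else as.numeric(cd8_cut)
  cf <- if (inherits(caf_cut, "Cutpoint")) caf_cut$value else as.numeric(caf_cut)
  lab <- paste0(ifelse(cd8_scores > c8, "CD8hi", "CD8lo"),
                ifelse(caf_scores > cf, "CAFhi", "CAFlo"))
  res <- data.frame(sample_id = sample_ids,
                    label = factor(lab, levels = c("CD8hiCAFhi", "CD8loCAFhi",
                                                   "CD8hiCAFlo", "CD8loCAFlo")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "scheme") <- "four-class"
  attr(res, "cutpoint") <- c(cd8 = c8, caf = cf)
  class(res) <- c("StratifiedCohort", "data.frame")
  res
}

#' Immune-infiltration clusters by K-means
#'
#' Unsupervised K-means on the immune-cell score matrix, with clusters
#' relabeled by descending cluster mean of the composite immune score:
#' `"high"`, `"medium"`, `"low"` for the default k = 3 (ranked `infil1`,
#' `infil2`, ... for larger k). Seeded, with multiple restarts.
#'
#' @param scores A `ScoreTable` (immune-cell signature columns are used).
#' @param k Number of clusters, default 3.
#' @param seed Random seed (recorded in the output).
#' @param nstart Number of K-means restarts, default 50.
#' @param cell_types Columns to cluster on; default the built-in immune-cell
#'   names present in the table (all columns if none match).
#' @param immune Optional per-sample composite immune score used to rank the
#'   clusters; default the row mean of the clustered columns.
#' @return A `StratifiedCohort` with ordered infiltration labels.
#' @export
infiltration_clusters <- function(scores, k = 3, seed = 1L, nstart = 50,
                                  cell_types = NULL, immune = NULL) {
  stopifnot(inherits(scores, "ScoreTable"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.null(cell_types)) {
    cell_types <- intersect(immune_cell_types(), colnames(scores$scores))
    if (length(cell_types) == 0L) cell_types <- colnames(scores$scores)
  }
  x <- scores$scores[, cell_types, drop = FALSE]
  if (anyNA(x)) stop("missing scores in clustering columns", call. = FALSE)
  if (k > nrow(x)) stop("k exceeds the number of samples", call. = FALSE)
  if (is.null(immune)) immune <- rowMeans(x)
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart)
  rank_means <- tapply(immune, km$cluster, mean)
  ord <- order(rank_means, decreasing = TRUE)  # cluster ids, highest first
  level_names <- if (k <= 3) c("high", "medium", "low")[seq_len(k)]
                 else paste0("infil", seq_len(k))
  relabel <- stats::setNames(level_names, as.character(ord))
  lab <- relabel[as.character(km$cluster)]
  res <- data.frame(sample_id = rownames(x),
                    label = factor(lab, levels = level_names),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "scheme") <- "infiltration-kmeans"
  attr(res, "seed") <- seed
  attr(res, "cluster_means") <- rank_means[ord]
  class(res) <- c("StratifiedCohort", "data.frame")
  res
}

#' Write a stratified cohort as a tab-separated table
#'
#' @param sc A `StratifiedCohort` or `CfrResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(sc, path) {
  utils::write.table(as.data.frame(sc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
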