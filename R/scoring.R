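#' Descending ranks with midrank ties
#'
#' Rank 1 is the largest value; tied values receive the average of the ranks
#' they span. Support routine for the ssGSEA walk.
#'
#' @param values Numeric vector.
#' @return Numeric vector of descending midranks.
#' @export
rank_with_ties <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  rank(-values, ties.method = "average", na.last = "keep")
}

# ssGSEA enrichment score for one sample against one gene set.
#
# x: expression vector (no NA), names = gene ids; set: character vector of
# matched set genes; alpha: rank-weight exponent. Genes are walked in order of
# decreasing expression (ties broken by gene identifier so the score is
# invariant to the storage order of rows); at each step the weighted running
# fraction of set genes (weights = ascending midrank ^ alpha, i.e. the most
# highly expressed gene carries weight ~ G^alpha) minus the running fraction
# of non-set genes is accumulated. The ES is the sum of those differences.
.es_one <- function(in_set, ord, asc_rank, alpha) {
  in_ord <- in_set[ord]
  w <- asc_rank[ord]^alpha
  w[!in_ord] <- 0
  tot_in <- sum(w)
  n_out <- sum(!in_ord)
  p_in <- cumsum(w) / tot_in
  p_out <- cumsum(!in_ord) / n_out
  sum(p_in - p_out)
}

#' Single-sample gene set enrichment (ssGSEA) scores
#'
#' Rank-based per-sample enrichment of each registry signature relative to all
#' other genes in the matrix. For each sample, genes are ranked by expression;
#' walking down the ranked list, the running rank-weighted fraction of
#' signature genes (weight = midrank from the bottom raised to `alpha`) minus
#' the running fraction of non-signature genes is summed to give the
#' enrichment score. Scores depend only on within-sample ranks, so they are
#' invariant under any strictly increasing per-sample transform and under row
#' permutations of the input.
#'
#' Signature genes absent from the matrix are dropped (coverage is reported);
#' a signature with fewer than 2 matched genes yields an all-`NA` column with
#' a warning; a signature covering every gene in the matrix is an error (the
#' complement running fraction is undefined). Genes with missing expression in
#' a sample are excluded from that sample's ranking, with a warning reporting
#' the count.
#'
#' @param m Expression matrix (genes x samples), non-negative or log-space.
#' @param registry A [signature_registry()] (or a single [gene_signature()]).
#' @param alpha Rank-weight exponent, default 0.25.
#' @param normalize When `TRUE` (default) all scores are divided by the range
#'   (max - min) of the enrichment scores over the entire table, the
#'   cross-sample normalization convention of ssGSEA; `"per-signature"`
#'   rescales each signature column by its own range.
#' @return An object of class `ScoreTable`: list with `scores` (samples x
#'   signatures numeric matrix), `alpha`, `normalized`, and `coverage` (data
#'   frame of matched/total genes per signature).
#' @export
ssgsea_score <- function(m, registry, alpha = 0.25, normalize = TRUE) {
  if (inherits(registry, "GeneSignature"))
    registry <- signature_registry(list(registry))
  stopifnot(inherits(registry, "SignatureRegistry"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a non-negative scalar", call. = FALSE)
  validate_expression(m, allow_log = TRUE, allow_duplicate_genes = FALSE)
  genes <- rownames(m)
  samples <- colnames(m)

  matched <- lapply(unclass(registry), function(s) intersect(s$genes, genes))
  coverage <- data.frame(
    signature = names(registry),
    matched = vapply(matched, length, integer(1)),
    total = vapply(unclass(registry), function(s) length(s$genes), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  low <- coverage$matched < 2L
  if (any(low))
    warning("signature(s) with < 2 matched genes scored as NA: ",
            paste(coverage$signature[low], collapse = ", "), call. = FALSE)
  if (any(coverage$matched == nrow(m)))
    stop("signature covers every gene in the matrix; complement is undefined: ",
         paste(coverage$signature[coverage$matched == nrow(m)],
               collapse = ", "), call. = FALSE)
  in_set <- lapply(matched, function(g) genes %in% g)

  es <- matrix(NA_real_, ncol(m), length(registry),
               dimnames = list(samples, names(registry)))
  n_na_dropped <- 0L
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    n_na_dropped <- n_na_dropped + sum(!ok)
    xj <- x[ok]
    # decreasing expression, gene-id tie-break: storage-order invariant
    ord <- order(-xj, genes[ok], method = "radix")
    asc_rank <- rank(xj, ties.method = "average")
    for (k in seq_along(registry)) {
      if (low[[k]]) next
      ins <- in_set[[k]][ok]
      if (sum(ins) < 2L) next
      es[j, k] <- .es_one(ins, ord, asc_rank, alpha)
    }
  }
  if (n_na_dropped > 0L)
    warning(sprintf("%d missing expression value(s) excluded from ranking",
                    n_na_dropped), call. = FALSE)

  norm_mode <- "none"
  if (isTRUE(normalize) || identical(normalize, "global")) {
    rng <- range(es, na.rm = TRUE)
    if (diff(rng) > 0) es <- es / diff(rng)
    norm_mode <- "global-range"
  } else if (identical(normalize, "per-signature")) {
    for (k in seq_len(ncol(es))) {
      rng <- range(es[, k], na.rm = TRUE)
      if (diff(rng) > 0) es[, k] <- es[, k] / diff(rng)
    }
    norm_mode <- "per-signature-range"
  }

  structure(list(scores = es, alpha = alpha, normalized = norm_mode,
                 coverage = coverage),
            class = "ScoreTable")
}

#' @export
print.ScoreTable <- function(x, ...) {
  cat(sprintf("<ScoreTable> %d sample(s) x %d signature(s), alpha = %g, normalization = %s\n",
              nrow(x$scores), ncol(x$scores), x$alpha, x$normalized))
  invisible(x)
}

#' Composite immune-infiltration score
#'
#' ssGSEA score of a broad immune meta-signature, summarizing overall immune
#' infiltration (the role the ESTIMATE immune score plays in bulk-expression
#' deconvolution). The shipped default meta-signature is the union of the 24
#' built-in immune-cell signatures; users may substitute the published
#' ESTIMATE immune gene list (or any other) via `meta_signature`.
#'
#' @param m Expression matrix.
#' @param meta_signature Optional [gene_signature()]; default union of the 24
#'   built-in immune-cell lists.
#' @param alpha,normalize Passed to [ssgsea_score()].
#' @return Named numeric vector of per-sample scores.
#' @export
immune_score <- function(m, meta_signature = NULL, alpha = 0.25,
                         normalize = TRUE) {
  if (is.null(meta_signature)) {
    reg <- builtin_registry()
    genes <- unique(unlist(lapply(immune_cell_types(),
                                  function(nm) reg[[nm]]$genes)))
    meta_signature <- gene_signature("ImmuneScore", genes,
                                     source = "union of built-in immune-cell signatures")
  }
  stopifnot(inherits(meta_signature, "GeneSignature"))
  st <- ssgsea_score(m, meta_signature, alpha = alpha, normalize = normalize)
  st$scores[, 1L]
}

#' Write a score table with its JSON parameter sidecar
#'
#' The tab-separated file holds samples x signatures scores; the sidecar
#' (`<path>.json`) records alpha, normalization mode and per-signature gene
#' coverage.
#'
#' @param st A `ScoreTable`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(st, path) {
  stopifnot(inherits(st, "ScoreTable"))
  df <- cbind(data.frame(sample_id = rownames(st$scores)),
              data.frame(st$scores, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(alpha = st$alpha, normalized = st$normalized,
                  coverage = st$coverage)
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#'
#' @param path TSV path (sidecar `<path>.json` read when present).
#' @return A `ScoreTable`.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  scores <- as.matrix(df[, -1L, drop = FALSE])
  rownames(scores) <- df[[1L]]
  alpha <- NA_real_; normalized <- "unknown"; coverage <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    side <- jsonlite::fromJSON(sc)
    alpha <- side$alpha; normalized <- side$normalized
    coverage <- side$coverage
  }
  structure(list(scores = scores, alpha = alpha, normalized = normalized,
                 coverage = coverage),
            class = "ScoreTable")
}
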