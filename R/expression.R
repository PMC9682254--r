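#' Validate an expression matrix
#'
#' Expression matrices are plain numeric matrices, genes in rows (rownames =
#' gene identifiers), samples in columns (colnames = sample identifiers),
#' values non-negative and finite (FPKM, TPM or array intensities; matrices
#' already in log space may be passed with `allow_log = TRUE`, which drops the
#' non-negativity requirement — rank-based scoring is unaffected).
#'
#' @param m Numeric matrix with row and column names.
#' @param allow_log Allow negative (log-space) values.
#' @param allow_duplicate_genes Allow duplicate row identifiers (to be
#'   resolved by [collapse_duplicate_genes()] before scoring).
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(m, allow_log = FALSE,
                                allow_duplicate_genes = TRUE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  if (!allow_duplicate_genes && anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers present; run collapse_duplicate_genes()",
         call. = FALSE)
  if (any(!is.finite(m) & !is.na(m)))
    stop("expression values must be finite", call. = FALSE)
  if (!allow_log && any(m < 0, na.rm = TRUE))
    stop("negative expression values; pass allow_log = TRUE for log-space data",
         call. = FALSE)
  invisible(m)
}

#' Convert FPKM to TPM
#'
#' Per sample j, `out[i, j] = in[i, j] / sum_i(in[i, j]) * 1e6`, so every
#' column sums to one million. The transform is idempotent and per-column
#' scale invariant; it does not change within-sample ranks, so downstream
#' ssGSEA scores are unaffected — it is provided so absolute values are
#' comparable across samples in reports.
#'
#' @param m Expression matrix (genes x samples), values >= 0.
#' @return Matrix of the same shape with columns summing to 1e6.
#' @export
fpkm_to_tpm <- function(m) {
  validate_expression(m)
  cs <- colSums(m, na.rm = TRUE)
  if (any(cs <= 0))
    stop("all-zero expression column(s): ",
         paste(colnames(m)[cs <= 0], collapse = ", "), call. = FALSE)
  sweep(m, 2, cs, "/") * 1e6
}

#' Collapse duplicate gene rows
#'
#' Resolves duplicate gene identifiers to a single row. `"max-mean"` (the
#' array-era convention) keeps, per identifier, the row with the highest row
#' mean; mean ties fall back to the first occurrence with a warning.
#' `"first"` always keeps the first occurrence.
#'
#' @param m Expression matrix.
#' @param method `"max-mean"` or `"first"`.
#' @return Matrix with unique row identifiers, original relative order kept.
#' @export
collapse_duplicate_genes <- function(m, method = c("max-mean", "first")) {
  method <- match.arg(method)
  validate_expression(m, allow_log = TRUE)
  if (!anyDuplicated(rownames(m))) return(m)
  ids <- rownames(m)
  keep <- rep(TRUE, nrow(m))
  if (method == "first") {
    keep <- !duplicated(ids)
  } else {
    rm_ <- rowMeans(m, na.rm = TRUE)
    for (g in unique(ids[duplicated(ids)])) {
      idx <- which(ids == g)
      best <- idx[which.max(rm_[idx])]
      if (sum(rm_[idx] == rm_[best]) > 1L) {
        best <- idx[rm_[idx] == rm_[best]][1L]
        warning("collapse_duplicate_genes: mean tie for '", g,
                "', keeping first occurrence", call. = FALSE)
      }
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  m[keep, , drop = FALSE]
}

#' Log2 transform with pseudocount
#'
#' `log2(x + pseudocount)`. A strictly monotone per-sample map, so ssGSEA
#' scores are identical before and after; offered for parity with array-style
#' pipelines and for plotting.
#'
#' @param m Expression matrix.
#' @param pseudocount Positive offset, default 1.
#' @return Transformed matrix.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a positive scalar", call. = FALSE)
  validate_expression(m)
  log2(m + pseudocount)
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs >= 2 columns", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  validate_expression(m, allow_log = TRUE)
  m
}

#' Write an expression matrix as tab-separated text
#'
#' @param m Expression matrix.
#' @param path Output path.
#' @param id_column Name for the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path, id_column = "gene_id") {
  df <- data.frame(m, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(m)), id_column), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GCT 1.2 expression file
#'
#' GCT 1.2: line 1 `#1.2`, line 2 `<n_genes>\t<n_samples>`, line 3 header
#' (`Name`, `Description`, samples...), then one row per gene.
#'
#' @param path Path to a GCT file.
#' @return Numeric matrix, genes x samples.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || !grepl("^#1\\.2", header[[1L]]))
    stop("not a GCT 1.2 file (missing '#1.2' header): ", path, call. = FALSE)
  dims <- as.integer(strsplit(header[[2L]], "\t", fixed = TRUE)[[1L]][1:2])
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = 2L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("GCT needs Name, Description and sample columns",
                          call. = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  if (!is.na(dims[1L]) && nrow(m) != dims[1L])
    warning(sprintf("GCT header declares %d genes, found %d", dims[1L],
                    nrow(m)), call. = FALSE)
  validate_expression(m, allow_log = TRUE)
  m
}

#' Write a GCT 1.2 expression file
#'
#' @param m Expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- cbind(data.frame(Name = rownames(m), Description = "na"),
              data.frame(m, check.names = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
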