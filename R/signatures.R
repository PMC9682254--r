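#' Construct a gene signature
#'
#' A `GeneSignature` is a named, ordered list of gene symbols together with a
#' free-text provenance tag. Duplicate symbols are collapsed keeping the first
#' occurrence; empty symbols are rejected. Matching against expression
#' matrices elsewhere in the package is case-sensitive and exact.
#'
#' @param name Short signature name (non-empty string).
#' @param genes Character vector of gene symbols.
#' @param source Free-text provenance tag.
#' @param warn_duplicates Emit a warning when duplicate symbols are collapsed.
#' @return An object of class `GeneSignature` with fields `name`, `genes`,
#'   `source`.
#' @export
gene_signature <- function(name, genes, source = "", warn_duplicates = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("signature name must be a non-empty string", call. = FALSE)
  genes <- as.character(genes)
  if (any(is.na(genes) | !nzchar(genes)))
    stop("signature '", name, "' contains empty gene symbols", call. = FALSE)
  dup <- duplicated(genes)
  if (any(dup)) {
    if (warn_duplicates)
      warning(sprintf("signature '%s': %d duplicate gene symbol(s) collapsed",
                      name, sum(dup)), call. = FALSE)
    genes <- genes[!dup]
  }
  if (length(genes) == 0L)
    stop("signature '", name, "' is empty after deduplication", call. = FALSE)
  structure(list(name = name, genes = genes, source = as.character(source)),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("<GeneSignature> %s: %d genes (%s)\n", x$name,
              length(x$genes), if (nzchar(x$source)) x$source else "unsourced"))
  invisible(x)
}

#' Construct a signature registry
#'
#' @param signatures List of [gene_signature()] objects with unique names.
#' @return An object of class `SignatureRegistry`: a named list of signatures.
#' @export
signature_registry <- function(signatures = list()) {
  if (!all(vapply(signatures, inherits, logical(1), "GeneSignature")))
    stop("all elements must be GeneSignature objects", call. = FALSE)
  nms <- vapply(signatures, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate signature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(signatures) <- nms
  structure(signatures, class = "SignatureRegistry")
}

#' @export
print.SignatureRegistry <- function(x, ...) {
  cat(sprintf("<SignatureRegistry> %d signature(s)\n", length(x)))
  for (s in x)
    cat(sprintf("  %-22s %3d genes  %s\n", s$name, length(s$genes), s$source))
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' GMT is tab-separated: one set per line, fields name, description, then gene
#' symbols. Duplicate symbols within a line are collapsed (first occurrence
#' kept) with a warning; duplicate set names across lines are an error.
#'
#' @param path Path to a GMT file.
#' @return A [signature_registry()].
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 gene",
                   i), call. = FALSE)
    sigs[[i]] <- gene_signature(fields[[1]], fields[-(1:2)],
                                source = fields[[2]], warn_duplicates = TRUE)
  }
  signature_registry(sigs)
}

#' Write a signature registry to a GMT file
#'
#' @param registry A [signature_registry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(registry, path) {
  stopifnot(inherits(registry, "SignatureRegistry"))
  lines <- vapply(registry, function(s) {
    desc <- if (nzchar(s$source)) s$source else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a signature registry as JSON
#'
#' @param registry A [signature_registry()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
registry_to_json <- function(registry, path = NULL) {
  stopifnot(inherits(registry, "SignatureRegistry"))
  obj <- lapply(unclass(registry), function(s)
    list(name = s$name, source = s$source, n_genes = length(s$genes),
         genes = s$genes))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Apply a symbol alias table to a registry
#'
#' Gene symbols are matched case-sensitively and verbatim; legacy symbols in
#' the shipped lists are deliberately not modernized. Users who need updated
#' symbols supply an alias table mapping `old` to `new`.
#'
#' @param registry A [signature_registry()].
#' @param aliases Data frame with columns `old` and `new`.
#' @return A new registry with symbols replaced (and re-deduplicated).
#' @export
apply_aliases <- function(registry, aliases) {
  stopifnot(inherits(registry, "SignatureRegistry"),
            is.data.frame(aliases), all(c("old", "new") %in% names(aliases)))
  map <- stats::setNames(as.character(aliases$new), as.character(aliases$old))
  signature_registry(lapply(unclass(registry), function(s) {
    g <- s$genes
    hit <- g %in% names(map)
    g[hit] <- unname(map[g[hit]])
    gene_signature(s$name, g, source = s$source)
  }))
}

#' Built-in tumor-microenvironment signature registry
#'
#' Returns the shipped registry: 24 immune-cell signatures spanning innate and
#' adaptive immunity plus the 8-gene cancer-associated fibroblast ("CAF")
#' signature of the MCP-counter population markers. The "CD8 T cells" list is
#' the published 38-entry marker list kept verbatim (two symbols appear twice
#' in print and are deduplicated to 36; legacy symbols such as C4orf15, MYST3
#' and SFRS7 are intentionally not modernized — see [apply_aliases()]). The
#' marker lists of the other 23 immune-cell types are synthetic
#' reconstructions assembled from standard immunology marker knowledge, and
#' should be treated as replaceable input (supply your own GMT via
#' [load_gmt()] for production use).
#'
#' @return A [signature_registry()] with 25 signatures.
#' @export
builtin_registry <- function() {
  sigs <- mapply(function(nm, genes) {
    src <- switch(nm,
      "CD8 T cells" = "published CD8+ T-cell marker list (verbatim, deduplicated)",
      "CAF" = "MCP-counter fibroblast population markers",
      "synthetic reconstruction of immune-cell markers")
    gene_signature(nm, genes, source = src)
  }, names(.builtin_signature_genes), .builtin_signature_genes,
  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  signature_registry(sigs)
}

#' Names of the 24 built-in immune-cell signatures
#'
#' All built-in signature names except "CAF"; the complement used for
#' immune-infiltration scoring and ICFR batteries.
#'
#' @return Character vector of length 24.
#' @export
immune_cell_types <- function() {
  setdiff(names(.builtin_signature_genes), "CAF")
}
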