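#' Pair-indicator matrix
#'
#' Internal constructor for the binary pairs x samples matrix. Row names
#' are pair identifiers `"A|B"` with `A < B` in the fixed lexicographic
#' gene ordering; entries are the within-sample comparison indicator
#' (1 when gene A is expressed above gene B, 0 otherwise, ties scoring 0).
#'
#' @param values integer/numeric 0-1 matrix with pair rownames and sample
#'   colnames.
#' @return A `pair_matrix`: list with `values`, `pairs` (tibble `pair_id`,
#'   `gene_a`, `gene_b`, `one_frequency`) and `sample_ids`.
#' @keywords internal
#' @export
new_pair_matrix <- function(values) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (is.null(rownames(values))) {
    if (nrow(values) > 0) abort("pair matrix needs pair-id rownames")
    rownames(values) <- character(0)
  }
  if (!all(values %in% c(0, 1))) abort("pair indicators must be 0 or 1")
  ab <- stringr::str_split_fixed(rownames(values), stringr::fixed("|"), 2)
  structure(list(
    values = values,
    pairs = tibble(pair_id = rownames(values),
                   gene_a = ab[, 1], gene_b = ab[, 2],
                   one_frequency = unname(rowMeans(values))),
    sample_ids = colnames(values)
  ), class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("<pair_matrix> %d pairs x %d samples\n",
              nrow(x$values), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.pair_matrix <- function(x) dim(x$values)

#' Per-pair summary of a pair matrix
#'
#' @param x a [pair_matrix][new_pair_matrix].
#' @param ... unused.
#' @return Tibble `pair_id`, `gene_a`, `gene_b`, `one_frequency`.
#' @export
tidy.pair_matrix <- function(x, ...) x$pairs

#' Build the 0/1 gene-pair indicator matrix
#'
#' For every unordered pair of the supplied genes (taken with `A < B`
#' lexicographically), the per-sample indicator is 1 when A's expression
#' strictly exceeds B's and 0 otherwise (ties score 0). Because the
#' indicator only compares expression *within* a sample, the matrix is
#' invariant to any strictly increasing transform applied to a whole
#' sample -- the property that makes pair signatures independent of
#' normalization and measurement scale. Pairs are generated in
#' deterministic chunks so large gene sets stream rather than allocate one
#' giant intermediate.
#'
#' @param expr an [lnc_expression].
#' @param genes character vector of at least 2 gene ids present in `expr`.
#' @param chunk_size pairs per processing chunk.
#' @return A [pair_matrix][new_pair_matrix] with `choose(length(genes), 2)`
#'   rows.
#' @export
build_pair_matrix <- function(expr, genes, chunk_size = 50000L) {
  stopifnot(inherits(expr, "lnc_expression"))
  genes <- sort(unique(genes))
  if (length(genes) < 2) abort("need at least 2 genes to form pairs")
  miss <- setdiff(genes, rownames(expr$values))
  if (length(miss)) abort(paste0("genes not in matrix: ",
                                 paste(head(miss, 5), collapse = ", ")))
  x <- expr$values[genes, , drop = FALSE]
  idx <- combn(length(genes), 2)
  n_pair <- ncol(idx)
  out <- matrix(0L, n_pair, ncol(x),
                dimnames = list(paste(genes[idx[1, ]], genes[idx[2, ]],
                                      sep = "|"),
                                colnames(x)))
  starts <- seq(1L, n_pair, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n_pair)
    ia <- idx[1, s:e]; ib <- idx[2, s:e]
    out[s:e, ] <- (x[ia, , drop = FALSE] > x[ib, , drop = FALSE]) * 1L
  }
  new_pair_matrix(out)
}

#' Filter pairs to those informative in a sizeable share of samples
#'
#' A pair whose indicator is (almost) constant carries no prognostic
#' contrast: there is no level of the pairing that can separate survival
#' outcomes. A pair is kept when *both* indicator outcomes occur in more
#' than `min_frac` of the samples, i.e. its one-frequency lies strictly
#' inside `(min_frac, 1 - min_frac)`. Row order is preserved.
#'
#' @param pm a [pair_matrix][new_pair_matrix].
#' @param min_frac validity threshold (default 0.3).
#' @return The filtered `pair_matrix` (possibly empty, with a message).
#' @export
validity_filter <- function(pm, min_frac = 0.3) {
  stopifnot(inherits(pm, "pair_matrix"))
  f <- pm$pairs$one_frequency
  keep <- pmin(f, 1 - f) > min_frac
  if (!any(keep)) inform("validity_filter: no pairs survive")
  new_pair_matrix(pm$values[keep, , drop = FALSE])
}

#' Write / read a pair-indicator matrix as TSV
#'
#' First column `pair_id`, one column per sample; values 0/1.
#'
#' @param pm a [pair_matrix][new_pair_matrix].
#' @param path TSV path.
#' @return `path` (write) or a `pair_matrix` (read).
#' @export
write_pair_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "pair_matrix"))
  df <- dplyr::bind_cols(tibble(pair_id = rownames(pm$values)),
                         as_tibble(pm$values))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    pair_id = "c", .default = "i"), progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$pair_id
  new_pair_matrix(m)
}

#' Restrict a pair matrix to given pairs and/or samples
#'
#' @param pm a [pair_matrix][new_pair_matrix].
#' @param pairs,samples identifiers to keep in order; `NULL` keeps all.
#' @return A `pair_matrix`.
#' @export
subset_pairs <- function(pm, pairs = NULL, samples = NULL) {
  stopifnot(inherits(pm, "pair_matrix"))
  ri <- if (is.null(pairs)) seq_len(nrow(pm$values)) else {
    miss <- setdiff(pairs, rownames(pm$values))
    if (length(miss)) abort(paste0("pairs not found: ",
                                   paste(head(miss, 5), collapse = ", ")))
    match(pairs, rownames(pm$values))
  }
  ci <- if (is.null(samples)) seq_len(ncol(pm$values)) else {
    miss <- setdiff(samples, colnames(pm$values))
    if (length(miss)) abort(paste0("samples not found: ",
                                   paste(head(miss, 5), collapse = ", ")))
    match(samples, colnames(pm$values))
  }
  new_pair_matrix(pm$values[ri, ci, drop = FALSE])
}
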