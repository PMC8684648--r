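#' Expression matrix container
#'
#' A light container for an FPKM-scale expression matrix together with
#' per-gene biotype labels and per-sample group labels. Values are stored
#' as a base numeric matrix (genes in rows, samples in columns); gene and
#' sample annotations are tibbles so they compose with dplyr verbs.
#'
#' @param values numeric matrix, genes x samples, nonnegative, no missing
#'   entries. Rownames are gene identifiers, colnames sample identifiers.
#' @param biotype character vector, one of `"lncRNA"`, `"protein_coding"`,
#'   `"other"` per gene. Recycled if length 1.
#' @param group character vector, `"tumor"` or `"normal"` per sample.
#'   Recycled if length 1.
#'
#' @return An object of class `lnc_expression`: a list with elements
#'   `values` (matrix), `genes` (tibble: `gene_id`, `biotype`) and
#'   `samples` (tibble: `sample_id`, `group`).
#' @export
#' @examples
#' m <- matrix(rexp(6), 3, 2,
#'   dimnames = list(c("G1", "G2", "G3"), c("s1", "s2")))
#' lnc_expression(m, biotype = c("lncRNA", "protein_coding", "other"),
#'   group = "tumor")
lnc_expression <- function(values, biotype = "other", group = "tumor") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene rownames and sample colnames.")
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    abort(sprintf("missing expression value at gene '%s', sample '%s'",
                  rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (any(values < 0)) abort("expression values must be nonnegative")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    abort(paste0("duplicate gene ids: ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    abort(paste0("duplicate sample ids: ", paste(dup, collapse = ", ")))
  }
  biotype <- vctrs_recycle(biotype, nrow(values), "biotype")
  group <- vctrs_recycle(group, ncol(values), "group")
  if (!all(biotype %in% c("lncRNA", "protein_coding", "other"))) {
    abort("biotype must be one of 'lncRNA', 'protein_coding', 'other'")
  }
  if (!all(group %in% c("tumor", "normal"))) {
    abort("group must be 'tumor' or 'normal'")
  }
  structure(
    list(
      values = values,
      genes = tibble(gene_id = rownames(values), biotype = biotype),
      samples = tibble(sample_id = colnames(values), group = group)
    ),
    class = "lnc_expression"
  )
}

vctrs_recycle <- function(x, n, what) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) {
    abort(sprintf("`%s` must have length %d (got %d)", what, n, length(x)))
  }
  x
}

#' @export
print.lnc_expression <- function(x, ...) {
  cat(sprintf("<lnc_expression> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  biotypes:", paste(sprintf("%s=%d", names(table(x$genes$biotype)),
                                   table(x$genes$biotype)), collapse = ", "), "\n")
  cat("  groups:  ", paste(sprintf("%s=%d", names(table(x$samples$group)),
                                   table(x$samples$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.lnc_expression <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an [lnc_expression] object.
#' @param genes,samples character vectors of identifiers to keep (in the
#'   given order); `NULL` keeps all.
#' @return An [lnc_expression] restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "lnc_expression"))
  gi <- if (is.null(genes)) seq_len(nrow(x$values)) else {
    miss <- setdiff(genes, rownames(x$values))
    if (length(miss)) abort(paste0("genes not found: ",
                                   paste(head(miss, 5), collapse = ", ")))
    match(genes, rownames(x$values))
  }
  si <- if (is.null(samples)) seq_len(ncol(x$values)) else {
    miss <- setdiff(samples, colnames(x$values))
    if (length(miss)) abort(paste0("samples not found: ",
                                   paste(head(miss, 5), collapse = ", ")))
    match(samples, colnames(x$values))
  }
  lnc_expression(x$values[gi, si, drop = FALSE],
                 biotype = x$genes$biotype[gi],
                 group = x$samples$group[si])
}

#' Gene identifiers of a given biotype
#'
#' @param x an [lnc_expression] object.
#' @param biotype biotype label to select.
#' @return Character vector of gene ids.
#' @export
genes_of_biotype <- function(x, biotype = "lncRNA") {
  stopifnot(inherits(x, "lnc_expression"))
  x$genes$gene_id[x$genes$biotype == biotype]
}

#' Strip Ensembl-style version suffixes from gene identifiers
#'
#' `"ENSG00000141510.15"` becomes `"ENSG00000141510"`; identifiers without
#' a trailing `.N` are returned unchanged (gene symbols pass through).
#'
#' @param ids character vector of gene identifiers.
#' @return Character vector of normalized identifiers.
#' @export
strip_gene_version <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}

#' log2(x + 1) transform of the expression values
#'
#' The screening and differential-expression stages operate on
#' log2(FPKM + 1); this helper centralizes the transform.
#'
#' @param x an [lnc_expression] object or numeric matrix.
#' @return A numeric matrix of log2(x + 1) values.
#' @export
log2p1 <- function(x) {
  if (inherits(x, "lnc_expression")) x <- x$values
  log2(x + 1)
}
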