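#' Read an expression matrix with gene biotypes and sample groups
#'
#' Reads a tab-delimited expression table (first column gene id, remaining
#' columns one per sample, FPKM-scale values), assigns gene biotypes from an
#' annotation file and sample groups from an optional sidecar table.
#' Ensembl-style version suffixes are stripped from gene ids before any
#' matching. Missing or nonnumeric cells are an error (with coordinates),
#' never silently imputed.
#'
#' @param path TSV of expression values.
#' @param annotation_path a GTF file (attributes `gene_id` and
#'   `gene_biotype`/`gene_type`) or a two-column TSV (`gene_id`, `biotype`).
#'   Genes absent from the annotation get biotype `"other"`.
#' @param groups_path optional TSV with columns `sample_id`, `group`
#'   (`tumor`/`normal`). Samples absent from the table default to
#'   `"tumor"`; with no table every sample is `"tumor"`.
#' @return An [lnc_expression] object.
#' @export
read_expression <- function(path, annotation_path = NULL, groups_path = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expression table needs a gene column plus samples")
  gene_ids <- strip_gene_version(raw[[1]])
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    abort(paste0("duplicate gene ids after version stripping: ",
                 paste(dup, collapse = ", ")))
  }
  vals <- as.matrix(raw[, -1])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "nonnumeric or missing expression value '%s' at gene '%s', sample '%s'",
      vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
      colnames(raw)[-1][bad[1, 2]]))
  }
  dimnames(num) <- list(gene_ids, colnames(raw)[-1])

  biotype <- rep("other", length(gene_ids))
  if (!is.null(annotation_path)) {
    ann <- read_annotation(annotation_path)
    hit <- match(gene_ids, ann$gene_id)
    biotype[!is.na(hit)] <- ann$biotype[hit[!is.na(hit)]]
  }

  group <- rep("tumor", ncol(num))
  if (!is.null(groups_path)) {
    grp <- readr::read_tsv(groups_path,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (!all(c("sample_id", "group") %in% names(grp))) {
      abort("groups table must have columns sample_id and group")
    }
    hit <- match(colnames(num), grp$sample_id)
    group[!is.na(hit)] <- grp$group[hit[!is.na(hit)]]
  }
  lnc_expression(num, biotype = biotype, group = group)
}

#' Read a gene-biotype annotation (GTF or two-column TSV)
#'
#' GTF files are parsed with rtracklayer; gene biotypes come from the
#' `gene_biotype` (Ensembl) or `gene_type` (GENCODE) attribute. Labels other
#' than `lncRNA`/`protein_coding` collapse to `"other"`; the GENCODE
#' spelling `lincRNA` and `lncRNA` variants map to `"lncRNA"`.
#'
#' @param path `.gtf`/`.gff` file or TSV with columns `gene_id`, `biotype`.
#' @return Tibble with columns `gene_id` (version-stripped) and `biotype`.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.g[tf]f[0-9]?(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GTF annotation requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    md <- as.data.frame(gr)
    bt <- if ("gene_biotype" %in% names(md)) md$gene_biotype
          else if ("gene_type" %in% names(md)) md$gene_type
          else abort("GTF has neither gene_biotype nor gene_type attribute")
    ann <- tibble(gene_id = strip_gene_version(md$gene_id),
                  biotype = normalize_biotype(bt))
  } else {
    ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (ncol(ann) < 2) abort("annotation TSV needs gene_id and biotype columns")
    names(ann)[1:2] <- c("gene_id", "biotype")
    ann <- tibble(gene_id = strip_gene_version(ann$gene_id),
                  biotype = normalize_biotype(ann$biotype))
  }
  distinct(ann, .data$gene_id, .keep_all = TRUE)
}

normalize_biotype <- function(x) {
  x <- tolower(x)
  dplyr::case_when(
    x %in% c("lncrna", "lincrna", "long_noncoding", "antisense") ~ "lncRNA",
    x %in% c("protein_coding", "mrna") ~ "protein_coding",
    TRUE ~ "other"
  )
}

#' Read a clinical follow-up table
#'
#' Requires columns `sample_id`, `time` (days) and `event` (0 censored /
#' 1 death); any further columns are kept as clinical covariates with
#' missing values recoded to `"unknown"`. Cases followed for less than
#' `min_followup_days` are excluded, duplicated sample ids keep the first
#' occurrence (with a warning), and records are returned sorted by
#' `sample_id`.
#'
#' @param path TSV file.
#' @param min_followup_days minimum follow-up in days (default 30).
#' @return Tibble with columns `sample_id`, `time`, `event`, covariates.
#' @export
read_clinical <- function(path, min_followup_days = 30) {
  cl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(cl))
  if (length(miss)) abort(paste0("clinical table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  cl$time <- as.numeric(cl$time)
  cl$event <- as.integer(cl$event)
  if (anyNA(cl$time) || any(cl$time <= 0)) {
    abort("clinical 'time' must be numeric and > 0")
  }
  if (!all(cl$event %in% c(0L, 1L))) abort("clinical 'event' must be 0 or 1")
  if (anyDuplicated(cl$sample_id)) {
    dup <- unique(cl$sample_id[duplicated(cl$sample_id)])
    warn(paste0("duplicate clinical records dropped (first kept): ",
                paste(dup, collapse = ", ")))
    cl <- cl[!duplicated(cl$sample_id), ]
  }
  n0 <- nrow(cl)
  cl <- cl[cl$time >= min_followup_days, ]
  if (nrow(cl) < n0) {
    inform(sprintf("excluded %d case(s) with follow-up < %g days",
                   n0 - nrow(cl), min_followup_days))
  }
  covars <- setdiff(names(cl), need)
  for (v in covars) cl[[v]][is.na(cl[[v]]) | cl[[v]] == ""] <- "unknown"
  as_tibble(cl[order(cl$sample_id), ])
}

#' Read a gene list (one identifier per line)
#'
#' @param path text file, one gene id or symbol per line; blank lines and
#'   `#` comments are skipped.
#' @return Character vector of unique, version-stripped identifiers.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) abort("gene list is empty")
  unique(strip_gene_version(x))
}

#' Align an expression matrix with a clinical table
#'
#' Restricts both objects to the tumor samples present in each, in a common
#' (sorted) order. Normal samples never carry survival records, so they are
#' dropped from the expression side here; run differential expression before
#' aligning.
#'
#' @param expr an [lnc_expression] object.
#' @param clinical tibble from [read_clinical()].
#' @return List with elements `expr` and `clinical`, sample-aligned.
#' @export
align_cohort <- function(expr, clinical) {
  stopifnot(inherits(expr, "lnc_expression"))
  tumor <- expr$samples$sample_id[expr$samples$group == "tumor"]
  common <- sort(intersect(tumor, clinical$sample_id))
  if (!length(common)) abort("no tumor samples shared between expression and clinical data")
  inform(sprintf("aligned %d tumor sample(s)", length(common)))
  list(
    expr = subset_expression(expr, samples = common),
    clinical = clinical[match(common, clinical$sample_id), ]
  )
}

#' Write an expression matrix (plus annotation and groups) to TSV
#'
#' Inverse of [read_expression()]: a value-identical round-trip.
#'
#' @param expr an [lnc_expression] object.
#' @param path output TSV for the values.
#' @param annotation_path,groups_path optional sidecar outputs.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, annotation_path = NULL,
                             groups_path = NULL) {
  stopifnot(inherits(expr, "lnc_expression"))
  df <- tibble(gene_id = rownames(expr$values))
  df <- dplyr::bind_cols(df, as_tibble(expr$values))
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(annotation_path)) {
    readr::write_tsv(expr$genes, annotation_path, progress = FALSE)
  }
  if (!is.null(groups_path)) {
    readr::write_tsv(expr$samples, groups_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a long-format immune infiltration table
#'
#' @param path TSV with columns `sample_id`, `method`, `cell_type`, `value`.
#' @return Tibble; `method` is checked against the supported deconvolution
#'   method names.
#' @export
read_infiltration <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", method = "c", cell_type = "c", value = "d"),
    progress = FALSE)
  bad <- setdiff(unique(x$method), infiltration_methods())
  if (length(bad)) abort(paste0("unknown infiltration method(s): ",
                                paste(bad, collapse = ", ")))
  if (any(!is.finite(x$value))) abort("infiltration values must be finite")
  x
}

#' Supported immune-deconvolution method labels
#' @return Character vector of method names.
#' @export
infiltration_methods <- function() {
  c("XCELL", "TIMER", "QUANTISEQ", "MCPCOUNTER", "EPIC",
    "CIBERSORT-ABS", "CIBERSORT")
}

#' Drugs with predicted IC50 tables supported by the drug-sensitivity test
#' @return Character vector of drug names.
#' @export
ic50_drugs <- function() {
  c("bleomycin", "doxorubicin", "erlotinib", "gemcitabine", "methotrexate",
    "mitomycin", "paclitaxel", "rapamycin", "cisplatin", "sorafenib")
}

#' Read a predicted drug-sensitivity (IC50) table
#'
#' @param path TSV with columns `sample_id`, `drug`, `ic50` (log-scale).
#' @return Tibble with drug names checked against [ic50_drugs()].
#' @export
read_ic50 <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", drug = "c", ic50 = "d"), progress = FALSE)
  bad <- setdiff(unique(x$drug), ic50_drugs())
  if (length(bad)) abort(paste0("unknown drug(s): ", paste(bad, collapse = ", ")))
  x
}
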