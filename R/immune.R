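#' Spearman correlation of risk score with immune-cell infiltration
#'
#' Per (cell type, deconvolution method), Spearman rho and p between the
#' continuous risk score and the abundance estimate, over their overlapping
#' samples. Constant abundance columns (rho undefined) are skipped with a
#' warning; pairs with fewer than `min_n` overlapping samples are skipped
#' likewise. Rows are ordered by rho (lollipop-plot order); BH-adjusted
#' p-values are reported next to the raw ones within this analysis family.
#'
#' @param cohort tibble from [stratify_cohort()] (needs `sample_id`,
#'   `risk_score`).
#' @param infiltration long tibble from [read_infiltration()] /
#'   [simulate_infiltration()].
#' @param min_n minimum overlapping samples (default 10).
#' @return Tibble `method`, `cell_type`, `rho`, `p`, `fdr`, `n`,
#'   `significant`, `stars`.
#' @export
risk_infiltration_correlation <- function(cohort, infiltration, min_n = 10) {
  need_cols(cohort, c("sample_id", "risk_score"))
  need_cols(infiltration, c("sample_id", "method", "cell_type", "value"))
  out <- infiltration %>%
    dplyr::inner_join(dplyr::select(cohort, "sample_id", "risk_score"),
                      by = "sample_id") %>%
    group_by(.data$method, .data$cell_type) %>%
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < min_n) {
        warn(sprintf("%s/%s: fewer than %d overlapping samples; skipped",
                     key$method, key$cell_type, min_n))
        return(tibble())
      }
      if (length(unique(d$value)) < 2) {
        warn(sprintf("%s/%s: constant abundance; rho undefined, skipped",
                     key$method, key$cell_type))
        return(tibble())
      }
      ct <- suppressWarnings(cor.test(d$risk_score, d$value,
                                      method = "spearman", exact = FALSE))
      tibble(rho = unname(ct$estimate), p = ct$p.value, n = nrow(d))
    }) %>%
    ungroup()
  out %>%
    mutate(fdr = p.adjust(.data$p, method = "BH"),
           significant = .data$p < 0.05,
           stars = p_stars(.data$p)) %>%
    arrange(.data$rho)
}

#' Checkpoint and immunosuppressive genes examined against the risk groups
#' @return Character vector of gene symbols.
#' @export
checkpoint_genes <- function() {
  c("CD276", "GSDME", "HAVCR2", "TNFRSF18", "CTLA4", "PDCD1", "LAG3")
}

#' Expression of selected genes between high- and low-risk groups
#'
#' Rank-sum (Mann-Whitney) test of log2(FPKM + 1) expression per gene
#' between the high- and low-risk groups; intended for checkpoint and
#' immunosuppressive molecules. Genes absent from the matrix are reported
#' and skipped.
#'
#' @param cohort tibble from [stratify_cohort()].
#' @param expr an [lnc_expression] containing the cohort samples.
#' @param genes gene symbols/ids to test (default [checkpoint_genes()]).
#' @return Tibble `gene_id`, `statistic`, `p`, `fdr`, `direction`
#'   (`up_in_high`/`down_in_high`), `n_high`, `n_low`, `stars`.
#' @export
group_expression_test <- function(cohort, expr, genes = checkpoint_genes()) {
  need_cols(cohort, c("sample_id", "group"))
  stopifnot(inherits(expr, "lnc_expression"))
  missing_genes <- setdiff(genes, rownames(expr$values))
  if (length(missing_genes)) {
    warn(paste0("gene(s) not in matrix, skipped: ",
                paste(missing_genes, collapse = ", ")))
  }
  genes <- setdiff(genes, missing_genes)
  samples <- intersect(cohort$sample_id, colnames(expr$values))
  if (length(samples) < 4) abort("too few overlapping samples")
  grp <- cohort$group[match(samples, cohort$sample_id)]
  lx <- log2p1(expr)[genes, samples, drop = FALSE]
  out <- purrr::map_dfr(genes, function(g) {
    hi <- lx[g, grp == "high"]; lo <- lx[g, grp == "low"]
    wt <- suppressWarnings(wilcox.test(hi, lo, exact = FALSE))
    tibble(gene_id = g, statistic = unname(wt$statistic), p = wt$p.value,
           direction = ifelse(median(hi) >= median(lo),
                              "up_in_high", "down_in_high"),
           n_high = length(hi), n_low = length(lo))
  })
  out %>% mutate(fdr = p.adjust(.data$p, method = "BH"),
                 stars = p_stars(.data$p))
}

#' Predicted drug sensitivity (IC50) between risk groups
#'
#' Per drug, rank-sum test of predicted log-IC50 between high- and
#' low-risk groups, with the direction of the median difference reported:
#' a higher IC50 in the high-risk group means that group is predicted
#' *less* sensitive to the drug.
#'
#' @param cohort tibble from [stratify_cohort()].
#' @param ic50 long tibble from [read_ic50()] / [simulate_ic50()].
#' @param min_n minimum samples per group per drug (default 2).
#' @return Tibble `drug`, `statistic`, `p`, `fdr`, `direction`
#'   (`less_sensitive`/`more_sensitive` for the high-risk group),
#'   `median_diff`, `n_high`, `n_low`, `stars`.
#' @export
drug_sensitivity_test <- function(cohort, ic50, min_n = 2) {
  need_cols(cohort, c("sample_id", "group"))
  need_cols(ic50, c("sample_id", "drug", "ic50"))
  dat <- ic50 %>%
    dplyr::inner_join(dplyr::select(cohort, "sample_id", "group"),
                      by = "sample_id") %>%
    filter(is.finite(.data$ic50))
  out <- purrr::map_dfr(unique(dat$drug), function(d) {
    dd <- dat[dat$drug == d, ]
    hi <- dd$ic50[dd$group == "high"]; lo <- dd$ic50[dd$group == "low"]
    if (length(hi) < min_n || length(lo) < min_n) {
      warn(paste0("drug '", d, "': too few samples per group; skipped"))
      return(tibble())
    }
    wt <- suppressWarnings(wilcox.test(hi, lo, exact = FALSE))
    md <- median(hi) - median(lo)
    tibble(drug = d, statistic = unname(wt$statistic), p = wt$p.value,
           direction = ifelse(md >= 0, "less_sensitive", "more_sensitive"),
           median_diff = md, n_high = length(hi), n_low = length(lo))
  })
  out %>% mutate(fdr = p.adjust(.data$p, method = "BH"),
                 stars = p_stars(.data$p))
}
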