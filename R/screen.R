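#' Screen lncRNAs by coexpression with immune genes
#'
#' A lncRNA is called immune-related when its log2(FPKM + 1) profile
#' correlates with at least one immune gene beyond `r_min` at a correlation
#' test p-value below `p_max`, across all samples (tumor and normal). The
#' returned witness is the immune gene with the largest absolute
#' correlation. By default the magnitude |r| is thresholded, keeping
#' negative regulators; `signed = TRUE` requires r > r_min.
#'
#' @param expr an [lnc_expression] with at least one lncRNA.
#' @param immune_genes character vector of immune gene identifiers.
#' @param r_min correlation threshold (default 0.4).
#' @param p_max correlation-test p-value threshold (default 0.001).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param signed if `TRUE`, threshold r rather than |r|.
#' @return Tibble with one row per retained lncRNA: `gene_id`,
#'   `witness_gene`, `r`, `p`.
#' @export
coexpression_screen <- function(expr, immune_genes, r_min = 0.4,
                                p_max = 0.001,
                                method = c("pearson", "spearman"),
                                signed = FALSE) {
  stopifnot(inherits(expr, "lnc_expression"))
  method <- match.arg(method)
  lnc <- genes_of_biotype(expr, "lncRNA")
  if (!length(lnc)) abort("expression matrix contains no lncRNA genes")
  imm <- intersect(strip_gene_version(immune_genes), rownames(expr$values))
  imm <- setdiff(imm, lnc)
  if (!length(imm)) abort("no immune genes found in the expression matrix")
  lx <- log2p1(expr)
  L <- t(lx[lnc, , drop = FALSE])
  I <- t(lx[imm, , drop = FALSE])
  if (method == "spearman") {
    L <- apply(L, 2, rank)
    I <- apply(I, 2, rank)
  }
  n <- nrow(L)
  if (n < 3) abort("need at least 3 samples for a correlation test")
  R <- suppressWarnings(cor(L, I))          # lnc x immune
  R[is.na(R)] <- 0                          # zero-variance genes never pass
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * pt(-abs(tstat), df = n - 2)
  score <- if (signed) R else abs(R)
  pass <- score > r_min & P < p_max
  keep <- which(rowSums(pass) > 0)
  out <- purrr::map_dfr(keep, function(i) {
    j <- which.max(ifelse(pass[i, ], abs(R[i, ]), -Inf))
    tibble(gene_id = lnc[i], witness_gene = imm[j],
           r = R[i, j], p = P[i, j])
  })
  if (!nrow(out)) {
    out <- tibble(gene_id = character(0), witness_gene = character(0),
                  r = numeric(0), p = numeric(0))
  }
  attr(out, "thresholds") <- list(r_min = r_min, p_max = p_max,
                                  method = method, signed = signed)
  out
}

#' Moderated-t differential expression between tumor and normal samples
#'
#' Per-gene two-group comparison on log2(FPKM + 1) with empirical-Bayes
#' variance moderation: the pooled sample variance s^2 (d residual df) is
#' shrunk toward a common prior s0^2 with prior df d0,
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`, and the t statistic uses
#' d + d0 degrees of freedom. `(d0, s0^2)` are estimated by moment matching
#' of the log sample variances against the scaled-F sampling theory; when
#' the observed variances are exactly exchangeable (no excess spread) the
#' prior df is infinite and the statistic reduces to a pooled-variance t
#' with a common variance. FDR is Benjamini-Hochberg across all tested
#' genes; a gene is flagged differentially expressed when |log2FC| >
#' `lfc_min` and FDR < `fdr_max`.
#'
#' @param expr an [lnc_expression] with both tumor and normal samples.
#' @param genes genes to test (default: all lncRNAs); typically the
#'   immune-related lncRNA set, in which case the FDR is taken within it.
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @param fdr_max FDR threshold (default 0.05).
#' @return Tibble: `gene_id`, `log2fc` (tumor minus normal), `stat`, `p`,
#'   `fdr`, `direction` (`up`/`down`), `de` (logical flag). Attributes
#'   `d0` and `s0_sq` carry the fitted prior.
#' @export
moderated_de_test <- function(expr, genes = NULL, lfc_min = 1,
                              fdr_max = 0.05) {
  stopifnot(inherits(expr, "lnc_expression"))
  if (is.null(genes)) genes <- genes_of_biotype(expr, "lncRNA")
  if (is.data.frame(genes)) genes <- genes$gene_id
  genes <- intersect(genes, rownames(expr$values))
  if (!length(genes)) abort("none of the requested genes are in the matrix")
  grp <- expr$samples$group
  n1 <- sum(grp == "tumor"); n2 <- sum(grp == "normal")
  if (n1 < 2 || n2 < 2) abort("need at least 2 samples per group")
  lx <- log2p1(expr)[genes, , drop = FALSE]
  xt <- lx[, grp == "tumor", drop = FALSE]
  xn <- lx[, grp == "normal", drop = FALSE]
  m1 <- rowMeans(xt); m2 <- rowMeans(xn)
  v1 <- apply(xt, 1, var); v2 <- apply(xn, 1, var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  sq <- squeeze_var(s2, d)
  lfc <- m1 - m2
  se <- sqrt(sq$var_post * (1 / n1 + 1 / n2))
  stat <- lfc / se
  df_total <- d + sq$d0
  p <- 2 * pt(-abs(stat), df = df_total)
  fdr <- p.adjust(p, method = "BH")
  out <- tibble(
    gene_id = genes, log2fc = unname(lfc), stat = unname(stat),
    p = unname(p), fdr = unname(fdr),
    direction = unname(ifelse(lfc >= 0, "up", "down")),
    de = unname(abs(lfc) > lfc_min & fdr < fdr_max)
  )
  attr(out, "d0") <- sq$d0
  attr(out, "s0_sq") <- sq$s0_sq
  out
}

# Empirical-Bayes variance shrinkage: moment matching of z = log(s^2)
# against the scaled-F theory (z | s0,d0 has mean log s0^2 + digamma(d/2)
# - log(d/2) + [digamma terms] and excess variance trigamma(d0/2)).
squeeze_var <- function(s2, d) {
  s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  n <- length(z)
  ev <- var(z) - trigamma(d / 2)
  if (!is.finite(ev) || ev <= 0) {
    # no excess spread over chi-squared sampling: infinite prior df; use the
    # geometric-mean variance so the equal-variance limit reduces exactly to
    # the pooled two-sample t
    d0 <- Inf
    s0_sq <- exp(mean(z))
    var_post <- rep(s0_sq, n)
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    var_post <- (d0 * s0_sq + d * s2) / (d0 + d)
  }
  list(d0 = d0, s0_sq = s0_sq, var_post = var_post)
}

# Newton inversion of the trigamma function (monotone decreasing on (0,Inf)).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}
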