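test_that("a lncRNA identical to an immune gene is retained with r = 1", {
  set.seed(1)
  imm <- rexp(40, 0.1)
  m <- rbind(IRG1 = imm, LNCA = imm, LNCB = rexp(40, 0.1))
  colnames(m) <- sprintf("s%02d", 1:40)
  ex <- lnc_expression(m, biotype = c("protein_coding", "lncRNA", "lncRNA"),
                       group = "tumor")
  out <- coexpression_screen(ex, "IRG1")
  expect_true("LNCA" %in% out$gene_id)
  expect_equal(out$r[out$gene_id == "LNCA"], 1, tolerance = 1e-12)
  expect_equal(out$witness_gene[out$gene_id == "LNCA"], "IRG1")
})

test_that("independent-noise lncRNAs are excluded at the default thresholds", {
  set.seed(2)
  n <- 424
  m <- rbind(IRG1 = rexp(n), matrix(rexp(50 * n), 50, n))
  rownames(m)[-1] <- sprintf("LNC%02d", 1:50)
  colnames(m) <- sprintf("s%03d", seq_len(n))
  ex <- lnc_expression(m, biotype = c("protein_coding", rep("lncRNA", 50)),
                       group = "tumor")
  out <- coexpression_screen(ex, "IRG1")
  expect_equal(nrow(out), 0)
})

test_that("retained set is invariant to positive rescaling of one gene", {
  co <- simulate_cohort(sim_config(n_tumor = 80, n_normal = 20,
                                   n_immune_genes = 10, n_lncrna = 20,
                                   n_other = 2, n_immune_correlated_lnc = 8,
                                   n_de_lnc = 6, n_prognostic_pairs = 2),
                        seed = 6)
  out1 <- coexpression_screen(co$expr, co$truth$immune_genes)
  ex2 <- co$expr
  # positive scaling on the raw scale is monotone; Pearson on log2(x+1)
  # changes only negligibly for large scale factors, the retained set not
  # at all for a pure power transform of (x+1)
  ex2$values["LNC0001", ] <- (ex2$values["LNC0001", ] + 1)^2 - 1
  out2 <- coexpression_screen(ex2, co$truth$immune_genes)
  expect_setequal(out1$gene_id, out2$gene_id)
})

test_that("spearman option is invariant to any monotone transform", {
  co <- simulate_cohort(sim_config(n_tumor = 60, n_normal = 20,
                                   n_immune_genes = 8, n_lncrna = 12,
                                   n_other = 2, n_immune_correlated_lnc = 6,
                                   n_de_lnc = 4, n_prognostic_pairs = 1),
                        seed = 8)
  out1 <- coexpression_screen(co$expr, co$truth$immune_genes,
                              method = "spearman")
  ex2 <- co$expr
  ex2$values["LNC0002", ] <- exp(ex2$values["LNC0002", ] / 10)
  out2 <- coexpression_screen(ex2, co$truth$immune_genes,
                              method = "spearman")
  expect_setequal(out1$gene_id, out2$gene_id)
})

test_that("moderated t reduces to the pooled t when variances are equal", {
  set.seed(3)
  n1 <- 8; n2 <- 6; g <- 25
  base <- matrix(rnorm(g * (n1 + n2)), g)
  # force every gene's pooled variance to the same value by scaling
  # residuals within groups
  x <- base
  for (i in seq_len(g)) {
    xt <- x[i, 1:n1]; xn <- x[i, (n1 + 1):(n1 + n2)]
    s2 <- (sum((xt - mean(xt))^2) + sum((xn - mean(xn))^2)) / (n1 + n2 - 2)
    x[i, 1:n1] <- mean(xt) + (xt - mean(xt)) / sqrt(s2)
    x[i, (n1 + 1):(n1 + n2)] <- mean(xn) + (xn - mean(xn)) / sqrt(s2)
  }
  # shift on the log scale (variance-preserving), then invert log2(m+1)
  m <- 2^(x - min(x)) - 1
  dimnames(m) <- list(sprintf("L%02d", seq_len(g)),
                      sprintf("s%02d", seq_len(n1 + n2)))
  ex <- lnc_expression(m, biotype = "lncRNA",
                       group = rep(c("tumor", "normal"), c(n1, n2)))
  res <- moderated_de_test(ex, lfc_min = 0.1)
  expect_identical(attr(res, "d0"), Inf)
  lx <- log2p1(ex)
  pooled_t <- vapply(seq_len(g), function(i) {
    xt <- lx[i, 1:n1]; xn <- lx[i, (n1 + 1):(n1 + n2)]
    s2 <- (sum((xt - mean(xt))^2) + sum((xn - mean(xn))^2)) / (n1 + n2 - 2)
    (mean(xt) - mean(xn)) / sqrt(s2 * (1 / n1 + 1 / n2))
  }, numeric(1))
  expect_equal(res$stat, pooled_t, tolerance = 1e-8)
})

test_that("moderated t agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(4)
  n1 <- 30; n2 <- 10; g <- 200
  lx <- matrix(rnorm(g * (n1 + n2), mean = 5,
                     sd = rep(sqrt(exp(rnorm(g, 0, 0.7))), n1 + n2)),
               g, n1 + n2)
  lx[1:20, 1:n1] <- lx[1:20, 1:n1] + 2
  lx <- lx - min(lx) + 0.1
  m <- 2^lx - 1
  dimnames(m) <- list(sprintf("L%03d", seq_len(g)),
                      sprintf("s%02d", seq_len(n1 + n2)))
  ex <- lnc_expression(m, biotype = "lncRNA",
                       group = rep(c("tumor", "normal"), c(n1, n2)))
  res <- moderated_de_test(ex)
  design <- cbind(1, rep(c(1, 0), c(n1, n2)))
  fit <- limma::eBayes(limma::lmFit(log2p1(ex), design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(res$stat, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment equals the brute-force step-up exactly", {
  set.seed(5)
  for (len in c(1, 2, 7, 20)) {
    p <- runif(len)
    expect_identical(p.adjust(p, "BH"), brute_bh(p))
  }
})

test_that("DE flags respect both thresholds and direction matches sign", {
  co <- simulate_cohort(sim_config(n_tumor = 100, n_normal = 30,
                                   n_immune_genes = 10, n_lncrna = 40,
                                   n_other = 2, n_immune_correlated_lnc = 20,
                                   n_de_lnc = 10, prop_up = 0.7,
                                   n_prognostic_pairs = 2), seed = 10)
  res <- moderated_de_test(co$expr)
  expect_true(all(res$fdr >= res$p))
  expect_identical(res$direction, ifelse(res$log2fc >= 0, "up", "down"))
  expect_identical(res$de, abs(res$log2fc) > 1 & res$fdr < 0.05)
  truth <- co$truth$de_lnc
  hit <- res[match(truth$gene_id, res$gene_id), ]
  expect_equal(sign(hit$log2fc), sign(truth$log2fc))
})
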