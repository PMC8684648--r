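#' Configuration for the synthetic-cohort generator
#'
#' Defines a tumor/normal cohort whose expression has (i) latent-factor
#' blocks shared between immune genes and a subset of lncRNAs, so that
#' immune-correlated lncRNAs exist with a known population correlation,
#' (ii) lncRNAs with a planted tumor-vs-normal log2 fold change
#' (predominantly upregulated, as is typical for tumor cohorts), and
#' (iii) gene pairs whose within-sample 0/1 indicators drive an exponential
#' proportional-hazards survival model with right censoring. Defaults mirror
#' a TCGA-style liver cohort (374 tumor / 50 normal samples) at a gene count
#' small enough for routine simulation.
#'
#' @param n_tumor,n_normal sample counts.
#' @param n_immune_genes immune (protein-coding) genes.
#' @param n_lncrna lncRNA genes.
#' @param n_other unrelated protein-coding genes.
#' @param n_immune_correlated_lnc lncRNAs loading on the immune latent
#'   factors.
#' @param n_de_lnc lncRNAs with a planted tumor/normal log2 fold change;
#'   drawn from the immune-correlated set so that DEirlncRNAs exist.
#' @param prop_up fraction of DE lncRNAs that are upregulated.
#' @param log2fc absolute planted log2 fold change.
#' @param target_r population correlation between an immune-correlated
#'   lncRNA and the immune genes of its factor (on the latent log scale).
#' @param n_prognostic_pairs planted prognostic pairs (gene-disjoint, both
#'   members DE with identical mean/shift so the indicator is balanced).
#' @param beta Cox log-hazard coefficient per planted pair indicator.
#' @param baseline_hazard exponential event rate per day at the centered
#'   linear predictor.
#' @param censor_max upper bound (days) of the uniform censoring time.
#' @param covariate_tilt log-odds slope tying clinical covariates (stage,
#'   ECOG, vascular invasion) to the standardized linear predictor.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tumor = 374, n_normal = 50,
                       n_immune_genes = 60, n_lncrna = 300, n_other = 140,
                       n_immune_correlated_lnc = 60, n_de_lnc = 40,
                       prop_up = 0.9, log2fc = 2, target_r = 0.6,
                       n_prognostic_pairs = 10, beta = 1,
                       baseline_hazard = 5e-4, censor_max = 3650,
                       covariate_tilt = 0.8) {
  cfg <- as.list(environment())
  counts <- unlist(cfg[c("n_tumor", "n_normal", "n_immune_genes", "n_lncrna",
                         "n_other", "n_immune_correlated_lnc", "n_de_lnc",
                         "n_prognostic_pairs")])
  if (any(counts < 0)) abort("all counts must be nonnegative")
  if (n_immune_correlated_lnc > n_lncrna) {
    abort("more immune-correlated lncRNAs requested than lncRNAs")
  }
  if (n_de_lnc > n_immune_correlated_lnc) {
    abort("n_de_lnc must not exceed n_immune_correlated_lnc")
  }
  if (2 * n_prognostic_pairs > n_de_lnc) {
    abort("not enough DE lncRNAs to host the planted pairs")
  }
  if (target_r <= 0 || target_r >= 1) abort("target_r must be in (0, 1)")
  structure(cfg, class = "sim_config")
}

#' Simulate a tumor/normal cohort with planted prognostic pair structure
#'
#' Expression is log-normal: log2 abundances are Gaussian with gene-specific
#' baselines, shared latent factors inducing immune-gene/lncRNA correlation
#' blocks, planted tumor-vs-normal shifts for DE lncRNAs, and unit noise;
#' FPKM-scale values are `2^latent`. Survival times for tumor samples are
#' exponential with hazard `baseline_hazard * exp(lp)`, where `lp` is the
#' centered sum of `beta` times the planted pair indicators; censoring is
#' `Uniform(0, censor_max)` and times are rounded to whole days (ties are
#' therefore expected, as in day-resolution registries).
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; the output is fully determined by
#'   `(config, seed)`.
#' @return A list of class `lnc_cohort`:
#' \describe{
#'   \item{expr}{[lnc_expression] of all genes x (tumor + normal) samples.}
#'   \item{clinical}{tibble of tumor samples: `sample_id`, `time`, `event`,
#'     covariates `t_stage`, `stage`, `grade`, `child_pugh`, `ecog`,
#'     `vascular_invasion`.}
#'   \item{truth}{ground truth: `immune_genes`, `immune_correlated_lnc`,
#'     `de_lnc` (tibble with signed `log2fc`), `planted_pairs` (tibble
#'     `gene_a`, `gene_b`, `beta`), `lp` (tibble per tumor sample).}
#' }
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cf <- config
  n_s <- cf$n_tumor + cf$n_normal
  samples <- c(sprintf("TUMOR-%04d", seq_len(cf$n_tumor)),
               sprintf("NORMAL-%03d", seq_len(cf$n_normal)))
  group <- rep(c("tumor", "normal"), c(cf$n_tumor, cf$n_normal))

  imm_ids <- sprintf("IRG%04d", seq_len(cf$n_immune_genes))
  lnc_ids <- sprintf("LNC%04d", seq_len(cf$n_lncrna))
  oth_ids <- sprintf("PCG%04d", seq_len(cf$n_other))
  gene_ids <- c(imm_ids, lnc_ids, oth_ids)
  biotype <- rep(c("protein_coding", "lncRNA", "protein_coding"),
                 c(cf$n_immune_genes, cf$n_lncrna, cf$n_other))

  # latent factors: ~10 immune genes per factor, correlated lncRNAs assigned
  # round-robin; equal loadings a give corr a^2/(a^2+1) = target_r
  n_fac <- max(1L, ceiling(cf$n_immune_genes / 10))
  fac_imm <- rep_len(seq_len(n_fac), cf$n_immune_genes)
  corr_lnc <- lnc_ids[seq_len(cf$n_immune_correlated_lnc)]
  fac_lnc <- rep_len(seq_len(n_fac), cf$n_immune_correlated_lnc)
  loading <- sqrt(cf$target_r / (1 - cf$target_r))
  Z <- matrix(rnorm(n_fac * n_s), n_fac, n_s)

  mu <- runif(length(gene_ids), 2, 7)
  latent <- matrix(rnorm(length(gene_ids) * n_s), length(gene_ids), n_s,
                   dimnames = list(gene_ids, samples))
  latent <- latent + mu
  latent[seq_len(cf$n_immune_genes), ] <-
    latent[seq_len(cf$n_immune_genes), ] + loading * Z[fac_imm, , drop = FALSE]
  ci <- match(corr_lnc, gene_ids)
  latent[ci, ] <- latent[ci, ] + loading * Z[fac_lnc, , drop = FALSE]

  # planted DE among the immune-correlated lncRNAs; pair members share a
  # baseline and shift so the pair indicator stays balanced
  de_ids <- corr_lnc[seq_len(cf$n_de_lnc)]
  n_up <- round(cf$prop_up * cf$n_de_lnc)
  lfc <- rep(c(cf$log2fc, -cf$log2fc),
             c(n_up, cf$n_de_lnc - n_up))
  pair_genes <- de_ids[seq_len(2 * cf$n_prognostic_pairs)]
  if (cf$n_prognostic_pairs > 0) {
    idx <- matrix(seq_len(2 * cf$n_prognostic_pairs), ncol = 2, byrow = TRUE)
    for (r in seq_len(nrow(idx))) {
      g <- match(pair_genes[idx[r, ]], gene_ids)
      common_mu <- mean(mu[g])
      latent[g, ] <- latent[g, ] - mu[g] + common_mu
      lfc[idx[r, 2]] <- lfc[idx[r, 1]]
    }
  }
  di <- match(de_ids, gene_ids)
  latent[di, group == "tumor"] <- latent[di, group == "tumor"] + lfc

  expr <- lnc_expression(2 ^ latent, biotype = biotype, group = group)

  # planted pairs and survival for tumor samples
  tum <- samples[group == "tumor"]
  planted <- tibble(gene_a = character(0), gene_b = character(0),
                    beta = numeric(0))
  lp <- setNames(rep(0, cf$n_tumor), tum)
  if (cf$n_prognostic_pairs > 0) {
    ab <- matrix(pair_genes, ncol = 2, byrow = TRUE)
    swap <- ab[, 1] > ab[, 2]
    ab[swap, ] <- ab[swap, 2:1]
    planted <- tibble(gene_a = ab[, 1], gene_b = ab[, 2],
                      beta = rep(cf$beta, cf$n_prognostic_pairs))
    for (r in seq_len(nrow(ab))) {
      s <- as.numeric(expr$values[ab[r, 1], tum] > expr$values[ab[r, 2], tum])
      lp <- lp + cf$beta * (s - 0.5)
    }
  }
  t_event <- rexp(cf$n_tumor, rate = cf$baseline_hazard * exp(lp))
  t_cens <- runif(cf$n_tumor, 0, cf$censor_max)
  time <- pmax(1, round(pmin(t_event, t_cens)))
  event <- as.integer(t_event <= t_cens)

  z <- if (sd(lp) > 0) (lp - mean(lp)) / sd(lp) else lp * 0
  tilt <- cf$covariate_tilt
  adv_stage <- rbinom(cf$n_tumor, 1, stats::plogis(-0.8 + tilt * z))
  stage <- ifelse(adv_stage == 1,
                  sample(c("III", "IV"), cf$n_tumor, TRUE, c(0.95, 0.05)),
                  sample(c("I", "II"), cf$n_tumor, TRUE, c(0.68, 0.32)))
  t_adv <- ifelse(runif(cf$n_tumor) < 0.9, adv_stage,
                  rbinom(cf$n_tumor, 1, 0.3))
  t_stage <- ifelse(t_adv == 1,
                    sample(c("T3", "T4"), cf$n_tumor, TRUE, c(0.8, 0.2)),
                    sample(c("T1", "T2"), cf$n_tumor, TRUE, c(0.65, 0.35)))
  grade <- ifelse(rbinom(cf$n_tumor, 1, stats::plogis(-0.4 + 0.3 * z)) == 1,
                  sample(c("G3", "G4"), cf$n_tumor, TRUE, c(0.85, 0.15)),
                  sample(c("G1", "G2"), cf$n_tumor, TRUE, c(0.3, 0.7)))
  child_pugh <- ifelse(runif(cf$n_tumor) < 0.02, "unknown",
                       ifelse(rbinom(cf$n_tumor, 1,
                                     stats::plogis(-2 + 0.3 * z)) == 1,
                              sample(c("B", "C"), cf$n_tumor, TRUE,
                                     c(0.9, 0.1)), "A"))
  ecog <- ifelse(rbinom(cf$n_tumor, 1, stats::plogis(-0.5 + tilt * z)) == 1,
                 sample(c("1", "2"), cf$n_tumor, TRUE, c(0.8, 0.2)), "0")
  vascular_invasion <- ifelse(
    rbinom(cf$n_tumor, 1, stats::plogis(-0.7 + tilt * z)) == 1, "yes", "no")

  clinical <- tibble(
    sample_id = tum, time = as.numeric(time), event = event,
    t_stage = t_stage, stage = stage, grade = grade,
    child_pugh = child_pugh, ecog = ecog,
    vascular_invasion = vascular_invasion
  )

  structure(list(
    expr = expr,
    clinical = clinical,
    truth = list(
      immune_genes = imm_ids,
      immune_correlated_lnc = corr_lnc,
      de_lnc = tibble(gene_id = de_ids, log2fc = lfc),
      planted_pairs = planted,
      lp = tibble(sample_id = tum, lp = unname(lp)),
      config = unclass(cf), seed = as.integer(seed)
    )
  ), class = "lnc_cohort")
}

#' @export
print.lnc_cohort <- function(x, ...) {
  cat(sprintf("<lnc_cohort> %d genes x %d samples; %d tumor survival records\n",
              nrow(x$expr$values), ncol(x$expr$values), nrow(x$clinical)))
  cat(sprintf("  planted: %d DE lncRNA, %d prognostic pair(s)\n",
              nrow(x$truth$de_lnc), nrow(x$truth$planted_pairs)))
  invisible(x)
}

#' Simulate a pair-indicator cohort directly (selection-stage benchmark)
#'
#' Bypasses expression simulation: draws independent Bernoulli(0.5) pair
#' indicators and exponential survival driven by the first `n_planted`
#' pairs. Used to study the stability-selection stage in isolation.
#'
#' @param n_samples,n_pairs cohort and feature dimensions.
#' @param n_planted number of prognostic pairs (the first rows).
#' @param beta log-hazard coefficient per planted indicator.
#' @param baseline_hazard,censor_max survival-model parameters (days).
#' @param seed integer seed.
#' @return List: `pm` (a [pair_matrix]), `clinical` (tibble), `planted`
#'   (character vector of planted pair ids).
#' @export
simulate_pair_cohort <- function(n_samples = 300, n_pairs = 205,
                                 n_planted = 5, beta = 1,
                                 baseline_hazard = 2e-3, censor_max = 1500,
                                 seed = 1) {
  set.seed(as.integer(seed))
  stopifnot(n_planted <= n_pairs)
  samples <- sprintf("S%04d", seq_len(n_samples))
  ids <- sprintf("LNCA%04d|LNCB%04d", seq_len(n_pairs), seq_len(n_pairs))
  v <- matrix(rbinom(n_pairs * n_samples, 1, 0.5), n_pairs, n_samples,
              dimnames = list(ids, samples))
  lp <- beta * colSums(v[seq_len(n_planted), , drop = FALSE] - 0.5)
  t_event <- rexp(n_samples, baseline_hazard * exp(lp))
  t_cens <- runif(n_samples, 0, censor_max)
  clinical <- tibble(
    sample_id = samples,
    time = pmax(1, round(pmin(t_event, t_cens))),
    event = as.integer(t_event <= t_cens)
  )
  list(pm = new_pair_matrix(v), clinical = clinical,
       planted = ids[seq_len(n_planted)])
}

#' Simulate a long-format immune infiltration table tied to a risk driver
#'
#' Cell-type abundances are monotone transforms of a latent Gaussian that
#' shares a planted correlation with the supplied driver (for example the
#' true linear predictor or a fitted risk score); B cells, neutrophils and
#' macrophages load positively, CD8+/CD4+ T cells and monocytes negatively,
#' NK cells and Tregs not at all.
#'
#' @param driver tibble with columns `sample_id` and a numeric second column.
#' @param methods deconvolution method labels to emit.
#' @param seed integer seed.
#' @return Long tibble `sample_id`, `method`, `cell_type`, `value`.
#' @export
simulate_infiltration <- function(driver,
                                  methods = infiltration_methods(),
                                  seed = 1) {
  set.seed(as.integer(seed))
  z <- as.numeric(scale(driver[[2]]))
  rho <- c(B_cells = 0.4, neutrophils = 0.4, macrophages = 0.35,
           CD8_T_cells = -0.4, CD4_T_cells = -0.35, monocytes = -0.4,
           NK_cells = 0, Tregs = 0)
  purrr::map_dfr(methods, function(m) {
    purrr::map_dfr(names(rho), function(ct) {
      r <- rho[[ct]]
      lat <- r * z + sqrt(1 - r^2) * rnorm(length(z))
      tibble(sample_id = driver$sample_id, method = m, cell_type = ct,
             value = exp(0.5 * lat))   # positive, method-agnostic scale
    })
  })
}

#' Simulate a predicted-IC50 table with planted risk associations
#'
#' Planted log-IC50 shifts along the driver reproduce the qualitative
#' chemosensitivity pattern studied for liver cancer: higher IC50 (less
#' sensitive) with risk for erlotinib, methotrexate and rapamycin; lower
#' for bleomycin, doxorubicin, gemcitabine, mitomycin and paclitaxel;
#' no association for cisplatin and sorafenib.
#'
#' @param driver tibble with columns `sample_id` and a numeric second column.
#' @param seed integer seed.
#' @return Long tibble `sample_id`, `drug`, `ic50`.
#' @export
simulate_ic50 <- function(driver, seed = 1) {
  set.seed(as.integer(seed))
  z <- as.numeric(scale(driver[[2]]))
  shift <- c(erlotinib = 0.8, methotrexate = 0.5, rapamycin = 0.5,
             bleomycin = -0.8, doxorubicin = -0.5, gemcitabine = -0.8,
             mitomycin = -0.8, paclitaxel = -0.4,
             cisplatin = 0, sorafenib = 0)
  purrr::map_dfr(names(shift), function(d) {
    tibble(sample_id = driver$sample_id, drug = d,
           ic50 = 2 + shift[[d]] * z + rnorm(length(z)))
  })
}

#' Serialize a simulated cohort in the pipeline's input formats
#'
#' Writes `expression.tsv`, `annotation.tsv`, `groups.tsv`, `clinical.tsv`,
#' `immune_genes.txt` and `truth.json` so that a cohort round-trips through
#' [read_expression()] / [read_clinical()] / [read_gene_list()].
#'
#' @param cohort an `lnc_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "lnc_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_expression(cohort$expr, p("expression.tsv"),
                   annotation_path = p("annotation.tsv"),
                   groups_path = p("groups.tsv"))
  readr::write_tsv(cohort$clinical, p("clinical.tsv"), progress = FALSE)
  readr::write_lines(cohort$truth$immune_genes, p("immune_genes.txt"))
  truth <- cohort$truth
  truth$de_lnc <- as.list(truth$de_lnc)
  truth$planted_pairs <- as.list(truth$planted_pairs)
  truth$lp <- as.list(truth$lp)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(expression = p("expression.tsv"),
              annotation = p("annotation.tsv"),
              groups = p("groups.tsv"),
              clinical = p("clinical.tsv"),
              immune_genes = p("immune_genes.txt"),
              truth = p("truth.json")))
}
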