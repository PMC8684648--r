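#' Run the full pair-signature pipeline on a synthetic cohort
#'
#' End-to-end driver used for validation and as the reference for the
#' command-line interface: simulate a cohort, serialize it, read it back
#' through the package's own readers, screen immune-related lncRNAs, test
#' differential expression, build and filter the 0/1 pair matrix, fit the
#' signature on a training split, dichotomize at the AIC cutpoint, and run
#' every downstream association analysis. All stage outputs are written as
#' TSV/JSON under `out_dir`; given the same `(config, seed)` two runs
#' produce byte-identical files.
#'
#' @param out_dir output directory.
#' @param config a [sim_config()].
#' @param seed master seed; every stage derives its own substream.
#' @param n_reps LASSO repetitions for the selection stage.
#' @param freq_frac selection-frequency threshold as a fraction of
#'   `n_reps` (default 0.1, the 100-of-1000 rule).
#' @param holdout_frac fraction of tumor samples held out from fitting for
#'   the out-of-sample concordance estimate.
#' @param horizon AUC horizon in years.
#' @param min_followup_days clinical exclusion threshold in days.
#' @return Invisibly, a list: `signature`, `metrics` (named list of the
#'   headline numbers), `paths`.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), seed = 1,
                         n_reps = 50, freq_frac = 0.1, holdout_frac = 0.3,
                         horizon = 5, min_followup_days = 30) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  set.seed(as.integer(seed))
  sub_seed <- sample.int(.Machine$integer.max - 1L, 4)

  cohort <- simulate_cohort(config, seed = sub_seed[1])
  fx <- write_fixture(cohort, file.path(out_dir, "fixtures"))
  expr <- read_expression(fx["expression"], fx["annotation"], fx["groups"])
  clinical <- suppressMessages(
    read_clinical(fx["clinical"], min_followup_days = min_followup_days))
  immune <- read_gene_list(fx["immune_genes"])

  ir <- coexpression_screen(expr, immune)
  de <- moderated_de_test(expr, ir)
  readr::write_tsv(ir, p("irlncrna.tsv"), progress = FALSE)
  readr::write_tsv(de, p("de_results.tsv"), progress = FALSE)
  de_genes <- de$gene_id[de$de]
  if (length(de_genes) < 2) abort("fewer than 2 DEirlncRNAs; nothing to pair")

  tumor <- expr$samples$sample_id[expr$samples$group == "tumor"]
  pm_all <- build_pair_matrix(subset_expression(expr, samples = tumor),
                              de_genes)
  pm <- validity_filter(pm_all)
  readr::write_tsv(
    tidy(pm_all) %>%
      mutate(kept = .data$pair_id %in% rownames(pm$values)),
    p("pairs.tsv"), progress = FALSE)

  al <- align_pm_clinical(pm, clinical)
  n <- length(al$pm$sample_ids)
  set.seed(sub_seed[2])
  test_idx <- sort(sample.int(n, round(holdout_frac * n)))
  train_ids <- al$pm$sample_ids[setdiff(seq_len(n), test_idx)]
  test_ids <- al$pm$sample_ids[test_idx]
  pm_train <- subset_pairs(al$pm, samples = train_ids)
  cl_train <- al$clinical[match(train_ids, al$clinical$sample_id), ]

  sig <- suppressWarnings(fit_pair_signature(
    pm_train, cl_train, n_reps = n_reps,
    freq_threshold = round(freq_frac * n_reps),
    seed = sub_seed[3], horizon = horizon))
  write_signature(sig, p("signature.json"))
  readr::write_tsv(sig$selection_freq, p("selection_freq.tsv"),
                   progress = FALSE)
  readr::write_tsv(sig$sweep, p("auc_sweep.tsv"), progress = FALSE)

  scores <- risk_score(sig, al$pm)
  readr::write_tsv(scores, p("risk_scores.tsv"), progress = FALSE)
  sc_train <- scores[scores$sample_id %in% train_ids, ]
  for (h in c(1, 3, 5)) {
    roc <- tryCatch(td_roc(sc_train, cl_train, h), error = function(e) NULL)
    if (!is.null(roc)) {
      readr::write_tsv(tidy(roc), p(sprintf("roc_%dyr.tsv", h)),
                       progress = FALSE)
    }
  }

  strat <- stratify_cohort(scores, al$clinical, sig$cutpoint)
  km <- km_logrank(strat)
  assoc <- suppressMessages(suppressWarnings(clinical_association(strat)))
  coxrep <- suppressWarnings(independence_cox(strat))
  readr::write_tsv(km$curves, p("km_curves.tsv"), progress = FALSE)
  readr::write_tsv(assoc, p("associations.tsv"), progress = FALSE)
  readr::write_tsv(coxrep, p("cox_forest.tsv"), progress = FALSE)

  sc_test <- scores[scores$sample_id %in% test_ids, ]
  cl_test <- al$clinical[match(test_ids, al$clinical$sample_id), ]
  cindex_test <- if (length(test_ids) >= 10) {
    score_cindex(sc_test, cl_test)
  } else NA_real_

  infil <- simulate_infiltration(scores, seed = sub_seed[4])
  ic50 <- simulate_ic50(scores, seed = sub_seed[4] %% 100000L + 1L)
  readr::write_tsv(infil, p("infiltration.tsv"), progress = FALSE)
  readr::write_tsv(ic50, p("ic50.tsv"), progress = FALSE)
  immune_rep <- suppressWarnings(risk_infiltration_correlation(strat, infil))
  drug_rep <- suppressWarnings(drug_sensitivity_test(strat, ic50))
  readr::write_tsv(immune_rep, p("immune_report.tsv"), progress = FALSE)
  readr::write_tsv(drug_rep, p("drug_report.tsv"), progress = FALSE)

  planted <- with(cohort$truth$planted_pairs, paste(gene_a, gene_b, sep = "|"))
  metrics <- list(
    n_irlncrna = nrow(ir),
    n_de_lncrna = length(de_genes),
    n_pairs_total = nrow(pm_all$values),
    n_pairs_valid = nrow(pm$values),
    n_pairs_univariate = sig$provenance$n_pairs_univariate,
    n_candidates = sig$provenance$n_candidates,
    n_signature_pairs = length(sig$pairs),
    auc_5yr = sig$auc,
    cutpoint = sig$cutpoint,
    n_high = sum(strat$group == "high"),
    n_low = sum(strat$group == "low"),
    logrank_p = km$p,
    holdout_cindex = cindex_test,
    planted_recovery = if (length(planted)) {
      mean(planted %in% sig$pairs)
    } else NA_real_
  )
  jsonlite::write_json(metrics, p("metrics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(signature = sig, metrics = metrics,
                 cohort = cohort, scores = scores, stratified = strat,
                 paths = out_dir))
}
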