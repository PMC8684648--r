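toy_surv <- function(n = 120, seed = 1, beta = 0, x = NULL) {
  set.seed(seed)
  if (is.null(x)) x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.01 * exp(beta * x))
  cc <- runif(n, 0, 250)
  tibble::tibble(sample_id = sprintf("s%04d", seq_len(n)),
                 time = pmax(1, round(pmin(tt, cc))),
                 event = as.integer(tt <= cc), x = x)
}

test_that("risk_score is the exact dot product of betas and indicators", {
  v <- rbind(`A|B` = c(1L, 1L, 0L), `A|C` = c(1L, 0L, 1L))
  colnames(v) <- c("s1", "s2", "s3")
  pm <- new_pair_matrix(v)
  expect_equal(risk_score(c(`A|B` = 1, `A|C` = -1), pm)$risk_score,
               c(0, 1, -1))
  expect_equal(risk_score(c(`A|B` = 0.5), pm)$risk_score, c(0.5, 0.5, 0))
  set.seed(2)
  b <- rnorm(2); names(b) <- rownames(v)
  expect_equal(risk_score(b, pm)$risk_score,
               as.numeric(t(v) %*% b))
  expect_error(risk_score(c(`Z|Q` = 1), pm), "missing")
})

test_that("coxph coefficient maximizes the Efron partial likelihood", {
  # 5-sample toy with a tie, checked against a grid search of the
  # hand-written Efron partial likelihood
  time <- c(5, 5, 8, 12, 20)
  event <- c(1, 1, 1, 0, 1)
  x <- c(1, 0, 1, 0, 0)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, efron_loglik, numeric(1), time = time, event = event,
               x = x)
  expect_lt(abs(unname(coef(fit)) - grid[which.max(ll)]), 1e-3)
  # and the partial likelihood at the fitted coefficient matches coxph's
  expect_equal(efron_loglik(unname(coef(fit)), time, event, x),
               unname(fit$loglik[2]), tolerance = 1e-8)
})

test_that("univariate screen drops degenerate pairs and keeps signal", {
  cl <- toy_surv(n = 200, seed = 3, beta = 1.2)
  v <- rbind(`A|B` = cl$x, `A|C` = rbinom(200, 1, 0.5),
             `A|D` = rep(0L, 200))
  colnames(v) <- cl$sample_id
  pm <- new_pair_matrix(v)
  expect_warning(out <- univariate_cox_screen(pm, cl), "constant")
  tab <- attr(out, "univariate")
  expect_equal(tab$status[tab$pair_id == "A|D"], "constant")
  expect_true("A|B" %in% rownames(out$values))
})

test_that("univariate screen has nominal type-I error on null pairs", {
  cl <- toy_surv(n = 200, seed = 4)
  set.seed(5)
  v <- matrix(rbinom(500 * 200, 1, 0.5), 500, 200,
              dimnames = list(sprintf("N%03d|M%03d", 1:500, 1:500),
                              cl$sample_id))
  pm <- new_pair_matrix(v)
  out <- suppressWarnings(univariate_cox_screen(pm, cl, p_max = 0.05))
  rate <- nrow(out$values) / 500
  expect_gt(rate, 0.03)   # binomial band around 0.05 at 500 trials
  expect_lt(rate, 0.075)
})

test_that("selection frequencies are reproducible under a fixed seed", {
  pc <- simulate_pair_cohort(n_samples = 120, n_pairs = 15, n_planted = 2,
                             beta = 1, seed = 6)
  a <- repeated_lasso_selection(pc$pm, pc$clinical, n_reps = 8,
                                n_folds = 5, freq_threshold = 2, seed = 99)
  b <- repeated_lasso_selection(pc$pm, pc$clinical, n_reps = 8,
                                n_folds = 5, freq_threshold = 2, seed = 99)
  expect_identical(a, b)
})

test_that("under the conservative lambda rule null pairs are rarely selected", {
  pc <- simulate_pair_cohort(n_samples = 200, n_pairs = 100, n_planted = 0,
                             beta = 0, seed = 7)
  freq <- repeated_lasso_selection(pc$pm, pc$clinical, n_reps = 100,
                                   n_folds = 10, freq_threshold = 10,
                                   seed = 8, lambda_rule = "1se")
  # most null pairs are never selected; only isolated chance-correlated
  # pairs can creep over the 10% threshold
  expect_equal(median(freq$count), 0)
  expect_lte(sum(freq$selected), 5)
})

test_that("stepwise keeps one of two duplicate columns and recovers betas", {
  pc <- simulate_pair_cohort(n_samples = 1000, n_pairs = 5, n_planted = 5,
                             beta = 1, seed = 9)
  v <- rbind(pc$pm$values,
             `LNCA0001|LNCZ9999` = pc$pm$values[1, ])  # duplicate column
  pm <- new_pair_matrix(v)
  expect_message(sw <- stepwise_cox(pm, pc$clinical), "duplicate")
  best <- sw$steps[[sw$best]]
  expect_setequal(best$pairs, pc$planted)
  expect_true(all(abs(coef(best$fit) - 1) < 0.15))
})

test_that("stepwise errors when nothing improves on the null model", {
  pc <- simulate_pair_cohort(n_samples = 60, n_pairs = 2, n_planted = 0,
                             beta = 0, seed = 10)
  # two pure-noise pairs: additions very likely worsen AIC; if one ever
  # enters, the sequence still starts from the null and is short
  res <- tryCatch(stepwise_cox(pc$pm, pc$clinical), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "no AIC improvement")
  } else {
    expect_lte(length(res$steps), 2)
  }
})

test_that("uncensored td-ROC equals the Mann-Whitney statistic", {
  set.seed(11)
  n <- 80
  cl <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                       time = sample(c(200:500, 2200:2500), n, TRUE),
                       event = 1L)
  sc <- tibble::tibble(sample_id = cl$sample_id,
                       risk_score = round(rnorm(n), 1))  # ties included
  horizon_days <- 5 * 365.25
  roc <- td_roc(sc, cl, 5)
  cases <- sc$risk_score[cl$time <= horizon_days]
  controls <- sc$risk_score[cl$time > horizon_days]
  expect_equal(roc$auc, mw_auc(cases, controls), tolerance = 1e-9)
})

test_that("td-ROC sensitivity/1-specificity are monotone along thresholds", {
  set.seed(12)
  cl <- toy_surv(n = 150, seed = 12, beta = 1)
  sc <- tibble::tibble(sample_id = cl$sample_id,
                       risk_score = cl$x + rnorm(150, 0, 0.2))
  roc <- td_roc(sc, cl, horizon_years = 0.2)
  expect_true(all(diff(roc$sensitivity) >= -1e-9))
  expect_true(all(diff(1 - roc$specificity) >= -1e-9))
  expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
})

test_that("select_best_model takes the AUC arg-max of the sweep", {
  pc <- simulate_pair_cohort(n_samples = 300, n_pairs = 6, n_planted = 3,
                             beta = 1.2, seed = 13)
  sw <- stepwise_cox(pc$pm, pc$clinical)
  sig <- select_best_model(sw, pc$pm, pc$clinical, horizon = 2)
  expect_s3_class(sig, "pair_signature")
  expect_equal(sig$auc, max(sig$sweep$auc, na.rm = TRUE))
  expect_equal(length(sig$pairs),
               sig$sweep$n_pairs[which.max(sig$sweep$auc)])
  # singleton sequence: returned unchanged
  sw1 <- structure(list(steps = sw$steps[1], best = 1L,
                        null_aic = sw$null_aic,
                        dropped_duplicates = character(0)),
                   class = "stepwise_cox")
  sig1 <- select_best_model(sw1, pc$pm, pc$clinical, horizon = 2)
  expect_equal(sig1$pairs, sw$steps[[1]]$pairs)
})

test_that("aic_cutpoint recovers a planted separation between score strata", {
  set.seed(14)
  n <- 200
  cluster <- rep(c(0, 1), each = n / 2)
  score <- cluster + rnorm(n, 0, 0.05)
  tt <- rexp(n, 0.002 * 5^cluster)
  cc <- runif(n, 0, 2000)
  cl <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                       time = pmax(1, round(pmin(tt, cc))),
                       event = as.integer(tt <= cc))
  sc <- tibble::tibble(sample_id = cl$sample_id, risk_score = score)
  cut <- aic_cutpoint(sc, cl)
  expect_gt(cut, max(score[cluster == 0]) - 0.2)
  expect_lt(cut, min(score[cluster == 1]) + 0.2)
  expect_error(aic_cutpoint(
    tibble::tibble(sample_id = cl$sample_id, risk_score = 1), cl),
    "identical")
})

test_that("stepwise beta recovery error decays with sample size", {
  mae <- vapply(c(250, 1000), function(n) {
    errs <- vapply(1:8, function(s) {
      pc <- simulate_pair_cohort(n_samples = n, n_pairs = 5, n_planted = 5,
                                 beta = 1, seed = 100 + s)
      sw <- tryCatch(stepwise_cox(pc$pm, pc$clinical),
                     error = function(e) NULL)
      if (is.null(sw)) return(NA_real_)
      best <- sw$steps[[sw$best]]
      b <- setNames(coef(best$fit), best$pairs)[pc$planted]
      median(abs(b - 1), na.rm = TRUE)
    }, numeric(1))
    median(errs, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mae[1], mae[2])
})
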