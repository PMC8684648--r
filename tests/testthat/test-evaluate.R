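test_that("stratify_cohort splits exactly at the cutpoint", {
  cl <- make_cohort(40, seed = 2)[, c("sample_id", "time", "event")]
  sc <- tibble::tibble(sample_id = cl$sample_id,
                       risk_score = seq(-1, 1, length.out = 40))
  st <- stratify_cohort(sc, cl, cutpoint = 0.25)
  expect_identical(st$group == "high", st$risk_score > 0.25)
  expect_equal(sum(st$group == "high") + sum(st$group == "low"), 40)
})

test_that("log-rank statistic matches the O-E/V oracle and detects HR 3", {
  co <- make_cohort(300, seed = 3, hr = 3)
  km <- km_logrank(co)
  expect_equal(km$statistic,
               brute_logrank(co$time, co$event, co$group),
               tolerance = 1e-8)
  expect_lt(km$p, 0.001)
})

test_that("log-rank on duplicated identical groups is exactly null", {
  base <- make_cohort(60, seed = 4)[, c("sample_id", "time", "event")]
  co <- dplyr::bind_rows(
    dplyr::mutate(base, group = "low", risk_score = 0,
                  sample_id = paste0(sample_id, "L")),
    dplyr::mutate(base, group = "high", risk_score = 1,
                  sample_id = paste0(sample_id, "H")))
  co$group <- factor(co$group, levels = c("low", "high"))
  km <- km_logrank(co)
  expect_equal(km$statistic, 0, tolerance = 1e-12)
  expect_equal(km$p, 1)
  expect_error(km_logrank(dplyr::filter(co, group == "low")), "two")
})

test_that("log-rank is invariant to group relabeling and time rescaling", {
  co <- make_cohort(150, seed = 5, hr = 2)
  km1 <- km_logrank(co)
  co2 <- dplyr::mutate(co, group = factor(
    ifelse(group == "high", "low", "high"), levels = c("low", "high")))
  expect_equal(km_logrank(co2)$statistic, km1$statistic, tolerance = 1e-10)
  co3 <- dplyr::mutate(co, time = time * 7 + 1)   # common monotone rescale
  expect_equal(km_logrank(co3)$statistic, km1$statistic, tolerance = 1e-10)
})

test_that("KM estimate with no censoring equals the empirical survivor", {
  set.seed(6)
  co <- tibble::tibble(sample_id = sprintf("s%02d", 1:50),
                       time = sample(1:400, 50, TRUE), event = 1L,
                       risk_score = rnorm(50),
                       group = factor(rep(c("low", "high"), 25),
                                      levels = c("low", "high")))
  km <- km_logrank(co)
  for (g in c("low", "high")) {
    cur <- km$curves[km$curves$group == g, ]
    tg <- co$time[co$group == g]
    expect_equal(cur$surv, vapply(cur$time, function(t) mean(tg > t),
                                  numeric(1)), tolerance = 1e-12)
  }
})

test_that("chi-square association matches the textbook 2x2 formula", {
  co <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:26),
    time = rep(100, 26), event = rep(1L, 26),
    risk_score = c(rep(1, 12), rep(0, 14)),
    group = factor(rep(c("high", "low"), c(12, 14)),
                   levels = c("low", "high")),
    marker = c(rep("pos", 10), rep("neg", 2), rep("pos", 3), rep("neg", 11))
  )
  rep_ <- suppressWarnings(clinical_association(co, "marker"))
  chi <- rep_[rep_$analysis == "chi-square", ]
  expect_equal(chi$statistic, 26 * (10 * 11 - 2 * 3)^2 /
                 (12 * 14 * 13 * 13), tolerance = 1e-10)
  expect_equal(chi$n, 26)
})

test_that("a factor equal to the risk group is maximally associated", {
  co <- make_cohort(100, seed = 7)
  co$copy <- as.character(co$group)
  rep_ <- suppressWarnings(clinical_association(co, "copy"))
  expect_lt(rep_$p[rep_$analysis == "chi-square"], 1e-10)
  expect_equal(rep_$stars[rep_$analysis == "chi-square"], "***")
})

test_that("unknown categories are excluded per-test, all-unknown skipped", {
  co <- make_cohort(80, seed = 8)
  co$f1 <- c(rep("unknown", 10), rep(c("a", "b"), 35))
  co$f2 <- "unknown"
  expect_warning(rep_ <- clinical_association(co, c("f1", "f2")),
                 "fewer than 2")
  expect_equal(unique(rep_$factor), "f1")
  expect_equal(unique(rep_$n[rep_$factor == "f1"]), 70)
})

test_that("multi-level factors use Kruskal-Wallis on the score", {
  co <- make_cohort(120, seed = 9)
  co$stage3 <- sample(c("I", "II", "III"), 120, TRUE)
  rep_ <- suppressWarnings(clinical_association(co, "stage3"))
  expect_true("kruskal-wallis" %in% rep_$analysis)
})

test_that("cox coefficients are scale-equivariant in the risk score", {
  co <- make_cohort(250, seed = 10, hr = 3)
  r1 <- suppressWarnings(independence_cox(co, covariates = character(0)))
  co2 <- dplyr::mutate(co, risk_score = risk_score * 10)
  r2 <- suppressWarnings(independence_cox(co2, covariates = character(0)))
  b1 <- r1$beta[r1$analysis == "univariate" & r1$term == "risk_score"]
  b2 <- r2$beta[r2$analysis == "univariate" & r2$term == "risk_score"]
  expect_equal(b1, 10 * b2, tolerance = 1e-6)
})

test_that("a known binary hazard ratio is recovered at large n", {
  set.seed(11)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.002 * 2^x)          # beta = log 2
  cc <- runif(n, 0, 2000)
  co <- tibble::tibble(sample_id = sprintf("s%04d", 1:n),
                       time = pmax(1, round(pmin(tt, cc))),
                       event = as.integer(tt <= cc),
                       risk_score = x,
                       group = factor(ifelse(x == 1, "high", "low"),
                                      levels = c("low", "high")))
  rep_ <- suppressWarnings(independence_cox(co, covariates = character(0)))
  hr <- rep_$hr[rep_$analysis == "univariate"]
  expect_gt(hr, 1.8); expect_lt(hr, 2.2)
})

test_that("score-driven hazard stays significant with a noisy stage copy", {
  set.seed(12)
  n <- 400
  score <- rnorm(n)
  tt <- rexp(n, 0.002 * exp(0.8 * score))
  cc <- runif(n, 0, 2000)
  stage_lv <- c("I", "II", "III", "IV")
  stage <- stage_lv[pmin(4, pmax(1, round(2.5 + 0.8 * score + rnorm(n))))]
  co <- tibble::tibble(sample_id = sprintf("s%04d", 1:n),
                       time = pmax(1, round(pmin(tt, cc))),
                       event = as.integer(tt <= cc),
                       risk_score = score,
                       group = factor(ifelse(score > 0, "high", "low"),
                                      levels = c("low", "high")),
                       stage = stage)
  rep_ <- suppressWarnings(independence_cox(co, covariates = "stage"))
  multi <- rep_[rep_$analysis == "multivariate", ]
  expect_true("risk_score" %in% multi$term)
  expect_lt(multi$p[multi$term == "risk_score"], 0.01)
})
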