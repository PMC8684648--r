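#' Significance stars
#' @param p numeric p-values.
#' @return `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05,
#'   otherwise `""`.
#' @keywords internal
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Ordered category dictionaries for the supported clinical factors
#'
#' Factor levels in prognostic order; used to encode covariates as ordinal
#' scores in Cox models. `"unknown"` is always admissible and excluded
#' per-test rather than per-sample.
#'
#' @return Named list of character vectors.
#' @export
clinical_dictionary <- function() {
  list(
    t_stage = c("T1", "T2", "T3", "T4"),
    stage = c("I", "II", "III", "IV"),
    grade = c("G1", "G2", "G3", "G4"),
    child_pugh = c("A", "B", "C"),
    ecog = c("0", "1", "2", "3", "4"),
    vascular_invasion = c("no", "yes")
  )
}

#' Dichotomize a scored cohort at a cutpoint
#'
#' @param scores tibble (`sample_id`, `risk_score`) or named numeric.
#' @param clinical tibble with `sample_id`, `time`, `event` and optional
#'   covariates.
#' @param cutpoint risk-score threshold: `score > cutpoint` is high risk.
#' @return Tibble: the clinical columns plus `risk_score` and `group`
#'   (factor `high`/`low`).
#' @export
stratify_cohort <- function(scores, clinical, cutpoint) {
  s <- score_vector(scores, clinical)
  clinical %>%
    mutate(risk_score = s,
           group = factor(ifelse(s > cutpoint, "high", "low"),
                          levels = c("low", "high")))
}

#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' @param cohort tibble from [stratify_cohort()] (columns `time`, `event`,
#'   `group`).
#' @return List of class `km_logrank`: `curves` (tibble `group`, `time`,
#'   `n_risk`, `n_event`, `surv`), `statistic` (log-rank chi-square, 1 df),
#'   `p`, `n` (group sizes).
#' @export
km_logrank <- function(cohort) {
  need_cols(cohort, c("time", "event", "group"))
  if (length(unique(cohort$group)) < 2) {
    abort("log-rank test needs two nonempty risk groups")
  }
  sf <- survfit(Surv(time, event) ~ group, data = cohort)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- tibble(group = sub("^group=", "", strata),
                   time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, surv = sf$surv)
  sd <- survdiff(Surv(time, event) ~ group, data = cohort)
  stat <- sd$chisq
  structure(list(curves = curves, statistic = stat,
                 p = pchisq(stat, df = 1, lower.tail = FALSE),
                 n = table(cohort$group)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> chi-square = %.3f, p = %.3g (n = %s)\n",
              x$statistic, x$p,
              paste(sprintf("%s %d", names(x$n), x$n), collapse = ", ")))
  invisible(x)
}

need_cols <- function(df, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) abort(paste0("missing column(s): ",
                                 paste(miss, collapse = ", ")))
  invisible(df)
}

#' Association of risk group and score with clinicopathological factors
#'
#' Per factor, two complementary tests: (a) a chi-square test of
#' independence between the high/low risk group and the factor's observed
#' categories (categories with expected count below 1 are merged into
#' `"other"`, and `"unknown"` entries are excluded per-test); (b) a
#' rank-based comparison of the continuous risk score across factor levels
#' (Mann-Whitney rank-sum for two levels, Kruskal-Wallis otherwise).
#'
#' @param cohort tibble from [stratify_cohort()].
#' @param covariates character vector of factor column names (default:
#'   every column beyond the survival/score core).
#' @return Association-report tibble: `analysis`, `factor`, `statistic`,
#'   `p`, `n`, `stars`.
#' @export
clinical_association <- function(cohort, covariates = NULL) {
  need_cols(cohort, c("risk_score", "group"))
  if (is.null(covariates)) {
    covariates <- setdiff(names(cohort),
                          c("sample_id", "time", "event", "risk_score",
                            "group"))
  }
  purrr::map_dfr(covariates, function(v) {
    x <- cohort[[v]]
    keep <- !is.na(x) & x != "unknown"
    if (length(unique(x[keep])) < 2) {
      warn(paste0("factor '", v, "' has fewer than 2 observed categories; skipped"))
      return(tibble())
    }
    g <- cohort$group[keep]
    xv <- factor(x[keep])
    tab <- table(g, xv)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    low <- apply(expected, 2, min) < 1
    if (any(low) && sum(!low) >= 1) {
      inform(paste0("factor '", v, "': merged sparse categories (",
                    paste(colnames(tab)[low], collapse = ", "),
                    ") into 'other'"))
      lv <- levels(xv)
      xv <- as.character(xv)
      xv[xv %in% lv[low]] <- "other"
      xv <- factor(xv)
      tab <- table(g, xv)
    }
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
    sc <- cohort$risk_score[keep]
    if (nlevels(xv) == 2) {
      rk <- suppressWarnings(wilcox.test(sc ~ xv, exact = FALSE))
      rk_name <- "rank-sum"
    } else {
      rk <- kruskal.test(sc ~ xv)
      rk_name <- "kruskal-wallis"
    }
    bind_rows(
      tibble(analysis = "chi-square", factor = v,
             statistic = unname(chi$statistic), p = chi$p.value,
             n = sum(keep)),
      tibble(analysis = rk_name, factor = v,
             statistic = unname(rk$statistic), p = rk$p.value,
             n = sum(keep))
    )
  }) %>%
    mutate(stars = p_stars(.data$p))
}

encode_ordinal <- function(x, levels) {
  out <- as.numeric(match(x, levels))
  out  # unknown / unexpected -> NA, excluded per-test
}

#' Univariate and multivariate Cox regression of risk score and clinical
#' factors
#'
#' Each clinical factor is encoded as an ordinal score via
#' [clinical_dictionary()] (unknowns excluded per-test); the risk score
#' enters as a continuous covariate. Every term is tested in a univariate
#' Cox model; terms with univariate p below `entry_p` enter a joint
#' multivariate model (complete cases for those terms). Hazard ratios are
#' `exp(beta)` with Wald 95% confidence intervals. A warning is issued
#' when events are fewer than ten per candidate covariate.
#'
#' @param cohort tibble from [stratify_cohort()].
#' @param covariates factor columns to test (default: dictionary factors
#'   present in the cohort).
#' @param entry_p univariate p threshold for multivariate entry.
#' @return Association-report tibble: `analysis`, `term`, `beta`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `n`, `stars`.
#' @export
independence_cox <- function(cohort, covariates = NULL, entry_p = 0.05) {
  need_cols(cohort, c("time", "event", "risk_score"))
  dict <- clinical_dictionary()
  if (is.null(covariates)) {
    covariates <- intersect(names(dict), names(cohort))
  }
  terms <- c("risk_score", covariates)
  enc <- tibble(risk_score = cohort$risk_score)
  for (v in covariates) {
    lv <- dict[[v]] %||% sort(unique(cohort[[v]][cohort[[v]] != "unknown"]))
    enc[[v]] <- encode_ordinal(cohort[[v]], lv)
  }
  if (sum(cohort$event) < 10 * length(terms)) {
    warn("fewer than 10 events per candidate covariate; estimates may be unstable")
  }
  one_fit <- function(fml, dat, nm, analysis) {
    fit <- tryCatch(suppressWarnings(
      coxph(fml, data = dat, ties = "efron")), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(analysis = analysis, term = nm, beta = NA_real_,
                    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_, n = NA_integer_))
    }
    cs <- summary(fit)$coefficients
    tibble(analysis = analysis, term = rownames(cs),
           beta = cs[, "coef"], hr = exp(cs[, "coef"]),
           ci_low = exp(cs[, "coef"] - 1.96 * cs[, "se(coef)"]),
           ci_high = exp(cs[, "coef"] + 1.96 * cs[, "se(coef)"]),
           p = cs[, "Pr(>|z|)"], n = fit$n)
  }
  uni <- purrr::map_dfr(terms, function(v) {
    dat <- tibble(time = cohort$time, event = cohort$event, x = enc[[v]])
    dat <- dat[!is.na(dat$x), ]
    if (length(unique(dat$x)) < 2) {
      warn(paste0("term '", v, "' has no variation; skipped"))
      return(tibble())
    }
    out <- one_fit(Surv(time, event) ~ x, dat, v, "univariate")
    out$term <- v
    out
  })
  sig_terms <- uni$term[!is.na(uni$p) & uni$p < entry_p]
  multi <- tibble()
  if (length(sig_terms) >= 1) {
    dat <- dplyr::bind_cols(tibble(time = cohort$time, event = cohort$event),
                            enc[sig_terms])
    dat <- dat[stats::complete.cases(dat), ]
    fml <- stats::as.formula(paste("Surv(time, event) ~",
                                   paste(sig_terms, collapse = " + ")))
    multi <- one_fit(fml, dat, sig_terms, "multivariate")
  }
  bind_rows(uni, multi) %>% mutate(stars = p_stars(.data$p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
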