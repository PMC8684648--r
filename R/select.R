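align_pm_clinical <- function(pm, clinical) {
  common <- intersect(pm$sample_ids, clinical$sample_id)
  if (length(common) < 2) abort("pair matrix and clinical table share too few samples")
  list(pm = subset_pairs(pm, samples = common),
       clinical = clinical[match(common, clinical$sample_id), ])
}

score_vector <- function(scores, clinical) {
  if (is.data.frame(scores)) {
    s <- setNames(scores$risk_score, scores$sample_id)
  } else if (!is.null(names(scores))) {
    s <- scores
  } else {
    abort("scores must be a tibble (sample_id, risk_score) or a named vector")
  }
  miss <- setdiff(clinical$sample_id, names(s))
  if (length(miss)) abort(paste0("no risk score for sample(s): ",
                                 paste(head(miss, 5), collapse = ", ")))
  unname(s[clinical$sample_id])
}

#' Univariate Cox screen of pair indicators
#'
#' Fits a single-covariate Cox proportional-hazards model (Efron tie
#' handling) per pair and keeps pairs with Wald p below `p_max`. Pairs with
#' a constant indicator, or whose fit fails to converge (for example a
#' monotone likelihood from perfect separation), are dropped with a
#' warning rather than an error.
#'
#' @param pm a [pair_matrix][new_pair_matrix].
#' @param clinical tibble with `sample_id`, `time`, `event`.
#' @param p_max Wald p-value threshold (default 0.05).
#' @return The filtered `pair_matrix`; attribute `"univariate"` holds a
#'   tibble (`pair_id`, `beta`, `se`, `p`, `kept`) over all tested pairs.
#' @export
univariate_cox_screen <- function(pm, clinical, p_max = 0.05) {
  al <- align_pm_clinical(pm, clinical)
  pm <- al$pm; clinical <- al$clinical
  y <- Surv(clinical$time, clinical$event)
  res <- purrr::map_dfr(seq_len(nrow(pm$values)), function(i) {
    x <- pm$values[i, ]
    if (length(unique(x)) < 2) {
      return(tibble(pair_id = rownames(pm$values)[i],
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    status = "constant"))
    }
    fit <- NULL
    bad <- FALSE
    withCallingHandlers(
      fit <- tryCatch(coxph(y ~ x, ties = "efron",
                            control = survival::coxph.control(eps = 1e-9)),
                      error = function(e) NULL),
      warning = function(w) {
        bad <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (is.null(fit) || bad || !is.finite(coef(fit)) ||
        abs(coef(fit)) > 15) {
      return(tibble(pair_id = rownames(pm$values)[i],
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    status = "nonconverged"))
    }
    b <- unname(coef(fit))
    se <- sqrt(unname(fit$var[1, 1]))
    tibble(pair_id = rownames(pm$values)[i], beta = b, se = se,
           p = 2 * pnorm(-abs(b / se)), status = "ok")
  })
  dropped <- res$pair_id[res$status != "ok"]
  if (length(dropped)) {
    warn(paste0("dropped ", length(dropped),
                " pair(s) with constant or non-converging fits"))
  }
  res$kept <- !is.na(res$p) & res$p < p_max
  out <- subset_pairs(pm, pairs = res$pair_id[res$kept])
  attr(out, "univariate") <- res
  out
}

#' Selection-frequency table from repeated cross-validated LASSO-Cox
#'
#' Repeats, `n_reps` times: draw a bootstrap resample of the cohort
#' (preserving each sample's time/event), run `n_folds`-fold
#' cross-validated L1-penalized Cox regression over a lambda path, take the
#' lambda minimizing mean cross-validated partial-likelihood deviance, and
#' record which pairs have nonzero coefficients there. Pairs selected more
#' than `freq_threshold` times form the candidate set for the multivariable
#' model. A resample with fewer events than folds is redrawn (bounded
#' retries). Each repetition runs on its own deterministic substream of the
#' master seed, so results do not depend on execution order.
#'
#' The lambda path is deliberately short and coarse (`nlambda`,
#' `lambda_min_ratio`, `thresh`): only membership of the active set at the
#' CV-optimal lambda matters here, not a finely resolved path, and the
#' dense small-lambda tail is by far the most expensive part of a
#' penalized Cox fit on bootstrap data.
#'
#' @param pm a [pair_matrix][new_pair_matrix] (typically after
#'   [univariate_cox_screen()]).
#' @param clinical tibble with `sample_id`, `time`, `event`.
#' @param n_reps LASSO repetitions (default 1000).
#' @param n_folds cross-validation folds (default 10).
#' @param freq_threshold selection count above which a pair is a candidate
#'   (default 100, i.e. 10% of the default repetitions).
#' @param seed master seed.
#' @param resample `"bootstrap"` (default) or `"cv-only"` (refresh only the
#'   fold assignment each repetition).
#' @param lambda_rule `"min"` (default) takes the CV-deviance minimum;
#'   `"1se"` takes the sparsest model within one standard error of it. The
#'   minimum rule maximizes sensitivity to planted signal but, on data with
#'   no signal at all, routinely admits noise pairs (the CV curve is flat
#'   and its empirical minimum sits at interior lambdas); the 1-SE rule is
#'   the conservative choice whose null selection frequencies stay low.
#' @param nlambda,lambda_min_ratio,thresh glmnet path controls.
#' @return Tibble `pair_id`, `count`, `selected`; attributes `n_reps`,
#'   `freq_threshold`, `seed`.
#' @export
repeated_lasso_selection <- function(pm, clinical, n_reps = 1000,
                                     n_folds = 10, freq_threshold = 100,
                                     seed = 1,
                                     resample = c("bootstrap", "cv-only"),
                                     lambda_rule = c("min", "1se"),
                                     nlambda = 15, lambda_min_ratio = 0.15,
                                     thresh = 1e-4) {
  resample <- match.arg(resample)
  lambda_rule <- match.arg(lambda_rule)
  s_choice <- if (lambda_rule == "min") "lambda.min" else "lambda.1se"
  al <- align_pm_clinical(pm, clinical)
  pm <- al$pm; clinical <- al$clinical
  x <- t(pm$values)
  n <- nrow(x)
  if (sum(clinical$event) < n_folds) {
    abort("fewer events than cross-validation folds")
  }
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  counts <- setNames(integer(ncol(x)), colnames(x))
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    idx <- seq_len(n)
    if (resample == "bootstrap") {
      ok <- FALSE
      for (try in 1:50) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(clinical$event[idx]) >= n_folds &&
            length(unique(clinical$time[idx][clinical$event[idx] == 1])) >= 2) {
          ok <- TRUE; break
        }
      }
      if (!ok) abort("could not draw a resample with enough events")
    }
    foldid <- sample(rep_len(seq_len(n_folds), n))
    y <- Surv(clinical$time[idx], clinical$event[idx])
    cv <- glmnet::cv.glmnet(x[idx, , drop = FALSE], y, family = "cox",
                            foldid = foldid, nlambda = nlambda,
                            lambda.min.ratio = lambda_min_ratio,
                            thresh = thresh)
    cf <- coef(cv, s = s_choice)
    nz <- rownames(cf)[as.numeric(cf) != 0]
    counts[nz] <- counts[nz] + 1L
  }
  out <- tibble(pair_id = names(counts), count = unname(counts),
                selected = unname(counts) > freq_threshold)
  attr(out, "n_reps") <- n_reps
  attr(out, "freq_threshold") <- freq_threshold
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Bidirectional stepwise Cox model over candidate pairs
#'
#' Starting from the null model, repeatedly takes the single addition or
#' removal that most reduces AIC (-2 log partial likelihood + 2 p), until
#' no move improves it. Identical indicator columns are deduplicated first
#' (keeping the lexicographically first pair). The full visited model
#' sequence is returned so a time-dependent-AUC sweep can choose among the
#' nested candidates.
#'
#' @param pm a [pair_matrix][new_pair_matrix].
#' @param clinical tibble with `sample_id`, `time`, `event`.
#' @param candidates pair ids to consider (default: all rows of `pm`).
#' @param max_steps safety bound on accepted moves.
#' @return List of class `stepwise_cox`: `steps` (each with `pairs`, `fit`,
#'   `aic`), `best` (index of the AIC-optimal model), `null_aic`,
#'   `dropped_duplicates`.
#' @export
stepwise_cox <- function(pm, clinical, candidates = NULL, max_steps = 50) {
  al <- align_pm_clinical(pm, clinical)
  pm <- al$pm; clinical <- al$clinical
  if (is.null(candidates)) candidates <- rownames(pm$values)
  if (is.data.frame(candidates)) {
    candidates <- candidates$pair_id[candidates$selected]
  }
  candidates <- intersect(candidates, rownames(pm$values))
  if (!length(candidates)) abort("no candidate pairs to fit")
  v <- pm$values[candidates, , drop = FALSE]
  dup <- duplicated(as.data.frame(v))
  dropped <- candidates[dup]
  if (length(dropped)) {
    inform(paste0("stepwise_cox: dropped ", length(dropped),
                  " duplicate indicator column(s)"))
  }
  candidates <- candidates[!dup]
  v <- v[!dup, , drop = FALSE]
  dat <- as.data.frame(t(v))
  vars <- paste0("v", seq_along(candidates))
  names(dat) <- vars
  dat$time <- clinical$time
  dat$event <- clinical$event
  fit_aic <- function(sel) {
    if (!length(sel)) return(list(fit = NULL, aic = null_aic))
    f <- stats::as.formula(paste("Surv(time, event) ~",
                                 paste(sel, collapse = " + ")))
    fit <- tryCatch(
      suppressWarnings(coxph(f, data = dat, ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(coef(fit)))) {
      return(list(fit = NULL, aic = Inf))
    }
    list(fit = fit, aic = -2 * fit$loglik[2] + 2 * length(sel))
  }
  f0 <- suppressWarnings(coxph(stats::as.formula(
    paste("Surv(time, event) ~", vars[1])), data = dat))
  null_aic <- -2 * f0$loglik[1]

  current <- character(0)
  cur_aic <- null_aic
  steps <- list()
  for (step in seq_len(max_steps)) {
    moves <- c(setdiff(vars, current),                    # additions
               if (length(current) > 1) current)          # removals
    if (!length(moves)) break
    cand <- purrr::map(moves, function(m) {
      sel <- if (m %in% current) setdiff(current, m) else c(current, m)
      c(list(sel = sel), fit_aic(sel))
    })
    aics <- purrr::map_dbl(cand, "aic")
    best <- which.min(aics)
    if (aics[best] >= cur_aic - 1e-8) break
    current <- cand[[best]]$sel
    cur_aic <- aics[best]
    steps[[length(steps) + 1]] <- list(
      pairs = candidates[match(current, vars)],
      fit = cand[[best]]$fit,
      aic = cur_aic
    )
  }
  if (!length(steps)) {
    abort("stepwise selection accepted no pair (no AIC improvement over null)")
  }
  structure(list(steps = steps,
                 best = which.min(purrr::map_dbl(steps, "aic")),
                 null_aic = null_aic,
                 dropped_duplicates = dropped),
            class = "stepwise_cox")
}

#' @export
print.stepwise_cox <- function(x, ...) {
  cat(sprintf("<stepwise_cox> %d visited model(s); AIC-optimal model %d (%d pairs, AIC %.2f)\n",
              length(x$steps), x$best, length(x$steps[[x$best]]$pairs),
              x$steps[[x$best]]$aic))
  invisible(x)
}

#' Risk score of a pair signature
#'
#' `RiskScore(s) = sum_i beta_i * S_i(s)` over the signature's pair
#' indicators.
#'
#' @param object a [pair_signature][fit_pair_signature], or a named numeric
#'   vector of coefficients keyed by pair id.
#' @param pm a [pair_matrix][new_pair_matrix] containing all signature
#'   pairs.
#' @return Tibble `sample_id`, `risk_score`.
#' @export
risk_score <- function(object, pm) {
  betas <- if (inherits(object, "pair_signature")) object$betas else object
  if (is.null(names(betas))) abort("coefficients must be named by pair id")
  miss <- setdiff(names(betas), rownames(pm$values))
  if (length(miss)) abort(paste0("signature pair(s) missing from matrix: ",
                                 paste(miss, collapse = ", ")))
  s <- as.numeric(betas %*% pm$values[names(betas), , drop = FALSE])
  tibble(sample_id = pm$sample_ids, risk_score = s)
}

km_surv_at <- function(time, event, t_star) {
  if (!length(time)) return(NA_real_)
  fit <- survfit(Surv(time, event) ~ 1)
  summary(fit, times = t_star, extend = TRUE)$surv
}

#' Time-dependent ROC curve for censored survival data
#'
#' Cumulative/dynamic ROC at a fixed horizon with the Kaplan-Meier-based
#' estimator of Heagerty, Lumley and Pepe (1998): cases are subjects with
#' an event by the horizon, controls are survivors past it, and the
#' censoring distribution is handled by KM estimates of survival overall
#' and within each `score > c` subgroup:
#' `TP(c) = [1 - S_c(t)] P(X > c) / [1 - S(t)]`,
#' `FP(c) = S_c(t) P(X > c) / S(t)`.
#' The AUC is the trapezoidal area over the curve. With no censoring this
#' reduces exactly to the classical empirical ROC and its Mann-Whitney
#' area.
#'
#' @param scores tibble (`sample_id`, `risk_score`) or named numeric.
#' @param clinical tibble with `sample_id`, `time` (days), `event`.
#' @param horizon_years evaluation horizon in years.
#' @param days_per_year conversion constant (default 365.25).
#' @return Object of class `td_roc`: `horizon`, `thresholds`,
#'   `sensitivity`, `specificity`, `auc`.
#' @export
td_roc <- function(scores, clinical, horizon_years = 5,
                   days_per_year = 365.25) {
  s <- score_vector(scores, clinical)
  t_star <- horizon_years * days_per_year
  time <- clinical$time; event <- clinical$event
  if (!any(time <= t_star & event == 1)) {
    abort("no events before the horizon; ROC undefined")
  }
  if (!any(time > t_star)) {
    abort("no samples at risk past the horizon; ROC undefined")
  }
  S_all <- km_surv_at(time, event, t_star)
  if (!is.finite(S_all) || S_all <= 0 || S_all >= 1) {
    abort("overall survival at the horizon is degenerate")
  }
  thr <- sort(unique(s), decreasing = TRUE)
  tp <- fp <- numeric(length(thr))
  for (k in seq_along(thr)) {
    grp <- s >= thr[k]      # test-positive at this threshold
    if (!any(grp)) { tp[k] <- 0; fp[k] <- 0; next }
    S_c <- km_surv_at(time[grp], event[grp], t_star)
    if (!is.finite(S_c)) S_c <- 0
    p_c <- mean(grp)
    tp[k] <- (1 - S_c) * p_c / (1 - S_all)
    fp[k] <- S_c * p_c / S_all
  }
  tp <- pmin(pmax(tp, 0), 1)
  fp <- pmin(pmax(fp, 0), 1)
  # the KM-weighted estimator can be locally non-monotone under censoring;
  # isotonize along the threshold sweep (no effect when uncensored)
  tp <- cummax(tp)
  fp <- cummax(fp)
  x <- c(0, fp); y <- c(0, tp)
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  structure(list(horizon = horizon_years,
                 thresholds = thr,
                 sensitivity = tp,
                 specificity = 1 - fp,
                 auc = auc),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("<td_roc> %g-year AUC = %.3f (%d thresholds)\n",
              x$horizon, x$auc, length(x$thresholds)))
  invisible(x)
}

#' Tidy a time-dependent ROC curve
#' @param x a [td_roc] object.
#' @param ... unused.
#' @return Tibble `threshold`, `sensitivity`, `specificity`.
#' @export
tidy.td_roc <- function(x, ...) {
  tibble(threshold = x$thresholds, sensitivity = x$sensitivity,
         specificity = x$specificity)
}

#' Choose the model maximizing the horizon AUC along a stepwise sequence
#'
#' Computes the time-dependent AUC (default 5-year) of the risk score of
#' every model visited by [stepwise_cox()] and returns the arg-max model as
#' a fitted signature; the AUC-versus-model curve is retained for plotting
#' and the stopping rule "terminate when the maximum AUC is the highest
#' point of the curve".
#'
#' @param sw a `stepwise_cox` object.
#' @param pm the [pair_matrix][new_pair_matrix] the models were fit on.
#' @param clinical tibble with `sample_id`, `time`, `event`.
#' @param horizon horizon in years (default 5).
#' @return A `pair_signature` (cutpoint not yet set); its `sweep` element
#'   is a tibble `model`, `n_pairs`, `auc`.
#' @export
select_best_model <- function(sw, pm, clinical, horizon = 5) {
  stopifnot(inherits(sw, "stepwise_cox"))
  al <- align_pm_clinical(pm, clinical)
  sweep <- purrr::map_dfr(seq_along(sw$steps), function(i) {
    st <- sw$steps[[i]]
    betas <- setNames(unname(coef(st$fit)), st$pairs)
    sc <- risk_score(betas, al$pm)
    auc <- tryCatch(td_roc(sc, al$clinical, horizon)$auc,
                    error = function(e) NA_real_)
    tibble(model = i, n_pairs = length(st$pairs), auc = auc)
  })
  if (all(is.na(sweep$auc))) abort("no model yielded a defined AUC")
  best <- which.max(sweep$auc)
  st <- sw$steps[[best]]
  new_pair_signature(
    betas = setNames(unname(coef(st$fit)), st$pairs),
    auc = sweep$auc[best], horizon = horizon, sweep = sweep
  )
}

#' AIC-optimal cutpoint for dichotomizing risk scores
#'
#' Candidate cutpoints are midpoints between consecutive sorted unique
#' scores, restricted so each side retains at least `min_side_frac` of the
#' samples (unrestricted if that leaves no candidate). Each candidate
#' dichotomizes the score into a single binary Cox covariate; the cutpoint
#' minimizing the model's AIC is returned, ties resolved toward the
#' smaller cutpoint.
#'
#' @param scores tibble (`sample_id`, `risk_score`) or named numeric.
#' @param clinical tibble with `sample_id`, `time`, `event`.
#' @param min_side_frac minimum fraction of samples on each side of the
#'   cut (default 0.1).
#' @return The cutpoint (numeric scalar). Attributes: `"aic"` (tibble
#'   `cutpoint`, `aic`) and `"delta_aic_vs_null"` (negative when the split
#'   improves on the null model; near zero flags an uninformative score).
#' @export
aic_cutpoint <- function(scores, clinical, min_side_frac = 0.1) {
  s <- score_vector(scores, clinical)
  u <- sort(unique(s))
  if (length(u) < 2) abort("all risk scores identical; no cutpoint exists")
  mids <- (u[-1] + u[-length(u)]) / 2
  n <- length(s)
  n_min <- ceiling(min_side_frac * n)
  n_high <- vapply(mids, function(c) sum(s > c), integer(1))
  ok <- n_high >= n_min & (n - n_high) >= n_min
  if (!any(ok)) ok <- rep(TRUE, length(mids))
  mids <- mids[ok]
  y <- Surv(clinical$time, clinical$event)
  aic <- vapply(mids, function(c) {
    fit <- tryCatch(suppressWarnings(coxph(y ~ I(s > c), ties = "efron")),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit))) return(Inf)
    -2 * fit$loglik[2] + 2
  }, numeric(1))
  best <- which(aic == min(aic))[1]          # ties -> smaller cutpoint
  f1 <- suppressWarnings(coxph(y ~ I(s > mids[best]), ties = "efron"))
  out <- mids[best]
  attr(out, "aic") <- tibble(cutpoint = mids, aic = aic)
  attr(out, "delta_aic_vs_null") <- aic[best] - (-2 * f1$loglik[1])
  out
}

#' Concordance index of a risk score against survival
#'
#' @param scores tibble (`sample_id`, `risk_score`) or named numeric.
#' @param clinical tibble with `sample_id`, `time`, `event`.
#' @return The C-index (higher score = higher risk = shorter survival).
#' @export
score_cindex <- function(scores, clinical) {
  s <- score_vector(scores, clinical)
  fit <- concordance(Surv(clinical$time, clinical$event) ~ s, reverse = TRUE)
  unname(fit$concordance)
}

#' Fit a pair signature end to end
#'
#' Runs the full selection cascade on a validity-filtered pair matrix:
#' univariate Cox screen, repeated cross-validated LASSO-Cox with
#' selection-frequency filtering, bidirectional stepwise Cox, the
#' horizon-AUC model sweep, and the AIC-optimal cutpoint on the chosen
#' model's risk scores.
#'
#' @inheritParams repeated_lasso_selection
#' @param p_max univariate Wald p threshold.
#' @param horizon AUC horizon in years.
#' @param min_side_frac cutpoint side constraint, see [aic_cutpoint()].
#' @return A fitted `pair_signature` with cutpoint set; provenance carries
#'   the selection-frequency table and all thresholds.
#' @export
fit_pair_signature <- function(pm, clinical, p_max = 0.05, n_reps = 1000,
                               n_folds = 10, freq_threshold = 100,
                               seed = 1, horizon = 5, min_side_frac = 0.1,
                               resample = c("bootstrap", "cv-only"),
                               lambda_rule = c("min", "1se"),
                               nlambda = 15, lambda_min_ratio = 0.15,
                               thresh = 1e-4) {
  resample <- match.arg(resample)
  lambda_rule <- match.arg(lambda_rule)
  al <- align_pm_clinical(pm, clinical)
  uni <- univariate_cox_screen(al$pm, al$clinical, p_max = p_max)
  if (nrow(uni$values) < 2) abort("fewer than 2 pairs pass the univariate screen")
  freq <- repeated_lasso_selection(uni, al$clinical, n_reps = n_reps,
                                   n_folds = n_folds,
                                   freq_threshold = freq_threshold,
                                   seed = seed, resample = resample,
                                   lambda_rule = lambda_rule,
                                   nlambda = nlambda,
                                   lambda_min_ratio = lambda_min_ratio,
                                   thresh = thresh)
  cand <- freq$pair_id[freq$selected]
  if (!length(cand)) abort("no pair exceeds the selection-frequency threshold")
  sw <- stepwise_cox(uni, al$clinical, candidates = cand)
  sig <- select_best_model(sw, uni, al$clinical, horizon = horizon)
  sc <- risk_score(sig, al$pm)
  sig$cutpoint <- as.numeric(aic_cutpoint(sc, al$clinical,
                                          min_side_frac = min_side_frac))
  sig$provenance <- list(
    n_reps = n_reps, n_folds = n_folds, freq_threshold = freq_threshold,
    p_max = p_max, seed = as.integer(seed), resample = resample,
    n_pairs_univariate = nrow(uni$values),
    n_candidates = length(cand)
  )
  sig$selection_freq <- freq
  sig
}
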