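#' Kaplan-Meier plot of a stratified cohort
#'
#' @param x a [km_logrank] result.
#' @param ... unused.
#' @return A ggplot object (step curves per risk group, log-rank p in the
#'   subtitle).
#' @export
autoplot.km_logrank <- function(x, ...) {
  ggplot2::ggplot(x$curves,
                  ggplot2::aes(.data$time, .data$surv,
                               color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  color = "Risk group",
                  subtitle = sprintf("log-rank p = %.2g", x$p)) +
    ggplot2::theme_minimal()
}

#' Time-dependent ROC plot
#'
#' @param x a [td_roc] object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.td_roc <- function(x, ...) {
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(1 - .data$specificity,
                                   .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("%g-year AUC = %.3f", x$horizon,
                                     x$auc)) +
    ggplot2::theme_minimal()
}

#' AUC-versus-model sweep of a fitted signature
#'
#' Shows the time-dependent AUC of every model visited by the stepwise
#' search, with the chosen (maximum-AUC) model highlighted.
#'
#' @param sig a `pair_signature` with a `sweep` element.
#' @return A ggplot object.
#' @export
plot_auc_sweep <- function(sig) {
  stopifnot(inherits(sig, "pair_signature"), !is.null(sig$sweep))
  best <- sig$sweep[which.max(sig$sweep$auc), ]
  ggplot2::ggplot(sig$sweep, ggplot2::aes(.data$model, .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = best, color = "red", size = 3) +
    ggplot2::labs(x = "Stepwise model index", y =
                    sprintf("%g-year AUC", sig$horizon)) +
    ggplot2::theme_minimal()
}

#' Lollipop plot of risk-infiltration correlations
#'
#' @param report tibble from [risk_infiltration_correlation()].
#' @param method optional single method to display (default: all,
#'   facetted).
#' @return A ggplot object.
#' @export
plot_infiltration <- function(report, method = NULL) {
  if (!is.null(method)) report <- report[report$method %in% method, ]
  report$label <- paste(report$cell_type, report$method, sep = " / ")
  report$label <- stats::reorder(report$label, report$rho)
  ggplot2::ggplot(report,
                  ggplot2::aes(.data$rho, .data$label,
                               color = .data$significant)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$rho,
                                       yend = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Spearman rho with risk score", y = NULL,
                  color = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
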