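#' Construct a pair-signature object
#'
#' @param betas named numeric vector of Cox coefficients keyed by pair id
#'   (`"A|B"`).
#' @param cutpoint risk-score threshold dividing high and low risk.
#' @param auc time-dependent AUC of the model at `horizon` at fit time.
#' @param horizon AUC horizon in years.
#' @param sweep tibble of the AUC-versus-model sweep (optional).
#' @param provenance list of fitting parameters (optional).
#' @return An object of class `pair_signature`.
#' @keywords internal
#' @export
new_pair_signature <- function(betas, cutpoint = NA_real_, auc = NA_real_,
                               horizon = 5, sweep = NULL,
                               provenance = list()) {
  if (is.null(names(betas)) || !length(betas)) {
    abort("betas must be a nonempty named vector")
  }
  structure(list(
    pairs = names(betas),
    betas = betas,
    cutpoint = cutpoint,
    auc = auc,
    horizon = horizon,
    sweep = sweep,
    provenance = provenance,
    selection_freq = NULL
  ), class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("<pair_signature> %d pair(s); %g-year AUC %.3f; cutpoint %s\n",
              length(x$pairs), x$horizon, x$auc,
              ifelse(is.na(x$cutpoint), "unset",
                     format(x$cutpoint, digits = 4))))
  print(tidy(x), n = 10)
  invisible(x)
}

#' Per-pair coefficients of a fitted signature
#'
#' @param x a `pair_signature`.
#' @param ... unused.
#' @return Tibble `pair_id`, `gene_a`, `gene_b`, `beta`, `hazard_ratio`.
#' @export
tidy.pair_signature <- function(x, ...) {
  ab <- stringr::str_split_fixed(x$pairs, stringr::fixed("|"), 2)
  tibble(pair_id = x$pairs, gene_a = ab[, 1], gene_b = ab[, 2],
         beta = unname(x$betas), hazard_ratio = exp(unname(x$betas)))
}

#' One-row summary of a fitted signature
#'
#' @param x a `pair_signature`.
#' @param ... unused.
#' @return Tibble `n_pairs`, `auc`, `horizon`, `cutpoint`.
#' @export
glance.pair_signature <- function(x, ...) {
  tibble(n_pairs = length(x$pairs), auc = x$auc, horizon = x$horizon,
         cutpoint = x$cutpoint)
}

#' Serialize a fitted signature to JSON
#'
#' Coefficients and the cutpoint are written at full precision so that
#' [read_signature()] reproduces the object exactly.
#'
#' @param sig a `pair_signature`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "pair_signature"))
  payload <- list(
    pairs = sig$pairs,
    betas = unname(sig$betas),
    cutpoint = sig$cutpoint,
    auc = sig$auc,
    horizon = sig$horizon,
    provenance = sig$provenance
  )
  if (!is.null(sig$sweep)) payload$sweep <- as.list(sig$sweep)
  # 17 significant digits: the smallest count that round-trips doubles
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized signature
#'
#' @param path `.json` file written by [write_signature()].
#' @return A `pair_signature`.
#' @export
read_signature <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sig <- new_pair_signature(
    betas = setNames(as.numeric(p$betas), p$pairs),
    cutpoint = as.numeric(p$cutpoint),
    auc = as.numeric(p$auc),
    horizon = as.numeric(p$horizon),
    sweep = if (!is.null(p$sweep)) as_tibble(p$sweep),
    provenance = as.list(p$provenance)
  )
  sig
}
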