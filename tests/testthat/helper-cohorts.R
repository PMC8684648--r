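# shared stratified-cohort fixture: two risk groups with a planted hazard
# ratio, day-rounded exponential times, uniform censoring
make_cohort <- function(n = 120, seed = 1, hr = 3) {
  set.seed(seed)
  group <- rep(c("low", "high"), each = n / 2)
  tt <- rexp(n, 0.002 * ifelse(group == "high", hr, 1))
  cc <- runif(n, 0, 2000)
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    time = pmax(1, round(pmin(tt, cc))),
    event = as.integer(tt <= cc),
    risk_score = ifelse(group == "high", 1, 0) + rnorm(n, 0, 0.1),
    group = factor(group, levels = c("low", "high"))
  )
}
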