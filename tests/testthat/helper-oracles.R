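# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# pair indicators by explicit double loop over ordered pairs and samples
brute_pair_matrix <- function(x, genes) {
  genes <- sort(genes)
  n <- length(genes)
  rows <- list()
  ids <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- genes[i]; b <- genes[j]
      row <- integer(ncol(x))
      for (s in seq_len(ncol(x))) {
        row[s] <- if (x[a, s] > x[b, s]) 1L else 0L
      }
      rows[[length(rows) + 1]] <- row
      ids <- c(ids, paste(a, b, sep = "|"))
    }
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(ids, colnames(x))
  m
}

# Benjamini-Hochberg step-up by the definition
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * (n / k))
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# Efron partial log-likelihood for a single covariate with possible ties
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(exp(beta * x[R]))
    sum_d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (j in 0:(d - 1)) {
      ll <- ll - log(sum_r - (j / d) * sum_d)
    }
  }
  ll
}

# Mann-Whitney AUC with midrank tie handling, by explicit pair counting
mw_auc <- function(score_case, score_control) {
  tot <- 0
  for (a in score_case) {
    for (b in score_control) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(score_case) * length(score_control))
}

# two-group log-rank chi-square by the O-E / V formula at each event time
brute_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))  # 1/2
  oe <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}

# Spearman rho with midranks, from first principles
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small random expression object for pair tests
random_expr <- function(n_genes = 6, n_samples = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n_genes * n_samples, 0.2), n_genes, n_samples,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  lnc_expression(m, biotype = "lncRNA", group = "tumor")
}

dir_digests <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) {
    unname(tools::md5sum(f))
  }, character(1)) |>
    setNames(sub(paste0("^", dir, "/?"), "", files))
}
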