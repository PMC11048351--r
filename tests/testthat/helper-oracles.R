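# Independent oracles, coded from first principles and kept separate from
# the implementations they check.

# Upper-tail Fisher p by brute-force enumeration of the hypergeometric
# support, using only choose().
oracle_fisher_one_sided <- function(a, b, c, d) {
  m <- a + b   # positive-set size
  n <- c + d   # background-set size
  k <- a + c   # total hits
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  pmf <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  sum(pmf[support >= a])
}

# Literal two-stage Benjamini-Krieger-Yekutieli rejection set, written as
# explicit step-up loops over the sorted p-values.
oracle_bky_reject <- function(p, q) {
  m <- length(p)
  step_up <- function(p, level) {
    o <- order(p)
    ps <- p[o]
    k_max <- 0
    for (k in seq_len(m)) if (ps[k] <= k * level / m) k_max <- k
    rej <- logical(m)
    if (k_max > 0) rej[o[seq_len(k_max)]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  stage1 <- step_up(p, q1)
  r1 <- sum(stage1)
  if (r1 == 0) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  step_up(p, q1 * m / (m - r1))
}

# AUC as the Mann-Whitney statistic: P(score_pos > score_neg) + 0.5 P(tie),
# via midranks.
oracle_auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Gaussian naive Bayes posterior for one test point, direct arithmetic.
oracle_nb_posterior <- function(x_by_class, test, prior, var_floor = 1e-9) {
  lik <- vapply(seq_along(x_by_class), function(k) {
    mu <- colMeans(x_by_class[[k]])
    v <- pmax(apply(x_by_class[[k]], 2, var), var_floor)
    prod(dnorm(test, mu, sqrt(v)))
  }, numeric(1))
  post <- lik * prior
  post / sum(post)
}

# Mixture p-value vectors (some true signal, p ~ U^strength) for FDR
# procedure comparisons.
random_p_mixture <- function(m, frac_signal = 0.3, strength = 6) {
  n_sig <- round(frac_signal * m)
  p <- runif(m)
  if (n_sig > 0) p[seq_len(n_sig)] <- runif(n_sig)^strength
  sample(p)
}
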