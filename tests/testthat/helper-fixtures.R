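# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Standard synthetic cohort (default study conditions, seed 7).
default_cohort <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- generate_cohort(simulation_config(seed = 7))
  }
  .fixture_env$default
}

# Null cohort: no implanted expression effects, >= 10^4 SNV-gene tests.
null_cohort <- function() {
  if (is.null(.fixture_env$null)) {
    .fixture_env$null <- generate_cohort(simulation_config(
      n_samples = 128, n_genes = 120, n_snvs = 120, n_effects = 0,
      n_bimodal = 0, n_prognostic = 0, seed = 11))
  }
  .fixture_env$null
}

# Brute-force simple OLS via the normal equations (independent oracle).
ols_oracle <- function(y, x, conf_level = 0.95) {
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  b <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% b
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(diag(xtx_inv) * s2)[2]
  tstat <- b[2] / se
  tcrit <- qt(1 - (1 - conf_level) / 2, n - 2)
  list(beta = b[2], se = se,
       ci = c(b[2] - tcrit * se, b[2] + tcrit * se),
       p = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration.
fisher_oracle_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by summation over all outcomes.
hyper_tail_oracle <- function(overlap, n_targets, universe, n_query) {
  support <- overlap:min(n_targets, n_query)
  if (length(support) == 0 || overlap > min(n_targets, n_query)) return(0)
  sum(choose(n_targets, support) * choose(universe - n_targets,
                                          n_query - support)) /
    choose(universe, n_query)
}
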