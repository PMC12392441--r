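# Shared fixtures and independent oracles for the test suite.

# the reference initial distribution: 6380 +/- 400 Da at 44 Da per monomer
ref_spec <- function(m) ensemble_spec(m, 145, 400 / 44)

ref_params <- function(oh_ss = 1e-16) kinetics_params(oh_ss = oh_ss, mn0 = 6380)

# expand a histogram ensemble into one length per individual chain
expand_chains <- function(ensemble) {
  rep(seq_along(ensemble$counts), times = ensemble$counts)
}

# Brute-force per-class selection probabilities: enumerate every individual
# chain, weight it by its rate constant, and sum weights per length class.
brute_force_weights <- function(ensemble, model = rate_model(),
                                eligible_min_length = 2L) {
  lens <- expand_chains(ensemble)
  k <- ifelse(lens >= eligible_min_length,
              chain_rate_constant(lens, model), 0)
  p <- k / sum(k)
  out <- numeric(length(ensemble$counts))
  for (i in seq_along(lens)) out[lens[i]] <- out[lens[i]] + p[i]
  out
}

# Brute-force cumulative mass fraction at a MW point, chain by chain.
brute_force_cum_wt <- function(ensemble, mw) {
  lens <- expand_chains(ensemble)
  mass <- lens * ensemble$mw_monomer
  100 * sum(mass[mass <= mw + 1e-9]) / sum(mass)
}

# Largest-remainder apportionment oracle: direct quota arithmetic over the
# discretized normal density, independent of build_initial_ensemble().
oracle_apportion <- function(m, lambda, sigma) {
  nmax <- max(ceiling(lambda + 8 * max(sigma, 1)), ceiling(lambda) + 1)
  p <- dnorm(seq_len(nmax), lambda, sigma)
  p <- p / sum(p)
  quota <- p * m
  cnt <- floor(quota)
  rem <- m - sum(cnt)
  ord <- order(quota - cnt, -seq_len(nmax), decreasing = TRUE)
  if (rem > 0) cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  cnt
}
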