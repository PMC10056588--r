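# Independent brute-force oracles used across test files. These deliberately
# re-derive quantities with naive loops so they share no code with the
# package internals they check.

# all 2^K binary profiles, attribute 1 in the first column, plain loop version
oracle_profiles <- function(K) {
  as.matrix(expand.grid(rep(list(0:1), K)))[, seq_len(K), drop = FALSE]
}

# naive per-profile probability for the deterministic-input family
oracle_detnoisy_p <- function(alpha, q, g, s, tau) {
  req <- which(q == 1)
  conj <- as.numeric(all(alpha[req] == 1))
  disj <- as.numeric(any(alpha[req] == 1))
  rat <- sum(alpha[req]) / length(req)
  g + (1 - s - g) * (tau[1] * conj + tau[2] * disj + tau[3] * rat)
}

# naive double-loop Bernoulli log-likelihood
oracle_loglik <- function(Y, P_ni) {
  ll <- 0
  for (n in seq_len(nrow(Y))) {
    for (i in seq_len(ncol(Y))) {
      p <- min(max(P_ni[n, i], 1e-12), 1 - 1e-12)
      ll <- ll + if (Y[n, i] == 1) log(p) else log(1 - p)
    }
  }
  ll
}

# a small deterministic DINMix dataset for sampler-level tests
tiny_sim <- function(N = 60, I = 5, K = 2, seed = 11) {
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 1), c(1, 0))
  par <- list(
    dinmix_pars(0.15, 0.1),
    dinmix_pars(0.1, 0.2),
    dinmix_pars(0.1, 0.1, c(0.6, 0.2, 0.2)),
    dinmix_pars(0.2, 0.15, c(0.2, 0.2, 0.6)),
    dinmix_pars(0.1, 0.1)
  )
  ip <- item_params_tbl(rep("DINMIX", I), par)
  alpha <- draw_attributes(N, K, "unstructured", seed = seed)
  Y <- simulate_responses(Q, alpha, ip, seed = seed + 1)
  list(Y = Y, Q = Q, alpha = alpha, item_params = ip)
}
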