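# Shared fixtures, built in code at test time.

# small random binary spike matrix
random_spikes <- function(C, T, p = 0.05, seed = 1, bin_width = 0.005,
                          n_surrogate = 0L) {
  set.seed(seed)
  spike_matrix(matrix(rbinom(C * T, 1, p), C, T), bin_width = bin_width,
               n_surrogate = n_surrogate)
}

# a 3-neuron network with one known connection 1 -> 2, cloglog generator
tiny_net <- function(w = 2.5, baseline = -4.5) {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- w
  network_spec(3L, adj, baselines = rep(baseline, 3),
               private_rates = rep(80, 3), private_coef = 0.5,
               link = "cloglog", sample_rate = 200)
}

# brute-force total response: the defining triple sum
brute_total_response <- function(baseline, ext_coef, loadings, basis, counts,
                                 ext_signals, t) {
  C <- nrow(counts); K <- basis$K; M <- basis$M
  lam <- baseline
  if (length(ext_coef) > 0)
    for (l in seq_along(ext_coef)) lam <- lam + ext_coef[l] * ext_signals[l, t]
  for (c in seq_len(C)) for (k in seq_len(K)) for (s in seq_len(M))
    if (t - s >= 1)
      lam <- lam + loadings[c, k] * basis$values[k, s] * counts[c, t - s]
  lam
}

# pair-counting AUC oracle: P(score+ > score-) + 0.5 P(equal)
auc_pair_count <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# analytic gradient of the penalized L2 objective at beta
analytic_gradient <- function(X, y, beta, eta, pen, link) {
  p <- link_prob(as.numeric(X %*% beta), link)
  as.numeric(crossprod(X, y - p)) - eta * pen * beta
}
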