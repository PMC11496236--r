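# shared fixtures, built in code

## small, well-separated two-class configuration (6 indicators keeps the
## pattern space tiny for closed-form cross-checks)
two_class_config <- function(n = 400L, seed = 1L, delta = rep(0, 6),
                             dropout = "none") {
  E <- rbind(c(0.05, 0.05, 0.10, 0.05, 0.10, 0.05),
             c(0.80, 0.70, 0.60, 0.75, 0.65, 0.70))
  colnames(E) <- lc_indicators()[1:6]
  generator_config(n_individuals = n, n_waves = 2L,
                   pi0 = c(0.7, 0.3),
                   A = rbind(c(0.9, 0.1), c(0.2, 0.8)),
                   emissions = E, baseline_delta = delta,
                   retention = 1, dropout = dropout, seed = seed)
}

## near-deterministic emissions: class k -> indicators 2k-1, 2k fire
degenerate_emissions <- function(K = 3L) {
  E <- matrix(1e-9, K, 2L * K)
  for (k in seq_len(K)) E[k, c(2L * k - 1L, 2L * k)] <- 1 - 1e-9
  colnames(E) <- lc_indicators()[seq_len(2L * K)]
  E
}

## the default study-scale configuration
paper_config <- function(seed = 1L) generator_config(seed = seed)

## empirical transition frequencies from the simulation truth column
truth_transitions <- function(d, K) {
  o <- order(d$person_id, d$wave)
  z <- d$latent_class_truth[o]
  pid <- d$person_id[o]
  same <- pid[-1L] == pid[-length(pid)]
  tab <- table(factor(z[-length(z)][same], seq_len(K)),
               factor(z[-1L][same], seq_len(K)))
  tab / pmax(rowSums(tab), 1)
}
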