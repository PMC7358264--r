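# Shared helpers for the test suite.

# Fast chain settings for tests that only need structural correctness.
quick_mcmc <- function(seed = NULL)
  mcmc_config(n_burnin = 200, n_draws = 600, seed = seed)

# Chain settings used by the simulation-evaluation harness.
eval_mcmc <- function() mcmc_config(n_burnin = 500, n_draws = 2000)

# A small random multi-round history for property-style tests.
random_history <- function(M = 4, T = 3, lambda = 3) {
  recs <- list()
  next_id <- rep(1L, M)
  for (t in seq_len(T)) {
    for (i in seq_len(M)) {
      k <- stats::rpois(1, lambda) + (t == 1 && i == 1)  # keep non-empty
      if (k == 0) next
      recs[[length(recs) + 1L]] <- data.frame(
        site_id = i, patient_id = seq.int(next_id[i], length.out = k),
        round = t, outcome = stats::rnorm(k))
      next_id[i] <- next_id[i] + k
    }
  }
  trial_history(do.call(rbind, recs), n_sites = M, n_rounds = T)
}
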