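# Fixture builders used across the test files. Everything is generated in
# code under fixed seeds.

# A pair of experiment tables where `n_signal` features carry strong
# signal in experiment 1, and optionally the same features carry signal
# in experiment 2 (the overlap alternative). Non-signal experiment-1
# p-values sit in [0.5, 1] so the significant set is exactly the signal
# block.
make_pair <- function(m = 1000L, n_signal = 100L, shared = FALSE,
                      seed = 1L, signal_p = 1e-6) {
  set.seed(seed)
  ids <- sprintf("f%04d", seq_len(m))
  signal <- seq_len(n_signal)
  p1 <- stats::runif(m, 0.5, 1)
  p1[signal] <- 1e-8
  p2 <- stats::runif(m)
  if (shared) p2[signal] <- signal_p
  lfc1 <- stats::rnorm(m)
  lfc2 <- stats::rnorm(m)
  if (shared) lfc2[signal] <- abs(lfc2[signal]) * sign(lfc1[signal])
  list(exp1 = differential_table(ids, p1, lfc = lfc1),
       exp2 = differential_table(ids, p2, lfc = lfc2),
       signal_ids = ids[signal])
}

# Down-scaled simulation configuration for fast module tests.
small_config <- function(seed = 1L, n_reps = 10L) {
  sim_config(m = 2000L, n_diff = 400L, n_shared_12 = 280L,
             n_shared_123 = 200L, n_per_group = 30L,
             n_reps = n_reps, seed = seed)
}

# Literal brute-force q-value oracle: for each feature, the minimum over
# the tail of pi0 * m * p_(j) / j, independent of the implementation.
brute_force_qvalues <- function(p, pi0) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) pi0 * m * ps[j] / j, numeric(1))
    q[ord[i]] <- min(c(cand, 1))
  }
  q
}
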