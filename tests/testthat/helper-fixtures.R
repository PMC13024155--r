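# Standard (geometric-dwell) HMM forward and Viterbi, as an independent
# oracle: with all dwell mass at duration 1 the HSMM reduces to an HMM whose
# transition matrix is the zero-diagonal A.
hmm_forward_loglik <- function(init, A, E) {
  K <- nrow(E); T_ <- ncol(E)
  a <- log(init) + E[, 1L]
  for (t in 2:T_) {
    a <- vapply(seq_len(K), function(k)
      logsumexp(a + log(A[, k])) + E[k, t], numeric(1L))
  }
  logsumexp(a)
}

hmm_viterbi <- function(init, A, E) {
  K <- nrow(E); T_ <- ncol(E)
  v <- log(init) + E[, 1L]
  bp <- matrix(0L, K, T_)
  for (t in 2:T_) {
    nv <- numeric(K)
    for (k in seq_len(K)) {
      sc <- v + log(A[, k])
      bp[k, t] <- which.max(sc)
      nv[k] <- sc[bp[k, t]] + E[k, t]
    }
    v <- nv
  }
  path <- integer(T_)
  path[T_] <- which.max(v)
  for (t in T_:2) path[t - 1L] <- bp[path[t], t]
  list(path = path, log_joint = max(v))
}

# Tiny two-group cohort for pipeline smoke tests: K states, R regions,
# n participants per group, short scans; states well separated.
tiny_cohort <- function(K = 3L, R = 4L, n_per_group = 4L, T = 80L,
                        seed = 1L) {
  base <- generate_params(R, K, separation = 6, seed = seed,
                          dwell_lambda = rep(3, K), max_dwell = 20L,
                          mean_geometry = "simplex")
  truth <- list(params_by_group = list(mindfulness = base, control = base),
                stress_model = list(intercept = 3, slope_per_state = rep(0, K),
                                    noise_sd = 0.5, random_intercept_sd = 0.3))
  generate_cohort(n_group1 = n_per_group, n_group2 = n_per_group,
                  scans_per_participant = 2L, T = T, truth = truth,
                  seed = seed)
}
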