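# Independent oracles, implemented without the package's recursions.

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Log probability of one full label path under the semi-Markov generative
# process: initial draw, dwell pmf for interior segments, transition at each
# switch, survival (right-censoring) for the final segment.
oracle_path_logprob <- function(params, labels) {
  pm <- dwell_pmf(params)
  surv <- t(apply(pm, 1L, function(r) rev(cumsum(rev(r)))))
  r <- rle(labels)
  n <- length(r$values)
  D <- ncol(pm)
  lp <- log(params$init[r$values[1L]])
  for (i in seq_len(n)) {
    s <- r$values[i]
    d <- r$lengths[i]
    if (d > D) return(-Inf)
    if (i < n) {
      lp <- lp + log(pm[s, d]) + log(params$trans[s, r$values[i + 1L]])
    } else {
      lp <- lp + log(surv[s, d])
    }
  }
  lp
}

# Exhaustive marginal log-likelihood and best path by enumerating all K^T
# label paths (only feasible for tiny K and T).
oracle_enumerate <- function(params, Y) {
  K <- params$K
  T_ <- nrow(Y)
  E <- statedyn:::log_emission_matrix(params, Y)
  grid <- expand.grid(rep(list(seq_len(K)), T_))
  lps <- apply(as.matrix(grid), 1L, function(labels) {
    lp <- oracle_path_logprob(params, as.integer(labels))
    if (!is.finite(lp)) return(-Inf)
    lp + sum(E[cbind(labels, seq_len(T_))])
  })
  best <- which.max(lps)
  list(loglik = logsumexp(lps),
       best_path = as.integer(grid[best, ]),
       best_logjoint = lps[best])
}

# Textbook Benjamini-Hochberg step-up: largest i with p_(i) <= i * alpha / m.
oracle_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  rejected <- logical(m)
  if (length(ok)) rejected[o[seq_len(max(ok))]] <- TRUE
  rejected
}

# Exhaustive maximum modularity over all set partitions of n nodes.
oracle_partitions <- function(n) {
  parts <- list(list(1L))
  if (n >= 2L) for (i in 2L:n) {
    new <- list()
    for (p in parts) {
      for (j in seq_along(p)) {
        q <- p
        q[[j]] <- c(q[[j]], i)
        new[[length(new) + 1L]] <- q
      }
      new[[length(new) + 1L]] <- c(p, list(i))
    }
    parts <- new
  }
  parts
}

oracle_max_modularity <- function(adj, gamma = 1) {
  n <- nrow(adj)
  best <- -Inf
  best_part <- NULL
  for (p in oracle_partitions(n)) {
    memb <- integer(n)
    for (j in seq_along(p)) memb[p[[j]]] <- j
    q <- modularity_score(adj, memb, gamma)
    if (q > best) { best <- q; best_part <- memb }
  }
  list(Q = best, membership = best_part)
}

# Random small HSMM parameter set for oracle comparisons.
random_tiny_params <- function(K = 2L, R = 2L, max_dwell = 5L, seed = 1L) {
  set.seed(seed)
  mu <- matrix(rnorm(K * R, sd = 2), K, R)
  sigma <- lapply(seq_len(K), function(k) {
    A <- matrix(rnorm(R * R), R, R)
    crossprod(A) / R + diag(0.5, R)
  })
  if (K >= 2L) {
    trans <- matrix(runif(K * K), K, K)
    diag(trans) <- 0
    trans <- trans / rowSums(trans)
  } else trans <- matrix(0, 1, 1)
  init <- runif(K)
  init <- init / sum(init)
  pmf <- matrix(runif(K * max_dwell), K, max_dwell)
  pmf <- pmf / rowSums(pmf)
  hsmm_params(mu = mu, sigma = sigma, trans = trans, init = init,
              dwell = list(family = "nonparametric", pmf = pmf),
              max_dwell = max_dwell)
}

# Greedy matching of fitted states to true states by mean distance.
match_states <- function(mu_fit, mu_true) {
  K <- nrow(mu_true)
  d <- as.matrix(stats::dist(rbind(mu_fit, mu_true)))[seq_len(K),
                                                      K + seq_len(K)]
  perm <- integer(K)   # perm[true] = fitted
  used <- logical(K)
  ord <- order(apply(d, 2L, min))
  for (j in ord) {
    cand <- order(d[, j])
    cand <- cand[!used[cand]][1L]
    perm[j] <- cand
    used[cand] <- TRUE
  }
  perm
}
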