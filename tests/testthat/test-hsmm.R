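test_that("single-state model reduces to iid Gaussian log-likelihood", {
  p <- generate_params(R = 3, K = 1, separation = 1, seed = 1)
  set.seed(5)
  Y <- matrix(rnorm(60), 20, 3)
  E <- statedyn:::log_emission_matrix(p, Y)
  expect_equal(hsmm_loglik(p, Y), sum(E))
  v <- viterbi_decode(p, Y)
  expect_equal(v$labels, rep(1L, 20))
})

test_that("marginal likelihood and Viterbi match exhaustive enumeration", {
  for (s in 1:12) {
    p <- random_tiny_params(K = 2, R = 2, max_dwell = 5, seed = s)
    set.seed(900 + s)
    Y <- matrix(rnorm(10, sd = 2), 5, 2)
    o <- oracle_enumerate(p, Y)
    expect_equal(hsmm_loglik(p, Y), o$loglik, tolerance = 1e-8)
    v <- viterbi_decode(p, Y)
    expect_equal(v$labels, o$best_path)
    expect_equal(v$log_joint, o$best_logjoint, tolerance = 1e-8)
  }
})

test_that("rescaling data and parameters shifts loglik by the Jacobian", {
  p <- random_tiny_params(K = 2, R = 3, max_dwell = 6, seed = 3)
  set.seed(33)
  Y <- matrix(rnorm(24), 8, 3)
  c0 <- 2.5
  p2 <- p
  p2$mu <- p$mu * c0
  p2$sigma <- lapply(p$sigma, function(s) s * c0^2)
  # Y' = c Y  =>  log p'(Y') = log p(Y) - T * R * log(c)
  expect_equal(hsmm_loglik(p2, Y * c0),
               hsmm_loglik(p, Y) - 8 * 3 * log(c0), tolerance = 1e-8)
})

test_that("forward-backward posteriors are proper and consistent", {
  p <- random_tiny_params(K = 3, R = 2, max_dwell = 8, seed = 4)
  set.seed(44)
  Y <- matrix(rnorm(60, sd = 2), 30, 2)
  fb <- forward_backward(p, Y)
  expect_equal(colSums(fb$gamma), rep(1, 30), tolerance = 1e-10)
  expect_equal(fb$loglik, hsmm_loglik(p, Y), tolerance = 1e-10)
  expect_equal(sum(fb$init_post), 1, tolerance = 1e-8)
  # expected transitions equal expected interior segment count
  expect_equal(sum(fb$trans_counts),
               sum(fb$dwell_counts), tolerance = 1e-8)
  # decoded joint probability never exceeds the marginal
  v <- viterbi_decode(p, Y)
  expect_lte(v$log_joint, fb$loglik + 1e-10)
})

test_that("decoding is equivariant under state relabeling", {
  p <- random_tiny_params(K = 3, R = 2, max_dwell = 6, seed = 6)
  set.seed(66)
  Y <- matrix(rnorm(50, sd = 2), 25, 2)
  perm <- c(3L, 1L, 2L)   # new index of old state k is perm[k]
  q <- p
  inv <- order(perm)
  q$mu <- p$mu[inv, ]
  q$sigma <- p$sigma[inv]
  q$trans <- p$trans[inv, inv]
  q$init <- p$init[inv]
  q$dwell$pmf <- p$dwell$pmf[inv, ]
  v1 <- viterbi_decode(p, Y)
  v2 <- viterbi_decode(q, Y)
  expect_equal(perm[v1$labels], v2$labels)
  expect_equal(v1$log_joint, v2$log_joint, tolerance = 1e-10)
})

test_that("unit dwells with a full transition matrix reproduce a plain HMM", {
  K <- 3
  set.seed(77)
  p <- random_tiny_params(K = K, R = 2, max_dwell = 4, seed = 7)
  pmf <- matrix(0, K, 4)
  pmf[, 1] <- 1
  p$dwell <- list(family = "nonparametric", pmf = pmf)
  Y <- matrix(rnorm(40, sd = 2), 20, 2)
  E <- statedyn:::log_emission_matrix(p, Y)
  expect_equal(hsmm_loglik(p, Y),
               hmm_forward_loglik(p$init, p$trans, E), tolerance = 1e-8)
  hv <- hmm_viterbi(p$init, p$trans, E)
  v <- viterbi_decode(p, Y)
  expect_equal(v$labels, hv$path)
  expect_equal(v$log_joint, hv$log_joint, tolerance = 1e-8)
})

test_that("initialization recovers well-separated cluster structure", {
  set.seed(88)
  cloudA <- matrix(rnorm(200, mean = 0, sd = 0.3), 100, 2)
  cloudB <- matrix(rnorm(200, mean = 5, sd = 0.3), 100, 2)
  p <- init_params(list(rbind(cloudA, cloudB)), K = 2, seed = 1)
  mu <- p$mu[order(p$mu[, 1]), ]
  expect_equal(mu[1, ], colMeans(cloudA), tolerance = 0.2, ignore_attr = TRUE)
  expect_equal(mu[2, ], colMeans(cloudB), tolerance = 0.2, ignore_attr = TRUE)

  p1 <- init_params(list(cloudA), K = 1, seed = 1)
  expect_equal(p1$mu[1, ], colMeans(cloudA), ignore_attr = TRUE)
  expect_equal(p1$sigma[[1]], cov(cloudA), tolerance = 1e-4,
               ignore_attr = TRUE)

  pa <- init_params(list(rbind(cloudA, cloudB)), K = 2, seed = 9)
  pb <- init_params(list(rbind(cloudA, cloudB)), K = 2, seed = 9)
  expect_identical(pa$mu, pb$mu)
})

test_that("EM increases the log-likelihood monotonically", {
  co <- tiny_cohort(K = 2, R = 3, n_per_group = 2, T = 60, seed = 13)
  cfg <- run_config(max_dwell = 20, n_starts = 1, max_iter = 25, seed = 13)
  fit <- em_fit(co$scans, 2, config = cfg)
  expect_true(all(diff(fit$loglik_trace) >=
                    -1e-6 * abs(fit$loglik_trace[-1])))
  # nonparametric dwell family also fits
  fitnp <- em_fit(co$scans, 2, config = run_config(max_dwell = 20,
                                                   n_starts = 1,
                                                   max_iter = 10, seed = 13),
                  dwell_family = "nonparametric")
  expect_s3_class(fitnp, "hsmm_fit")
  expect_equal(rowSums(dwell_pmf(fitnp$params)), rep(1, 2), tolerance = 1e-8)
})

test_that("K = 1 EM reproduces the pooled sample moments in one step", {
  set.seed(99)
  Y <- matrix(rnorm(300), 100, 3)
  fit <- em_fit(list(Y), 1, config = run_config(n_starts = 1, max_iter = 2,
                                                seed = 1))
  expect_equal(fit$params$mu[1, ], colMeans(Y), tolerance = 1e-6,
               ignore_attr = TRUE)
  n <- nrow(Y)
  expect_equal(fit$params$sigma[[1]], cov(Y) * (n - 1) / n, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("noiseless observations decode to the generating path", {
  p <- generate_params(R = 3, K = 3, separation = 8, seed = 15,
                       dwell_lambda = c(3, 4, 5), max_dwell = 20,
                       mean_geometry = "simplex")
  path <- sample_path(p, 120, seed = 16)
  p0 <- p
  p0$sigma <- lapply(p0$sigma, function(s) diag(1e-6, 3))
  Y <- sample_observations(p0, path, seed = 17)
  v <- viterbi_decode(p, Y)
  expect_equal(v$labels, path$labels)
})
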