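test_that("generated parameters satisfy their postconditions", {
  for (seed in 1:3) {
    p <- generate_params(R = 36, K = 6, separation = 2, seed = seed)
    expect_equal(nrow(p$mu), 6L)
    expect_equal(ncol(p$mu), 36L)
    expect_gte(min(dist(p$mu)), 2)
    for (k in 1:6) {
      ev <- eigen(p$sigma[[k]], symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
    expect_equal(diag(p$trans), rep(0, 6))
    expect_equal(rowSums(p$trans), rep(1, 6))
    expect_true(all(dwell_mean(p) >= 3))
  }
  p3 <- generate_params(R = 4, K = 3, separation = 1.5, seed = 9)
  expect_gte(min(dist(p3$mu)), 1.5)

  k1 <- generate_params(R = 3, K = 1, separation = 1, seed = 2)
  expect_equal(k1$trans, matrix(0, 1, 1))
  expect_equal(k1$init, 1)

  # simplex geometry: all pairwise distances equal to separation
  ps <- generate_params(R = 6, K = 3, separation = 5, seed = 4,
                        mean_geometry = "simplex")
  expect_equal(as.numeric(dist(ps$mu)), rep(5, 3), tolerance = 1e-10)
})

test_that("semi-Markov path sampling respects forced structures", {
  p1 <- generate_params(R = 2, K = 1, separation = 1, seed = 1)
  expect_equal(sample_path(p1, 50, seed = 1)$labels, rep(1L, 50))

  # all dwell mass at 5, deterministic alternation -> blocks of exactly 5
  pmf <- matrix(0, 2, 10)
  pmf[, 5] <- 1
  p2 <- hsmm_params(mu = matrix(0, 2, 2),
                    sigma = list(diag(2), diag(2)),
                    trans = matrix(c(0, 1, 1, 0), 2, 2),
                    init = c(1, 0),
                    dwell = list(family = "nonparametric", pmf = pmf),
                    max_dwell = 10)
  path <- sample_path(p2, 23, seed = 5)$labels
  expect_equal(path[1:20], rep(rep(1:2, 2), each = 5))
  expect_equal(path[21:23], rep(1L, 3))  # final dwell truncated at T
})

test_that("sampled dwell lengths follow the specified distribution", {
  p <- generate_params(R = 2, K = 2, separation = 3, seed = 11,
                       dwell_lambda = c(3, 6), max_dwell = 40)
  long <- sample_path(p, 1e5, seed = 12)
  dw <- dwell_times(long, 2, exclude_edges = TRUE)
  pm <- dwell_pmf(p)
  for (k in 1:2) {
    obs <- tabulate(dw[[k]], nbins = 40)
    expe <- sum(obs) * pm[k, ]
    keep <- expe >= 5
    chi <- sum((obs[keep] - expe[keep])^2 / expe[keep])
    pval <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
    expect_gt(pval, 0.01)
  }
})

test_that("observations match state emission moments", {
  p <- generate_params(R = 3, K = 2, separation = 4, seed = 21)
  n <- 1e4
  path <- rep(1:2, each = n)
  Y <- sample_observations(p, path, seed = 22)
  for (k in 1:2) {
    Yk <- Y[path == k, ]
    se <- sqrt(diag(p$sigma[[k]]) / n)
    expect_true(all(abs(colMeans(Yk) - p$mu[k, ]) < 3.5 * se))
    # covariance converges in Frobenius norm
    err_n <- norm(cov(Yk) - p$sigma[[k]], "F")
    err_small <- norm(cov(Yk[1:200, ]) - p$sigma[[k]], "F")
    expect_lt(err_n, err_small)
    expect_lt(err_n, 0.1 * norm(p$sigma[[k]], "F"))
  }
  # noiseless limit: rows collapse onto the state means
  p0 <- p
  p0$sigma <- lapply(p0$sigma, function(s) diag(1e-12, 3))
  Y0 <- sample_observations(p0, c(1L, 2L), seed = 23)
  expect_equal(Y0, p$mu, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("cohort generation is reproducible and respects the design", {
  co <- generate_cohort(n_group1 = 2, n_group2 = 3, scans_per_participant = 2,
                        T = 60, truth = NULL, seed = 42)
  expect_equal(length(co$scans), 10L)
  expect_equal(nrow(co$manifest), 10L)
  expect_equal(sum(co$manifest$group == "mindfulness"), 4L)
  expect_true(all(vapply(co$truth$true_paths, function(p)
    length(p$labels), 1L) == 60L))
  expect_true(all(co$manifest$stress_score >= 1 &
                    co$manifest$stress_score <= 10))

  co2 <- generate_cohort(n_group1 = 2, n_group2 = 3,
                         scans_per_participant = 2, T = 60, truth = NULL,
                         seed = 42)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(lapply(co$scans, `[[`, "matrix"),
                   lapply(co2$scans, `[[`, "matrix"))

  mini <- generate_cohort(1, 1, 1, T = 30, truth = NULL, seed = 7)
  expect_equal(length(mini$scans), 2L)
  expect_equal(sort(unique(mini$manifest$group)), c("control", "mindfulness"))
})

test_that("long-run occupancy matches the semi-Markov stationary law", {
  p <- generate_params(R = 2, K = 3, separation = 2, seed = 31,
                       dwell_lambda = c(2, 4, 7), max_dwell = 40)
  # closed form: occupancy_k proportional to pi_tilde_k * E[dwell_k],
  # pi_tilde the stationary law of the embedded jump chain
  ev <- eigen(t(p$trans))
  pi_t <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_t <- pi_t / sum(pi_t)
  occ_theory <- pi_t * dwell_mean(p)
  occ_theory <- 100 * occ_theory / sum(occ_theory)
  long <- sample_path(p, 2e5, seed = 32)
  occ_emp <- occupancy_time(long, 3)
  expect_equal(occ_emp, occ_theory, tolerance = 0.02)
})

test_that("raising one state's dwell raises that group's occupancy of it", {
  occ_for_lambda <- function(lam1) {
    p <- generate_params(R = 2, K = 3, separation = 2, seed = 51,
                         dwell_lambda = c(lam1, 4, 4), max_dwell = 40)
    mean(vapply(1:30, function(i)
      occupancy_time(sample_path(p, 500, seed = 100 + i), 3)[1], numeric(1)))
  }
  occs <- vapply(c(2, 5, 9), occ_for_lambda, numeric(1))
  expect_true(all(diff(occs) > 0))
})

test_that("stress scores follow the occupancy coupling", {
  sm0 <- list(intercept = 4, slope_per_state = c(0, 0), noise_sd = 0,
              random_intercept_sd = 0)
  occ <- matrix(c(30, 70, 50, 50), 2, 2, byrow = TRUE)
  s <- generate_stress(sm0, occ, c("a", "b"), seed = 1)
  expect_equal(as.numeric(s), c(4, 4))

  sm1 <- list(intercept = 8, slope_per_state = c(-0.05, 0), noise_sd = 0,
              random_intercept_sd = 0)
  occ2 <- cbind(seq(10, 90, by = 20), 0)
  s2 <- generate_stress(sm1, occ2, letters[1:5], seed = 1)
  expect_true(all(diff(as.numeric(s2)) < 0))

  # clipping to the 1-10 instrument range
  sm2 <- list(intercept = 12, slope_per_state = c(0, 0), noise_sd = 0,
              random_intercept_sd = 0)
  expect_message(s3 <- generate_stress(sm2, occ, c("a", "b"), seed = 1),
                 "clipped")
  expect_equal(as.numeric(s3), c(10, 10))
})
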