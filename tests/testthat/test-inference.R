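test_that("mean-difference permutation test handles degenerate and extreme inputs", {
  r0 <- permutation_test_mean_diff(rep(5, 8), rep(c("a", "b"), each = 4),
                                   n_perm = 99, seed = 1)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p_value, 1)

  # 3 vs 3 with complete separation: exactly 2 of the 20 label assignments
  # reproduce |diff| = 10, so the add-one p concentrates near 0.1
  r1 <- permutation_test_mean_diff(c(0, 0, 0, 10, 10, 10),
                                   c("a", "a", "a", "b", "b", "b"),
                                   n_perm = 500, seed = 2)
  expect_equal(abs(r1$observed), 10)
  exact_exceed <- mean(apply(combn(6, 3), 2, function(idx) {
    v <- c(0, 0, 0, 10, 10, 10)
    abs(mean(v[idx]) - mean(v[-idx])) >= 10
  }))
  expect_equal(exact_exceed, 2 / 20)
  expect_gt(r1$p_value, 0.05)
  expect_lt(r1$p_value, 0.16)
  binom_ci <- qbinom(c(0.0005, 0.9995), 500, exact_exceed)
  expect_gte(r1$p_value, (1 + binom_ci[1]) / 501)
  expect_lte(r1$p_value, (1 + binom_ci[2]) / 501)

  expect_error(permutation_test_mean_diff(1:4, rep("a", 4), 10, 1),
               "two groups")
  expect_error(permutation_test_mean_diff(1:4, c("a", "a", "b", "b"), 0, 1),
               "n_perm")
})

test_that("KL divergence matches its definition and the Gaussian closed form", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(kl_divergence(p, p), 0)
  set.seed(5)
  for (i in 1:20) {
    a <- runif(10); a <- a / sum(a)
    b <- runif(10); b <- b / sum(b)
    expect_gte(kl_divergence(a, b), 0)
  }
  # discretized Gaussians vs closed form KL = (mu1-mu2)^2 / (2 sigma^2)
  grid <- seq(-12, 13, by = 0.01)
  p1 <- dnorm(grid, 0, 1); p1 <- p1 / sum(p1)
  p2 <- dnorm(grid, 1, 1); p2 <- p2 / sum(p2)
  expect_equal(kl_divergence(p1, p2), 0.5, tolerance = 1e-3)
  expect_error(kl_divergence(p, c(0.5, 0.5)), "grid")
})

test_that("dwell KL permutation test separates distinct dwell regimes", {
  same <- c(rep(list(c(3L, 4L, 5L)), 4), rep(list(c(3L, 4L, 5L)), 4))
  g <- rep(c("mindfulness", "control"), each = 4)
  r0 <- permutation_test_dwell_kl(same, g, n_perm = 99, seed = 3,
                                  max_dwell = 30)
  expect_equal(r0$observed, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)

  short <- lapply(1:10, function(i) sample(2:3, 6, replace = TRUE))
  long <- lapply(1:10, function(i) sample(c(20L, 30L), 6, replace = TRUE))
  r1 <- permutation_test_dwell_kl(c(short, long),
                                  rep(c("mindfulness", "control"), each = 10),
                                  n_perm = 500, seed = 4, max_dwell = 40)
  expect_lte(r1$p_value, 0.01)

  # the symmetrized statistic ignores which group is labeled first
  r2 <- permutation_test_dwell_kl(c(long, short),
                                  rep(c("mindfulness", "control"), each = 10),
                                  n_perm = 10, seed = 5, max_dwell = 40)
  expect_equal(r2$observed, r1$observed, tolerance = 1e-12)
})

test_that("participant-level permutation keeps scan pairs together", {
  co <- tiny_cohort(K = 2, R = 3, n_per_group = 5, T = 60, seed = 23)
  sm <- summarize_dynamics(co$truth$true_paths, co$manifest, 2)
  agg <- aggregate(occupancy_pct ~ participant_id + group,
                   data = sm$table[sm$table$state == 1, ], FUN = mean)
  # one value per participant enters the test: structural guarantee that
  # permutation operates on participants, not scans
  expect_equal(nrow(agg), 10L)
  r <- permutation_test_mean_diff(agg$occupancy_pct, agg$group,
                                  n_perm = 199, seed = 6)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  expect_equal(length(r$null_samples), 199L)
})

test_that("Benjamini-Hochberg matches the step-up definition", {
  fc <- fdr_correct(rep(0.001, 6), 0.05)
  expect_true(all(fc$rejected))

  fc1 <- fdr_correct(0.04, 0.05)
  expect_equal(fc1$q_values, 0.04)
  expect_true(fc1$rejected)

  p <- c(0.01, 0.02, 0.03, 0.20, 0.50, 0.90)
  fc2 <- fdr_correct(p, 0.05)
  expect_equal(fc2$rejected, oracle_bh(p, 0.05))
  expect_true(all(fc2$q_values >= p))

  set.seed(31)
  for (i in 1:25) {
    ps <- runif(sample(3:12, 1))^2
    fci <- fdr_correct(ps, 0.05)
    expect_equal(fci$rejected, oracle_bh(ps, 0.05))
  }
  expect_equal(fdr_correct(numeric(0), 0.05)$q_values, numeric(0))
})

test_that("two-state occupancy tests are reflections of each other", {
  co <- tiny_cohort(K = 2, R = 3, n_per_group = 4, T = 80, seed = 29)
  sm <- summarize_dynamics(co$truth$true_paths, co$manifest, 2)
  cfg <- run_config(n_permutations = 199, seed = 7, max_dwell = 20)
  tests <- group_tests(sm, 2, config = cfg)
  occ <- tests[tests$property == "occupancy", ]
  expect_equal(occ$p_value[1], occ$p_value[2])
  expect_equal(occ$observed[1], -occ$observed[2], tolerance = 1e-9)
})
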