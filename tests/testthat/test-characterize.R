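two_cliques <- function(w_bridge = 1) {
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1
  adj[5:8, 5:8] <- 1
  diag(adj) <- 0
  adj[4, 5] <- adj[5, 4] <- w_bridge
  adj
}

test_that("covariance converts to correlation by the defining formula", {
  expect_equal(cov_to_corr(diag(3)), diag(3))
  cr <- cov_to_corr(matrix(c(4, 2, 2, 9), 2, 2))
  expect_equal(cr[1, 2], 2 / 6)
  set.seed(3)
  for (i in 1:10) {
    A <- matrix(rnorm(25), 5, 5)
    S <- crossprod(A) + diag(0.1, 5)
    cr <- cov_to_corr(S)
    expect_equal(diag(cr), rep(1, 5))
    expect_equal(cr, t(cr))
    expect_true(all(abs(cr) <= 1 + 1e-12))
    # correlation ignores per-region variance rescaling
    d <- diag(runif(5, 0.2, 3))
    expect_equal(cov_to_corr(d %*% S %*% d), cr, tolerance = 1e-12)
  }
  expect_error(cov_to_corr(matrix(c(0, 0, 0, 1), 2, 2)), "positive")
})

test_that("positive network zeroes negative edges and the diagonal", {
  cr <- matrix(c(1, 0.5, -0.3, 0.5, 1, 0.2, -0.3, 0.2, 1), 3, 3)
  adj <- positive_network(cr)
  expect_equal(diag(adj), rep(0, 3))
  expect_equal(adj[1, 3], 0)
  expect_equal(adj[1, 2], 0.5)
  expect_equal(positive_network(adj + diag(3)), adj)  # idempotent
  expect_equal(positive_network(-abs(cr) + 2 * diag(3))[lower.tri(cr)],
               rep(0, 3))
})

test_that("spectral partition recovers canonical modular structure", {
  part <- newman_partition(two_cliques(), gamma = 1)
  expect_equal(length(unique(part$modules)), 2L)
  expect_equal(part$modules[1:4], rep(part$modules[1], 4))
  expect_equal(part$modules[5:8], rep(part$modules[5], 4))

  # trivial one-community partition has Q = 0 at gamma 1
  expect_equal(modularity_score(two_cliques(), rep(1L, 8), 1), 0)

  expect_error(newman_partition(matrix(0, 3, 3)), "empty network")
})

test_that("spectral Q never exceeds the exhaustive partition maximum", {
  # exact agreement on the two-clique family
  o <- oracle_max_modularity(two_cliques(), 1)
  p <- newman_partition(two_cliques(), 1)
  expect_equal(p$Q, o$Q, tolerance = 1e-9)

  set.seed(41)
  for (i in 1:6) {
    n <- sample(5:7, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) *
      rbinom(n * (n - 1) / 2, 1, 0.6)
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    sp <- newman_partition(adj, 1)
    ex <- oracle_max_modularity(adj, 1)
    expect_lte(sp$Q, ex$Q + 1e-9)
  }
})

test_that("modularity is invariant to relabeling and edge-weight scale", {
  adj <- two_cliques(0.5)
  memb <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)
  relab <- c(7L, 7L, 7L, 7L, 3L, 3L, 3L, 3L)
  expect_equal(modularity_score(adj, memb, 1),
               modularity_score(adj, relab, 1))
  expect_equal(modularity_score(adj * 4.2, memb, 1),
               modularity_score(adj, memb, 1), tolerance = 1e-12)
})

test_that("disconnected components are never merged at gamma 1", {
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1
  adj[4:6, 4:6] <- 1
  diag(adj) <- 0
  part <- newman_partition(adj, 1)
  expect_true(all(part$modules[1:3] == part$modules[1]))
  expect_true(all(part$modules[4:6] == part$modules[4]))
  expect_true(part$modules[1] != part$modules[4])
})

test_that("spectral Q agrees with igraph on weighted graphs", {
  skip_if_not_installed("igraph")
  set.seed(51)
  adj <- two_cliques(0.8)
  part <- newman_partition(adj, 1)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  qi <- igraph::modularity(g, part$modules,
                           weights = igraph::E(g)$weight)
  expect_equal(part$Q, qi, tolerance = 1e-10)
})

test_that("activity maps z-score each region across states", {
  p <- generate_params(R = 5, K = 4, separation = 3, seed = 61)
  z <- activity_map(p)
  expect_equal(colMeans(z), rep(0, 5), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(apply(z, 2, sd), rep(1, 5), tolerance = 1e-10,
               ignore_attr = TRUE)

  # constant region: z collapses to 0 rather than dividing by zero
  p$mu[, 2] <- 7
  expect_message(z2 <- activity_map(p), "constant")
  expect_equal(z2[, 2], rep(0, 4), ignore_attr = TRUE)

  # K = 2: equal magnitude, opposite sign per region
  p2 <- generate_params(R = 4, K = 2, separation = 3, seed = 62)
  z3 <- activity_map(p2)
  expect_equal(z3[1, ], -z3[2, ], ignore_attr = TRUE)

  expect_error(activity_map(generate_params(R = 4, K = 1, separation = 1,
                                            seed = 1)), "K >= 2")
})

test_that("full state characterization is assembled per state", {
  p <- generate_params(R = 6, K = 3, separation = 3, seed = 71)
  ch <- characterize_states(p, gamma = 1)
  expect_length(ch$networks, 3L)
  for (nw in ch$networks) {
    expect_equal(diag(nw$corr), rep(1, 6))
    expect_true(all(nw$positive_adj >= 0))
    expect_equal(length(nw$modules), 6L)
  }
  expect_equal(dim(ch$zmap), c(3L, 6L))
})
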