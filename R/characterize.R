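#' Covariance to correlation
#'
#' `corr[i, j] = sigma[i, j] / sqrt(sigma[i, i] * sigma[j, j])`. The
#' correlation matrix is the weighted network representation of a state.
#'
#' @param sigma symmetric covariance matrix with strictly positive diagonal.
#' @return correlation matrix with unit diagonal.
#' @export
cov_to_corr <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (any(diag(sigma) <= 0)) stop("covariance diagonal must be positive")
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8)))
    stop("covariance must be symmetric")
  cr <- stats::cov2cor(sigma)
  diag(cr) <- 1
  cr
}

#' Positive network of a correlation matrix
#'
#' Keeps positive off-diagonal correlations as edge weights; negative entries
#' and the diagonal are set to zero.
#'
#' @param corr correlation matrix.
#' @return nonnegative weighted adjacency matrix, zero diagonal.
#' @export
positive_network <- function(corr) {
  adj <- pmax(as.matrix(corr), 0)
  diag(adj) <- 0
  adj
}

#' Newman spectral community detection with resolution
#'
#' Recursive leading-eigenvector bisection of the resolution-scaled
#' modularity matrix `B = A - gamma * k k' / 2m`, with deterministic
#' Kernighan-Lin-style fine tuning of each split (single vertices are moved
#' greedily while the bisection improves). Recursion stops when no split
#' increases modularity. Weighted modularity is
#' `Q = (1/2m) * sum_ij (A_ij - gamma * k_i k_j / 2m) * delta(c_i, c_j)`.
#'
#' @param adj symmetric nonnegative weighted adjacency, zero diagonal,
#'   positive total weight.
#' @param gamma resolution parameter (1 = standard null model).
#' @return list with `modules` (integer community labels) and `Q`.
#' @export
newman_partition <- function(adj, gamma = 1) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  if (any(abs(adj - t(adj)) > 1e-10)) stop("adjacency must be symmetric")
  if (any(adj < 0)) stop("adjacency must be nonnegative")
  m2 <- sum(adj)
  if (m2 <= 0) stop("empty network")
  deg <- rowSums(adj)
  B <- adj - gamma * tcrossprod(deg) / m2

  membership <- rep(1L, n)
  queue <- list(seq_len(n))
  next_label <- 2L
  while (length(queue)) {
    idx <- queue[[1L]]
    queue <- queue[-1L]
    if (length(idx) < 2L) next
    Bg <- B[idx, idx, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)  # generalized modularity matrix
    es <- eigen(Bg, symmetric = TRUE)
    if (es$values[1L] <= 1e-10) next
    v <- es$vectors[, 1L]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1L]] < 0) v <- -v  # deterministic sign
    s <- ifelse(v >= 0, 1, -1)
    # fine-tuning: greedily flip single vertices while dQ improves
    repeat {
      gains <- -4 * s * (Bg %*% s) + 4 * diag(Bg)
      best <- which.max(gains)
      if (gains[best] <= 1e-12) break
      s[best] <- -s[best]
      if (all(s == s[1L])) { s[best] <- -s[best]; break }
    }
    dQ <- as.numeric(t(s) %*% Bg %*% s) / (2 * m2)
    if (dQ <= 1e-12 || all(s == s[1L])) next
    grp2 <- idx[s < 0]
    grp1 <- idx[s > 0]
    membership[grp2] <- next_label
    next_label <- next_label + 1L
    queue <- c(queue, list(grp1), list(grp2))
  }
  membership <- as.integer(factor(membership,
                                  levels = unique(membership)))
  list(modules = membership, Q = modularity_score(adj, membership, gamma))
}

#' Weighted modularity of a partition
#'
#' @param adj symmetric nonnegative weighted adjacency, zero diagonal.
#' @param membership integer community labels.
#' @param gamma resolution parameter.
#' @return scalar Q.
#' @export
modularity_score <- function(adj, membership, gamma = 1) {
  m2 <- sum(adj)
  deg <- rowSums(adj)
  same <- outer(membership, membership, "==")
  sum((adj - gamma * tcrossprod(deg) / m2) * same) / m2
}

#' Cross-state activity map
#'
#' For each region, z-scores its K state means across states, so a state's
#' entry says how active the region is in that state relative to the other
#' states (mean 0, sample SD 1 per region). Regions with identical means in
#' all states get z = 0 via an SD floor.
#'
#' @param params an [hsmm_params()] object with `K >= 2`.
#' @param sd_floor lower bound on the cross-state SD.
#' @return K x R matrix of z-scores.
#' @export
activity_map <- function(params, sd_floor = 1e-12) {
  if (params$K < 2L) stop("activity_map requires K >= 2 (cross-state SD undefined)")
  mu <- params$mu
  ctr <- sweep(mu, 2L, colMeans(mu), "-")
  sds <- apply(mu, 2L, stats::sd)
  flat <- sds < sd_floor
  if (any(flat))
    message(sum(flat), " region(s) have constant mean across states; z set to 0")
  sds[flat] <- Inf
  zmap <- sweep(ctr, 2L, sds, "/")
  dimnames(zmap) <- list(paste0("state", seq_len(params$K)),
                         params$region_names %||% paste0("R", seq_len(params$R)))
  zmap
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Characterize every fitted state as a network
#'
#' Converts each state's covariance to a correlation matrix, extracts the
#' positive network, runs Newman spectral community detection at the
#' configured resolution, and computes the cross-state activity map.
#'
#' @param params an [hsmm_params()] object.
#' @param gamma resolution parameter.
#' @return list of class `state_characterization` with `networks` (per state:
#'   `corr`, `positive_adj`, `modules`, `Q`), `zmap`, `gamma`.
#' @export
characterize_states <- function(params, gamma = 1) {
  networks <- lapply(seq_len(params$K), function(k) {
    corr <- cov_to_corr(params$sigma[[k]])
    adj <- positive_network(corr)
    part <- newman_partition(adj, gamma = gamma)
    list(state = k, corr = corr, positive_adj = adj,
         modules = part$modules, Q = part$Q)
  })
  structure(list(networks = networks,
                 zmap = if (params$K >= 2L) activity_map(params) else NULL,
                 gamma = gamma),
            class = "state_characterization")
}

#' @export
print.state_characterization <- function(x, ...) {
  cat(sprintf("State characterization (gamma = %g):\n", x$gamma))
  for (nw in x$networks)
    cat(sprintf("  state %d: %d modules, Q = %.4f\n", nw$state,
                length(unique(nw$modules)), nw$Q))
  invisible(x)
}
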