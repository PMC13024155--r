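#' HSMM parameter set
#'
#' Container for all parameters of an explicit-duration hidden semi-Markov
#' model with multivariate Gaussian emissions: state mean activity vectors,
#' state covariance matrices, the transition matrix over *distinct* next
#' states (zero diagonal — a semi-Markov chain never self-transitions), the
#' dwell-time distribution of each state, and the initial state probabilities.
#'
#' Dwell-time distributions live on the positive integers and are truncated at
#' `max_dwell` (the pmf is renormalized over `1..max_dwell`). Two families are
#' supported: `"shifted_poisson"` (`d - 1 ~ Poisson(lambda)`, guaranteeing
#' `d >= 1`) and `"nonparametric"` (an arbitrary pmf on `1..max_dwell`).
#'
#' @param mu K x R matrix of state means (states in rows).
#' @param sigma list of K symmetric positive-definite R x R covariance
#'   matrices.
#' @param trans K x K stochastic matrix with zero diagonal; `trans[j, k]` is
#'   the probability that the next distinct state is `k` given the current
#'   state is `j`. For `K = 1` this is a degenerate 1 x 1 zero matrix.
#' @param init length-K initial state probability vector.
#' @param dwell dwell specification: `list(family = "shifted_poisson",
#'   lambda = <length-K positive vector>)` or `list(family = "nonparametric",
#'   pmf = <K x max_dwell matrix>)`.
#' @param max_dwell truncation bound for dwell times (timepoints).
#' @param region_names optional character vector of R region names.
#'
#' @return An object of class `hsmm_params`.
#' @export
hsmm_params <- function(mu, sigma, trans, init, dwell, max_dwell = 50L,
                        region_names = NULL) {
  mu <- as.matrix(mu)
  K <- nrow(mu)
  R <- ncol(mu)
  obj <- structure(list(
    K = K, R = R, mu = mu, sigma = sigma, trans = as.matrix(trans),
    init = as.numeric(init), dwell = dwell, max_dwell = as.integer(max_dwell),
    region_names = region_names
  ), class = "hsmm_params")
  validate_hsmm_params(obj)
  obj
}

#' Validate an `hsmm_params` object
#'
#' Checks the structural invariants: stochastic zero-diagonal transition
#' matrix, positive-definite covariances, dwell pmfs summing to one over the
#' truncated support, and a proper initial distribution.
#'
#' @param p an `hsmm_params` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_hsmm_params <- function(p) {
  stopifnot(inherits(p, "hsmm_params"))
  K <- p$K; R <- p$R
  if (K < 1L) stop("K must be >= 1")
  if (R < 1L) stop("R must be >= 1")
  if (!is.list(p$sigma) || length(p$sigma) != K)
    stop("sigma must be a list of K covariance matrices")
  for (k in seq_len(K)) {
    S <- p$sigma[[k]]
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      stop(sprintf("sigma[[%d]] is not symmetric", k))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop(sprintf("sigma[[%d]] is not positive-definite", k))
  }
  if (!all(dim(p$trans) == c(K, K))) stop("trans must be K x K")
  if (K >= 2L) {
    if (any(abs(diag(p$trans)) > 1e-12))
      stop("trans must have a zero diagonal (no self-transitions)")
    if (any(p$trans < -1e-12)) stop("trans has negative entries")
    if (any(abs(rowSums(p$trans) - 1) > 1e-8))
      stop("rows of trans must sum to 1")
  }
  if (length(p$init) != K || any(p$init < -1e-12) ||
      abs(sum(p$init) - 1) > 1e-8)
    stop("init must be a length-K probability vector")
  if (p$max_dwell < 1L) stop("max_dwell must be positive")
  pmf <- dwell_pmf(p)
  if (any(abs(rowSums(pmf) - 1) > 1e-8))
    stop("dwell pmf must sum to 1 over 1..max_dwell")
  if (!is.null(p$region_names)) {
    if (length(p$region_names) != R) stop("region_names must have length R")
    if (anyDuplicated(p$region_names)) stop("region_names must be unique")
  }
  invisible(p)
}

#' Dwell-time pmf matrix
#'
#' Evaluates each state's dwell distribution on `1..max_dwell`, renormalized
#' over the truncated support.
#'
#' @param p an `hsmm_params` object, or a dwell specification list together
#'   with `max_dwell` and `K`.
#' @param max_dwell,K required only when `p` is a bare dwell specification.
#' @return K x max_dwell matrix of probabilities; rows sum to 1.
#' @export
dwell_pmf <- function(p, max_dwell = NULL, K = NULL) {
  if (inherits(p, "hsmm_params")) {
    spec <- p$dwell; max_dwell <- p$max_dwell; K <- p$K
  } else {
    spec <- p
    if (is.null(max_dwell) || is.null(K))
      stop("max_dwell and K are required with a bare dwell specification")
  }
  D <- as.integer(max_dwell)
  if (identical(spec$family, "shifted_poisson")) {
    lam <- rep_len(spec$lambda, K)
    pm <- t(vapply(lam, function(l) stats::dpois(0:(D - 1L), l),
                   numeric(D)))
  } else if (identical(spec$family, "nonparametric")) {
    pm <- as.matrix(spec$pmf)
    if (ncol(pm) < D) pm <- cbind(pm, matrix(0, nrow(pm), D - ncol(pm)))
    pm <- pm[, seq_len(D), drop = FALSE]
    if (nrow(pm) != K) stop("nonparametric dwell pmf must have K rows")
    if (any(pm < 0)) stop("dwell pmf entries must be nonnegative")
  } else {
    stop("unknown dwell family: ", spec$family)
  }
  sums <- rowSums(pm)
  if (any(sums <= 0)) stop("dwell pmf has zero total mass for some state")
  pm / sums
}

#' Mean dwell time per state
#'
#' Expected dwell length (timepoints) under the truncated dwell pmf.
#'
#' @param p an `hsmm_params` object.
#' @return length-K numeric vector.
#' @export
dwell_mean <- function(p) {
  pm <- dwell_pmf(p)
  as.numeric(pm %*% seq_len(ncol(pm)))
}

#' @export
print.hsmm_params <- function(x, ...) {
  cat(sprintf("HSMM parameters: K = %d states, R = %d regions, max_dwell = %d\n",
              x$K, x$R, x$max_dwell))
  cat(sprintf("  dwell family: %s; mean dwell: %s timepoints\n",
              x$dwell$family,
              paste(sprintf("%.2f", dwell_mean(x)), collapse = ", ")))
  if (x$K >= 2L)
    cat(sprintf("  min pairwise state-mean distance: %.4f\n",
                min_state_distance(x)))
  invisible(x)
}

# Log emission density matrix: K x T, entry (k, t) = log N(y_t; mu_k, sigma_k).
# Cholesky-based; errors name the offending state if a covariance is singular.
log_emission_matrix <- function(p, Y) {
  Y <- as.matrix(Y)
  T_ <- nrow(Y); R <- ncol(Y)
  if (R != p$R) stop("scan has ", R, " regions but params expect ", p$R)
  E <- matrix(0, p$K, T_)
  for (k in seq_len(p$K)) {
    ch <- tryCatch(chol(p$sigma[[k]]),
                   error = function(e) stop("singular covariance in state ", k,
                                            call. = FALSE))
    ctr <- sweep(Y, 2L, p$mu[k, ], "-")
    z <- backsolve(ch, t(ctr), transpose = TRUE)
    quad <- colSums(z^2)
    logdet <- 2 * sum(log(diag(ch)))
    E[k, ] <- -0.5 * (R * log(2 * pi) + logdet + quad)
  }
  E
}

# Log-space ingredients for the C++ recursions.
hsmm_log_ingredients <- function(p) {
  pm <- dwell_pmf(p)
  logpmf <- log(pm)
  # survival S(d) = P(dwell >= d); S(1) = 1 by construction
  surv <- t(apply(pm, 1L, function(r) rev(cumsum(rev(r)))))
  if (p$K == 1L) surv <- matrix(surv, nrow = 1L)
  logS <- log(pmin(surv, 1))
  logA <- log(p$trans)
  diag(logA) <- -Inf
  logpi <- log(p$init)
  list(logpmf = logpmf, logS = logS, logA = logA, logpi = logpi)
}
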