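#' Marginal log-likelihood of a scan under an HSMM
#'
#' Log probability of the observed series marginalized over all
#' duration-respecting state paths, computed by the explicit-duration forward
#' recursion in log space. The final dwell is right-censored at the end of
#' the scan (a survival term), matching the generative truncation.
#'
#' @param params an [hsmm_params()] object.
#' @param scan a [scan_series()] or bare T x R matrix.
#' @return scalar log-likelihood.
#' @export
hsmm_loglik <- function(params, scan) {
  Y <- scan_matrix(scan, params)
  E <- log_emission_matrix(params, Y)
  if (params$K == 1L) return(sum(E))
  ing <- hsmm_log_ingredients(params)
  hsmm_forward_cpp(E, ing$logpmf, ing$logS, ing$logA, ing$logpi)
}

#' Explicit-duration forward-backward pass
#'
#' Posterior state-occupation probabilities and the expected sufficient
#' statistics for one scan: per-timepoint state posteriors, expected dwell
#' counts (uncensored segments and the censored tail separately), expected
#' transition counts, and the posterior over the initial segment's state.
#'
#' @inheritParams hsmm_loglik
#' @return list with `loglik`, `gamma` (K x T), `dwell_counts` (K x
#'   max_dwell), `dwell_censored`, `trans_counts` (K x K), `init_post`.
#' @export
forward_backward <- function(params, scan) {
  Y <- scan_matrix(scan, params)
  E <- log_emission_matrix(params, Y)
  if (params$K == 1L) {
    T_ <- ncol(E)
    return(list(loglik = sum(E), gamma = matrix(1, 1L, T_),
                dwell_counts = matrix(0, 1L, params$max_dwell),
                dwell_censored = matrix(0, 1L, params$max_dwell),
                trans_counts = matrix(0, 1L, 1L), init_post = 1))
  }
  ing <- hsmm_log_ingredients(params)
  hsmm_fb_cpp(E, ing$logpmf, ing$logS, ing$logA, ing$logpi)
}

#' Most probable state path (duration-aware Viterbi)
#'
#' Jointly most probable duration-respecting path under the model; ties are
#' broken toward the lower state index, then the shorter dwell.
#'
#' @inheritParams hsmm_loglik
#' @return A [state_sequence()] with `log_joint` set to the log probability
#'   of the decoded path together with the data.
#' @export
viterbi_decode <- function(params, scan) {
  Y <- scan_matrix(scan, params)
  E <- log_emission_matrix(params, Y)
  if (params$K == 1L)
    return(state_sequence(rep(1L, ncol(E)), 1L, log_joint = sum(E)))
  ing <- hsmm_log_ingredients(params)
  v <- hsmm_viterbi_cpp(E, ing$logpmf, ing$logS, ing$logA, ing$logpi)
  state_sequence(v$labels + 1L, params$K, log_joint = v$log_joint)
}

scan_matrix <- function(scan, params = NULL) {
  Y <- if (inherits(scan, "scan_series")) scan$matrix else as.matrix(scan)
  if (!is.null(params) && ncol(Y) != params$R)
    stop("scan has ", ncol(Y), " regions but params expect ", params$R)
  Y
}

#' Initialize HSMM parameters from pooled data
#'
#' Means and covariances come from k-means clustering of the pooled
#' timepoints (restarted internally on empty clusters); the transition matrix
#' is uniform off-diagonal, dwell distributions are shifted Poisson with mean
#' 5, and the initial distribution is uniform.
#'
#' @param scans list of [scan_series()] (or matrices) sharing R.
#' @param K number of states.
#' @param seed integer seed (k-means is stochastic).
#' @param max_dwell dwell truncation bound.
#' @return An [hsmm_params()] object.
#' @export
init_params <- function(scans, K, seed = 1L, max_dwell = 50L) {
  Y <- do.call(rbind, lapply(scans, scan_matrix))
  n <- nrow(Y); R <- ncol(Y)
  if (n < K) stop("K exceeds the number of pooled timepoints")
  if (n < K * (R + 1L))
    warning("fewer pooled timepoints than K*(R+1); initialization may be unstable")
  pooled_cov <- stats::cov(Y)
  ridge <- diag(1e-6 * mean(diag(pooled_cov)) + 1e-12, R)
  if (K == 1L) {
    mu <- matrix(colMeans(Y), 1L, R)
    sigma <- list(pooled_cov + ridge)
  } else {
    set.seed(derive_seed(seed, 11L))
    km <- stats::kmeans(Y, centers = K, nstart = 5L, iter.max = 50L)
    mu <- km$centers
    sigma <- lapply(seq_len(K), function(k) {
      idx <- which(km$cluster == k)
      if (length(idx) >= R + 2L) stats::cov(Y[idx, , drop = FALSE]) + ridge
      else pooled_cov + ridge
    })
  }
  trans <- matrix(1 / max(K - 1L, 1L), K, K)
  diag(trans) <- 0
  if (K == 1L) trans <- matrix(0, 1L, 1L)
  hsmm_params(mu = mu, sigma = sigma, trans = trans, init = rep(1 / K, K),
              dwell = list(family = "shifted_poisson", lambda = rep(4, K)),
              max_dwell = max_dwell)
}

#' Fit an HSMM to pooled scans by EM
#'
#' The E-step runs the explicit-duration forward-backward pass per scan
#' (scans are independent sequences, never concatenated); the M-step updates
#' means, covariances (with a small diagonal ridge), the transition matrix,
#' the initial distribution, and the dwell parameters from the expected
#' duration counts of uncensored segments. A state whose total responsibility
#' collapses is re-seeded from the worst-fit timepoints. With `n_starts > 1`
#' the fit is restarted from different k-means initializations and the best
#' final log-likelihood is kept.
#'
#' @param scans list of [scan_series()] (or matrices) sharing R.
#' @param K number of states.
#' @param config a [run_config()]; `max_dwell`, `n_starts`, `max_iter`,
#'   `tol`, and `seed` are used.
#' @param dwell_family `"shifted_poisson"` (parametric rates) or
#'   `"nonparametric"` (free truncated pmf).
#' @param verbose print per-iteration log-likelihoods?
#' @return list of class `hsmm_fit` with `params`, `loglik_trace`, `n_iter`,
#'   `converged`, `K`, `n_scans`.
#' @export
em_fit <- function(scans, K, config = run_config(),
                   dwell_family = c("shifted_poisson", "nonparametric"),
                   verbose = FALSE) {
  dwell_family <- match.arg(dwell_family)
  if (!is.list(scans) || inherits(scans, "scan_series")) scans <- list(scans)
  best <- NULL
  for (s in seq_len(config$n_starts)) {
    fit <- em_fit_once(scans, K, config, dwell_family,
                       seed = derive_seed(config$seed, 20L + s),
                       verbose = verbose)
    if (is.null(best) ||
        fit$loglik_trace[fit$n_iter] > best$loglik_trace[best$n_iter])
      best <- fit
  }
  best
}

em_fit_once <- function(scans, K, config, dwell_family, seed, verbose) {
  mats <- lapply(scans, scan_matrix)
  R <- ncol(mats[[1L]])
  D <- config$max_dwell
  params <- init_params(mats, K, seed = seed, max_dwell = D)
  if (dwell_family == "nonparametric") {
    pm0 <- dwell_pmf(params)
    params$dwell <- list(family = "nonparametric", pmf = pm0)
  }
  trace <- numeric(0)
  converged <- FALSE
  n_pool <- sum(vapply(mats, nrow, 1L))
  for (iter in seq_len(config$max_iter)) {
    # E-step
    tot_ll <- 0
    sw <- numeric(K)                 # total responsibility per state
    swy <- matrix(0, K, R)
    swyy <- vector("list", K)
    for (k in seq_len(K)) swyy[[k]] <- matrix(0, R, R)
    dwell_cnt <- matrix(0, K, D)
    cens_cnt <- matrix(0, K, D)
    trans_cnt <- matrix(0, K, K)
    init_cnt <- numeric(K)
    for (m in mats) {
      fb <- forward_backward(params, m)
      if (!is.finite(fb$loglik))
        stop("non-finite log-likelihood at EM iteration ", iter)
      tot_ll <- tot_ll + fb$loglik
      g <- fb$gamma                  # K x T
      sw <- sw + rowSums(g)
      swy <- swy + g %*% m
      for (k in seq_len(K)) swyy[[k]] <- swyy[[k]] + crossprod(m * g[k, ], m)
      dwell_cnt <- dwell_cnt + fb$dwell_counts
      cens_cnt <- cens_cnt + fb$dwell_censored
      trans_cnt <- trans_cnt + fb$trans_counts
      init_cnt <- init_cnt + fb$init_post
    }
    trace <- c(trace, tot_ll)
    if (verbose) message(sprintf("EM iter %d: loglik = %.6f", iter, tot_ll))
    if (iter > 1L) {
      rel <- abs(trace[iter] - trace[iter - 1L]) /
        (abs(trace[iter - 1L]) + 1e-12)
      if (rel < config$tol) { converged <- TRUE; break }
    }

    # M-step
    empty <- which(sw < 1e-8)
    if (length(empty)) {
      message("re-seeding empty state(s) ", paste(empty, collapse = ", "),
              " from worst-fit timepoints")
      pooled <- do.call(rbind, mats)
      Eall <- log_emission_matrix(params, pooled)
      worst <- order(apply(Eall, 2L, max))[seq_along(empty)]
      for (i in seq_along(empty)) {
        k <- empty[i]
        params$mu[k, ] <- pooled[worst[i], ]
        params$sigma[[k]] <- stats::cov(pooled) +
          diag(1e-6 * mean(diag(stats::cov(pooled))) + 1e-12, R)
        sw[k] <- 1
      }
      next
    }
    mu <- swy / sw
    sigma <- vector("list", K)
    for (k in seq_len(K)) {
      S <- swyy[[k]] / sw[k] - tcrossprod(mu[k, ])
      S <- (S + t(S)) / 2
      ridge <- 1e-6 * mean(diag(S))
      sigma[[k]] <- S + diag(max(ridge, 1e-10), R)
    }
    if (K >= 2L) {
      rs <- rowSums(trans_cnt)
      trans <- trans_cnt / ifelse(rs > 0, rs, 1)
      trans[rs <= 0, ] <- 1 / (K - 1L)
      diag(trans) <- 0
      trans <- trans / rowSums(trans)
      init <- init_cnt / sum(init_cnt)
    } else {
      trans <- matrix(0, 1L, 1L)
      init <- 1
    }
    dcnt <- rowSums(dwell_cnt)
    ccnt <- rowSums(cens_cnt)
    if (dwell_family == "shifted_poisson") {
      # Exact M-step: maximize the expected dwell log-likelihood, including
      # the right-censored survival terms, by 1-D search per state.
      lam <- numeric(K)
      for (k in seq_len(K)) {
        if (dcnt[k] + ccnt[k] <= 1e-10) { lam[k] <- params$dwell$lambda[k]; next }
        wu <- dwell_cnt[k, ]
        wc <- cens_cnt[k, ]
        qfun <- function(l) {
          pm <- stats::dpois(0:(D - 1L), l)
          pm <- pm / sum(pm)
          lg <- log(pmax(pm, 1e-300))
          ls <- log(pmax(rev(cumsum(rev(pm))), 1e-300))
          sum(wu * lg) + sum(wc * ls)
        }
        moment <- sum((wu + wc) * (seq_len(D) - 1)) / (dcnt[k] + ccnt[k])
        lo <- max(1e-6, moment / 4)
        hi <- min(D, max(moment * 4, 1))
        lam[k] <- stats::optimize(qfun, c(lo, hi), maximum = TRUE,
                                  tol = 1e-6)$maximum
      }
      dwell <- list(family = "shifted_poisson", lambda = pmax(lam, 1e-6))
    } else {
      pm <- dwell_cnt
      for (k in seq_len(K)) {
        if (dcnt[k] > 1e-10) pm[k, ] <- dwell_cnt[k, ] / dcnt[k]
        else pm[k, ] <- dwell_pmf(params)[k, ]
      }
      pm <- pmax(pm, 1e-10)
      dwell <- list(family = "nonparametric", pmf = pm / rowSums(pm))
    }
    params <- hsmm_params(mu = mu, sigma = sigma, trans = trans, init = init,
                          dwell = dwell, max_dwell = D,
                          region_names = params$region_names)
  }
  structure(list(params = params, loglik_trace = trace,
                 n_iter = length(trace), converged = converged,
                 K = K, n_scans = length(mats), n_pooled = n_pool),
            class = "hsmm_fit")
}

#' @export
print.hsmm_fit <- function(x, ...) {
  cat(sprintf("HSMM fit: K = %d, %d scans, %d EM iterations (%s), loglik = %.2f\n",
              x$K, x$n_scans, x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              x$loglik_trace[x$n_iter]))
  invisible(x)
}
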