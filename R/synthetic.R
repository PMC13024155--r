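#' Decoded or simulated state sequence
#'
#' @param labels integer vector of state labels in `1..K`.
#' @param K number of states.
#' @param log_joint log probability of the path and data under the model
#'   (`NA` for simulated ground-truth paths).
#' @return object of class `state_sequence`.
#' @export
state_sequence <- function(labels, K, log_joint = NA_real_) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("empty state sequence")
  if (any(labels < 1L | labels > K)) stop("labels must lie in 1..K")
  structure(list(labels = labels, K = as.integer(K),
                 log_joint = as.numeric(log_joint)),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("state_sequence: T = %d, K = %d, %d runs%s\n",
              length(x$labels), x$K, length(rle(x$labels)$lengths),
              if (is.finite(x$log_joint))
                sprintf(", log_joint = %.3f", x$log_joint) else ""))
  invisible(x)
}

#' Generate a random ground-truth HSMM parameter set
#'
#' State means are drawn until every pair is at least `separation` apart
#' (Euclidean); covariances are random symmetric positive-definite matrices
#' with eigenvalues in `[0.5, 2]`; the transition matrix has a zero diagonal
#' with Dirichlet rows; dwell distributions come from the requested family
#' with mean dwell at least 3 timepoints.
#'
#' @param R number of regions (>= 2).
#' @param K number of states (>= 1).
#' @param separation minimum pairwise distance between state means, in signal
#'   units.
#' @param seed integer seed.
#' @param dwell_lambda optional length-K shifted-Poisson rates; drawn
#'   uniformly from `[2, 8]` when `NULL`.
#' @param max_dwell dwell truncation bound.
#' @param max_tries mean draws attempted before giving up on `separation`.
#' @param mean_geometry `"gaussian"` draws means from a spherical normal and
#'   retries until the pairwise separation holds; `"simplex"` places them on
#'   a randomly rotated regular simplex with side exactly `separation`, so
#'   all states are equally distinct (requires `K <= R`).
#' @return An [hsmm_params()] object.
#' @export
generate_params <- function(R, K, separation = 2, seed = 1L,
                            dwell_lambda = NULL, max_dwell = 50L,
                            max_tries = 200L,
                            mean_geometry = c("gaussian", "simplex")) {
  stopifnot(K >= 1L, R >= 2L, separation > 0)
  mean_geometry <- match.arg(mean_geometry)
  set.seed(derive_seed(seed, 1L))
  mu <- NULL
  if (mean_geometry == "simplex") {
    if (K > R) stop("simplex geometry requires K <= R")
    V <- diag(1, K)                                   # rows: unit vertices
    V <- sweep(V, 2L, colMeans(V), "-")               # center (side sqrt(2))
    V <- V * separation / sqrt(2)                     # side = separation
    emb <- cbind(V, matrix(0, K, R - K))
    Q <- qr.Q(qr(matrix(stats::rnorm(R * R), R, R)))  # random rotation
    mu <- emb %*% Q
  } else {
    for (i in seq_len(max_tries)) {
      cand <- matrix(stats::rnorm(K * R, sd = separation), K, R)
      if (K < 2L || min(stats::dist(cand)) >= separation) { mu <- cand; break }
    }
  }
  if (is.null(mu))
    stop("could not achieve the requested mean separation after ",
         max_tries, " tries")
  sigma <- lapply(seq_len(K), function(k) {
    Q <- qr.Q(qr(matrix(stats::rnorm(R * R), R, R)))
    ev <- stats::runif(R, 0.5, 2)
    S <- Q %*% (ev * t(Q))
    (S + t(S)) / 2
  })
  if (K >= 2L) {
    trans <- matrix(stats::rgamma(K * K, shape = 2), K, K)
    diag(trans) <- 0
    trans <- trans / rowSums(trans)
  } else {
    trans <- matrix(0, 1L, 1L)
  }
  if (is.null(dwell_lambda)) dwell_lambda <- stats::runif(K, 2, 8)
  stopifnot(length(dwell_lambda) == K, all(dwell_lambda >= 2))
  hsmm_params(mu = mu, sigma = sigma, trans = trans,
              init = rep(1 / K, K),
              dwell = list(family = "shifted_poisson",
                           lambda = as.numeric(dwell_lambda)),
              max_dwell = max_dwell)
}

#' Sample a semi-Markov state path
#'
#' Draws the initial state from the initial distribution, a dwell length from
#' that state's (truncated) dwell distribution, emits that many labels, then
#' transitions according to the zero-diagonal transition matrix; the final
#' dwell is truncated at `T`.
#'
#' @param params an [hsmm_params()] object.
#' @param T path length in timepoints.
#' @param seed integer seed.
#' @return A [state_sequence()].
#' @export
sample_path <- function(params, T, seed = 1L) {
  stopifnot(T >= 1L)
  set.seed(derive_seed(seed, 2L))
  K <- params$K
  if (K == 1L) return(state_sequence(rep(1L, T), 1L))
  pm <- dwell_pmf(params)
  D <- ncol(pm)
  labels <- integer(T)
  t <- 0L
  s <- sample.int(K, 1L, prob = params$init)
  while (t < T) {
    d <- sample.int(D, 1L, prob = pm[s, ])
    d <- min(d, T - t)
    labels[(t + 1L):(t + d)] <- s
    t <- t + d
    if (t < T) s <- sample.int(K, 1L, prob = params$trans[s, ])
  }
  state_sequence(labels, K)
}

#' Sample observations given a state path
#'
#' Row `t` is drawn from the multivariate normal of state `path[t]`; rows are
#' independent given the path.
#'
#' @param params an [hsmm_params()] object.
#' @param path a [state_sequence()] or integer label vector in `1..K`.
#' @param seed integer seed.
#' @return T x R numeric matrix.
#' @export
sample_observations <- function(params, path, seed = 1L) {
  labels <- if (inherits(path, "state_sequence")) path$labels else
    as.integer(path)
  if (any(labels < 1L | labels > params$K)) stop("path labels out of range")
  set.seed(derive_seed(seed, 3L))
  T_ <- length(labels)
  R <- params$R
  Y <- matrix(NA_real_, T_, R)
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    ch <- chol(params$sigma[[k]])
    Z <- matrix(stats::rnorm(length(idx) * R), length(idx), R)
    Y[idx, ] <- sweep(Z %*% ch, 2L, params$mu[k, ], "+")
  }
  Y
}

#' Default two-group ground truth
#'
#' Emission means and covariances are shared across groups (states are
#' population-level and estimated from pooled data); group effects enter only
#' through the dwell rates and the transition rows. The defaults emulate the
#' study design: the mindfulness group dwells longer in, and transitions more
#' often into, state 2, while the control group favors states 1 and 3; states
#' 4-6 do not differ. The stress model couples the score negatively to
#' state-2 occupancy.
#'
#' @param R number of regions.
#' @param K number of states (the group contrasts above assume `K >= 3`).
#' @param separation minimum pairwise distance between state means.
#' @param seed integer seed.
#' @param base_lambda baseline shifted-Poisson dwell rate for unaffected
#'   states.
#' @param max_dwell dwell truncation bound.
#' @return list with `params_by_group` (named list of [hsmm_params()]) and
#'   `stress_model`.
#' @export
default_ground_truth <- function(R = 36L, K = 6L, separation = 2, seed = 1L,
                                 base_lambda = 5, max_dwell = 50L) {
  base <- generate_params(R, K, separation = separation, seed = seed,
                          dwell_lambda = rep(base_lambda, K),
                          max_dwell = max_dwell)
  lam_m <- rep(base_lambda, K)
  lam_c <- rep(base_lambda, K)
  w_m <- rep(1, K)
  w_c <- rep(1, K)
  if (K >= 3L) {
    lam_m[1:3] <- c(2.5, 8, 2.5)
    lam_c[1:3] <- c(8, 2.5, 8)
    w_m[1:3] <- c(0.7, 2, 0.7)
    w_c[1:3] <- c(2, 0.7, 2)
  }
  reweight <- function(trans, w) {
    tw <- sweep(trans, 2L, w, "*")
    diag(tw) <- 0
    tw / rowSums(tw)
  }
  pm <- base
  pm$dwell$lambda <- lam_m
  pm$trans <- reweight(base$trans, w_m)
  pc <- base
  pc$dwell$lambda <- lam_c
  pc$trans <- reweight(base$trans, w_c)
  slopes <- rep(0, K)
  if (K >= 2L) slopes[2L] <- -0.06  # per occupancy percentage point
  list(
    params_by_group = list(mindfulness = validate_hsmm_params(pm),
                           control = validate_hsmm_params(pc)),
    stress_model = list(intercept = 3.0, slope_per_state = slopes,
                        noise_sd = 1.0, random_intercept_sd = 0.8)
  )
}

#' Single-state designed-effect ground truth
#'
#' A two-group ground truth in which exactly one designated state differs
#' between groups: group 1 (mindfulness) dwells longer in it (shifted-Poisson
#' rate `lambda_g1` vs `lambda_g2`) and transitions into it more often
#' (transition-column weight `w_g1` vs `w_g2`); every other state is
#' identical across groups. Emission means sit on a regular simplex so all
#' states are equally identifiable. Useful for validating that the pipeline
#' localizes a known group contrast.
#'
#' The default effect sizes were chosen by a power calculation for the
#' default cohort (15 + 17 participants, two 281-timepoint scans each): the
#' designated state's occupancy, entry-count, and dwell contrasts are several
#' permutation standard errors wide, while the occupancy spillover forced
#' onto the other states (occupancy sums to 100%) stays near one standard
#' error.
#'
#' @param R number of regions.
#' @param K number of states.
#' @param designated the state carrying the group contrast.
#' @param seed integer seed.
#' @param base_lambda dwell rate of the unaffected states.
#' @param lambda_g1,lambda_g2 designated-state dwell rates per group.
#' @param w_g1,w_g2 designated-state transition-column weights per group.
#' @param separation simplex side for the state means.
#' @param max_dwell dwell truncation bound.
#' @return list with `params_by_group`, `stress_model`, `designated`.
#' @export
designed_effect_truth <- function(R = 12L, K = 6L, designated = 2L,
                                  seed = 1L, base_lambda = 4,
                                  lambda_g1 = 4.8, lambda_g2 = 3.2,
                                  w_g1 = 1.35, w_g2 = 0.75,
                                  separation = 6, max_dwell = 50L) {
  base <- generate_params(R, K, separation = separation, seed = seed,
                          dwell_lambda = rep(base_lambda, K),
                          max_dwell = max_dwell,
                          mean_geometry = "simplex")
  uni <- matrix(1 / (K - 1L), K, K)
  diag(uni) <- 0
  base$trans <- uni
  reweight <- function(w) {
    wv <- rep(1, K)
    wv[designated] <- w
    tw <- sweep(uni, 2L, wv, "*")
    diag(tw) <- 0
    tw / rowSums(tw)
  }
  p1 <- base
  p1$dwell$lambda[designated] <- lambda_g1
  p1$trans <- reweight(w_g1)
  p2 <- base
  p2$dwell$lambda[designated] <- lambda_g2
  p2$trans <- reweight(w_g2)
  list(params_by_group = list(mindfulness = validate_hsmm_params(p1),
                              control = validate_hsmm_params(p2)),
       stress_model = list(intercept = 3, slope_per_state = rep(0, K),
                           noise_sd = 1, random_intercept_sd = 0.8),
       designated = as.integer(designated))
}

#' Outcome scores coupled to state occupancy
#'
#' `score = intercept + sum_k slope_k * occupancy_k + participant random
#' intercept + Gaussian noise`, clipped to the instrument's 1-10 scale.
#'
#' @param stress_model list with `intercept`, `slope_per_state`, `noise_sd`,
#'   `random_intercept_sd`.
#' @param occupancy scans x K matrix of occupancy percentages (one row per
#'   scan).
#' @param participant_ids character vector, one per scan.
#' @param seed integer seed.
#' @return numeric vector of scores, one per scan; the number of clipped
#'   scores is attached as attribute `"n_clipped"`.
#' @export
generate_stress <- function(stress_model, occupancy, participant_ids,
                            seed = 1L) {
  occupancy <- as.matrix(occupancy)
  if (nrow(occupancy) != length(participant_ids))
    stop("one occupancy row per scan is required")
  set.seed(derive_seed(seed, 4L))
  ids <- unique(participant_ids)
  b <- stats::rnorm(length(ids), 0, stress_model$random_intercept_sd)
  names(b) <- ids
  raw <- stress_model$intercept +
    as.numeric(occupancy %*% stress_model$slope_per_state) +
    b[participant_ids] +
    stats::rnorm(nrow(occupancy), 0, stress_model$noise_sd)
  clipped <- pmin(pmax(raw, 1), 10)
  n_clip <- sum(clipped != raw)
  if (n_clip > 0L)
    message(n_clip, " stress score(s) clipped to the 1-10 scale")
  structure(as.numeric(clipped), n_clipped = n_clip)
}

#' Generate a synthetic two-group cohort with known ground truth
#'
#' Group-1 (mindfulness) scans are sampled under the group-1 dwell and
#' transition parameters and likewise for group 2 (control); emissions are
#' shared. Returns the manifest, the scan list, and the full ground truth
#' (parameters, true paths, stress model), all reproducible from `seed`.
#'
#' @param n_group1,n_group2 participants per group (defaults 15 and 17).
#' @param scans_per_participant scans per participant (default 2).
#' @param T timepoints per scan (default 281, a 297-volume scan after
#'   trimming).
#' @param truth ground truth as returned by [default_ground_truth()]; built
#'   with the defaults when `NULL`.
#' @param seed integer master seed.
#' @return list with `manifest`, `scans`, `truth` (the input truth plus
#'   `true_paths`, a named list keyed `"participant/scan"`).
#' @export
generate_cohort <- function(n_group1 = 15L, n_group2 = 17L,
                            scans_per_participant = 2L, T = 281L,
                            truth = NULL, seed = 1L) {
  stopifnot(n_group1 >= 1L, n_group2 >= 1L, scans_per_participant >= 1L,
            T >= 2L)
  if (is.null(truth)) truth <- default_ground_truth(seed = seed)
  pg <- truth$params_by_group
  stopifnot(all(c("mindfulness", "control") %in% names(pg)))
  K <- pg$mindfulness$K

  ids <- c(sprintf("m%02d", seq_len(n_group1)),
           sprintf("c%02d", seq_len(n_group2)))
  groups <- rep(c("mindfulness", "control"), c(n_group1, n_group2))

  set.seed(derive_seed(seed, 5L))
  drinks <- ifelse(groups == "mindfulness",
                   stats::rnorm(length(ids), 1.9, 0.5),
                   stats::rnorm(length(ids), 2.5, 0.8))
  drinks <- round(pmax(drinks, 0.5), 1)

  rows <- list()
  scans <- list()
  paths <- list()
  occ <- NULL
  scan_pid <- character(0)
  i <- 0L
  for (p in seq_along(ids)) {
    for (s in seq_len(scans_per_participant)) {
      i <- i + 1L
      prm <- pg[[groups[p]]]
      sd_i <- derive_seed(seed, 100L + i)
      path <- sample_path(prm, T, seed = sd_i)
      Y <- sample_observations(prm, path, seed = sd_i)
      key <- paste0(ids[p], "/scan", s)
      paths[[key]] <- path
      scans[[i]] <- scan_series(Y, participant_id = ids[p],
                                scan_id = paste0("scan", s),
                                group = groups[p], tr_seconds = 2)
      rows[[i]] <- data.frame(participant_id = ids[p],
                              scan_id = paste0("scan", s),
                              group = groups[p],
                              stress_score = NA_real_,
                              avg_drinks = drinks[p],
                              path = NA_character_,
                              stringsAsFactors = FALSE)
      occ <- rbind(occ, occupancy_time(path, K))
      scan_pid <- c(scan_pid, ids[p])
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$stress_score <- suppressMessages(
    generate_stress(truth$stress_model, occ, scan_pid, seed = seed))
  manifest <- as_manifest(manifest)
  truth$true_paths <- paths
  list(manifest = manifest, scans = scans, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Writes the manifest (CSV), one matrix CSV per scan, and a ground-truth
#' JSON (means, covariances, transitions, dwell parameters, true paths).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- cohort$manifest
  for (i in seq_along(cohort$scans)) {
    s <- cohort$scans[[i]]
    fn <- sprintf("%s_%s.csv", s$participant_id, s$scan_id)
    write_scan(s, file.path(dir, fn))
    man$path[i] <- fn
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  truth <- cohort$truth
  truth$true_paths <- lapply(truth$true_paths, function(p) p$labels)
  truth$params_by_group <- lapply(truth$params_by_group, function(p)
    list(K = p$K, R = p$R, mu = p$mu, sigma = p$sigma, trans = p$trans,
         init = p$init, dwell = p$dwell, max_dwell = p$max_dwell))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = I(17), auto_unbox = TRUE, matrix = "rowmajor")
  invisible(dir)
}
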