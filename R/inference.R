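#' Participant-level permutation test for a group mean difference
#'
#' Two-sided test on the absolute difference in group means of a
#' participant-level summary (each participant contributes one value,
#' typically the mean over their scans). Permutations shuffle group labels at
#' the participant level, so both of a participant's scans always move
#' together. The p-value uses the add-one formula: one plus the number of
#' null statistics at least as large as the observed one, over `n_perm + 1`.
#'
#' @param values numeric vector, one summary value per participant.
#' @param groups character/factor group labels, one per participant (two
#'   non-empty groups).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param statistic_name label stored in the result.
#' @return list of class `group_test` with `observed` (signed difference,
#'   group1 minus group2), `statistic` (absolute, the tested quantity),
#'   `null_samples`, `p_value`, `statistic_name`.
#' @export
permutation_test_mean_diff <- function(values, groups, n_perm = 500L,
                                       seed = 1L,
                                       statistic_name = "mean_diff") {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (setequal(lev, c("mindfulness", "control")))
    lev <- c("mindfulness", "control")  # report mindfulness minus control
  g1 <- groups == lev[1L]
  if (!any(g1) || all(g1)) stop("both groups must be non-empty")
  obs_signed <- mean(values[g1]) - mean(values[!g1])
  obs <- abs(obs_signed)
  set.seed(derive_seed(seed, 31L))
  n <- length(values)
  n1 <- sum(g1)
  null_samples <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n1)
    abs(mean(values[idx]) - mean(values[-idx]))
  }, numeric(1L))
  p <- (1 + sum(null_samples >= obs - 1e-12)) / (n_perm + 1)
  structure(list(statistic_name = statistic_name, observed = obs_signed,
                 statistic = obs, null_samples = null_samples, p_value = p),
            class = "group_test")
}

#' Kullback-Leibler divergence between discrete densities
#'
#' `sum(p * log(p / q))` with the natural logarithm. Both densities must live
#' on the same grid, sum to one, and be strictly positive (use the epsilon
#' floor of [dwell_density()]).
#'
#' @param p,q numeric probability vectors on a common grid.
#' @return nonnegative scalar; 0 iff `p == q`.
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must live on the same grid")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("p and q must each sum to 1")
  if (any(p <= 0) || any(q <= 0))
    stop("p and q must be strictly positive (apply an epsilon floor)")
  sum(p * log(p / q))
}

#' Permutation test on dwell-time distributions via symmetrized KL
#'
#' Pools each group's dwell times for one state, smooths them into discrete
#' densities on `1..max_dwell`, and tests the symmetrized KL divergence
#' `(KL(p||q) + KL(q||p)) / 2` against a null built by permuting participant
#' group labels and recomputing the pooled densities. A permutation that
#' leaves a group with no dwells is redrawn (the redraw count is recorded).
#'
#' @param dwells_by_participant list of integer vectors, one per participant
#'   (that participant's pooled dwell times for the state, both scans).
#' @param groups group labels, one per participant.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param max_dwell grid upper bound for the densities.
#' @param direction `"symmetrized"` (default), `"pq"` (group1 vs group2), or
#'   `"qp"`.
#' @return list of class `group_test` with `observed`, `null_samples`,
#'   `p_value`, `n_redrawn`, and the two group densities.
#' @export
permutation_test_dwell_kl <- function(dwells_by_participant, groups,
                                      n_perm = 500L, seed = 1L,
                                      max_dwell = 50L,
                                      direction = c("symmetrized", "pq", "qp")) {
  direction <- match.arg(direction)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (setequal(lev, c("mindfulness", "control")))
    lev <- c("mindfulness", "control")  # report mindfulness minus control
  grid <- seq_len(max_dwell)
  stat <- function(g1_idx) {
    d1 <- unlist(dwells_by_participant[g1_idx], use.names = FALSE)
    d2 <- unlist(dwells_by_participant[-g1_idx], use.names = FALSE)
    if (length(d1) == 0L || length(d2) == 0L) return(NULL)
    p <- dwell_density(pmin(d1, max_dwell), grid)
    q <- dwell_density(pmin(d2, max_dwell), grid)
    v <- switch(direction,
                symmetrized = (kl_divergence(p, q) + kl_divergence(q, p)) / 2,
                pq = kl_divergence(p, q),
                qp = kl_divergence(q, p))
    list(v = v, p = p, q = q)
  }
  g1_idx <- which(groups == lev[1L])
  obs <- stat(g1_idx)
  if (is.null(obs)) stop("each group must contribute at least one dwell")
  set.seed(derive_seed(seed, 32L))
  n <- length(groups)
  n1 <- length(g1_idx)
  null_samples <- numeric(n_perm)
  n_redrawn <- 0L
  for (i in seq_len(n_perm)) {
    repeat {
      s <- stat(sample.int(n, n1))
      if (!is.null(s)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_perm) stop("too many degenerate permutations")
    }
    null_samples[i] <- s$v
  }
  if (n_redrawn > 0L)
    message(n_redrawn, " degenerate permutation(s) redrawn")
  p_value <- (1 + sum(null_samples >= obs$v - 1e-12)) / (n_perm + 1)
  structure(list(statistic_name = "dwell_kl", observed = obs$v,
                 statistic = obs$v, null_samples = null_samples,
                 p_value = p_value, n_redrawn = n_redrawn,
                 density_group1 = obs$p, density_group2 = obs$q),
            class = "group_test")
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values and rejection flags at level `alpha`.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param alpha FDR level.
#' @return list with `q_values` and `rejected` (logical).
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    return(list(q_values = numeric(0), rejected = logical(0)))
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, rejected = q <= alpha)
}

#' All group-difference tests for a decoded cohort
#'
#' Runs, for every state, the participant-level permutation tests on mean
#' occupancy and mean transition frequency (scan means per participant) and
#' the dwell-distribution KL test, then applies Benjamini-Hochberg correction
#' within each dynamic property (occupancy family, transition family, dwell
#' family).
#'
#' @param summary result of [summarize_dynamics()].
#' @param K number of states.
#' @param config a [run_config()]; permutations, FDR level, `max_dwell`, and
#'   seed are used.
#' @return data.frame with one row per state x property: `state`, `property`,
#'   `observed`, `p_value`, `q_value`, `significant`.
#' @export
group_tests <- function(summary, K, config = run_config()) {
  tab <- summary$table
  # participant-level scan means
  agg <- stats::aggregate(cbind(occupancy_pct, transitions_in) ~
                            participant_id + group + state, data = tab,
                          FUN = mean)
  res <- list()
  for (prop in c("occupancy", "transitions", "dwell_kl")) {
    rows <- vector("list", K)
    for (k in seq_len(K)) {
      if (prop %in% c("occupancy", "transitions")) {
        sub <- agg[agg$state == k, ]
        sub <- sub[order(sub$participant_id), ]
        vals <- if (prop == "occupancy") sub$occupancy_pct else
          sub$transitions_in
        # one shared permutation stream per property, so states are compared
        # against identical label reshuffles (and K = 2 reflections agree)
        t1 <- permutation_test_mean_diff(
          vals, sub$group, n_perm = config$n_permutations,
          seed = derive_seed(config$seed,
                             1000L + match(prop, c("occupancy", "transitions"))),
          statistic_name = prop)
      } else {
        pid <- unique(tab$participant_id)
        dl <- lapply(pid, function(p) {
          keys <- grep(paste0("^", p, "/"), names(summary$dwells))
          unlist(lapply(summary$dwells[keys], function(d) d[[k]]),
                 use.names = FALSE)
        })
        pgr <- tab$group[match(pid, tab$participant_id)]
        t1 <- permutation_test_dwell_kl(
          dl, pgr, n_perm = config$n_permutations,
          seed = derive_seed(config$seed, 2000L + k),
          max_dwell = config$max_dwell)
      }
      rows[[k]] <- data.frame(state = k, property = prop,
                              observed = t1$observed, p_value = t1$p_value,
                              stringsAsFactors = FALSE)
    }
    fam <- do.call(rbind, rows)
    fc <- fdr_correct(fam$p_value, alpha = config$fdr_alpha)
    fam$q_value <- fc$q_values
    fam$significant <- fc$rejected
    res[[prop]] <- fam
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
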