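#' Occupancy time per state
#'
#' Fraction of the scan's timepoints spent in each state, as a percentage.
#'
#' @param seq a [state_sequence()] or integer label vector in `1..K`.
#' @param K number of states.
#' @return length-K numeric vector summing to 100.
#' @export
occupancy_time <- function(seq, K) {
  labels <- seq_labels(seq, K)
  100 * tabulate(labels, nbins = K) / length(labels)
}

#' Transition frequency into each state
#'
#' Number of times the sequence *enters* each state, i.e. change-points whose
#' destination is that state. By the entry convention the initial state at
#' the start of the scan is not counted; set `count_initial = TRUE` for the
#' inclusive convention.
#'
#' @param seq a [state_sequence()] or integer label vector in `1..K`.
#' @param K number of states.
#' @param count_initial count the first state as an entry?
#' @return length-K integer vector of entry counts.
#' @export
transition_frequency <- function(seq, K, count_initial = FALSE) {
  labels <- seq_labels(seq, K)
  r <- rle(labels)$values
  dest <- if (count_initial) r else r[-1L]
  tabulate(dest, nbins = K)
}

#' Dwell times per state
#'
#' Run-length encodes the sequence into per-state lists of consecutive
#' dwell lengths. With `exclude_edges` the first and last runs are dropped
#' regardless of their state, because the time spent in a state immediately
#' before or after the scan window is unknown (a sequence with at most two
#' runs then yields empty lists).
#'
#' @param seq a [state_sequence()] or integer label vector in `1..K`.
#' @param K number of states.
#' @param exclude_edges drop the first and last dwell periods?
#' @return list of K integer vectors of run lengths, named `state1..stateK`.
#' @export
dwell_times <- function(seq, K, exclude_edges = TRUE) {
  labels <- seq_labels(seq, K)
  r <- rle(labels)
  vals <- r$values
  lens <- r$lengths
  if (exclude_edges) {
    n <- length(vals)
    keep <- if (n <= 2L) integer(0) else 2L:(n - 1L)
    vals <- vals[keep]
    lens <- lens[keep]
  }
  out <- lapply(seq_len(K), function(k) as.integer(lens[vals == k]))
  names(out) <- paste0("state", seq_len(K))
  out
}

seq_labels <- function(seq, K) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else
    as.integer(seq)
  if (length(labels) == 0L) stop("empty state sequence")
  if (any(labels < 1L | labels > K)) stop("labels must lie in 1..K")
  labels
}

#' Discrete dwell-time density on an integer grid
#'
#' Gaussian-kernel smoothing of the integer dwell histogram, evaluated on
#' `grid`, floored at a small epsilon and renormalized to sum to one. The
#' floor keeps Kullback-Leibler divergences finite everywhere. The default
#' bandwidth is Silverman's rule on the raw dwells, with a lower bound so a
#' single observation still yields a proper (near point-mass) density.
#'
#' @param dwells positive integer dwell observations (pooled over a group).
#' @param grid integer grid, typically `1:max_dwell`.
#' @param bandwidth kernel bandwidth; `NULL` for Silverman's rule.
#' @param floor_eps density floor before renormalization.
#' @return numeric vector on `grid`, strictly positive, summing to one.
#' @export
dwell_density <- function(dwells, grid, bandwidth = NULL, floor_eps = 1e-10) {
  dwells <- as.numeric(dwells)
  if (length(dwells) == 0L) stop("no dwells for state")
  if (any(dwells < 1)) stop("dwell times must be positive integers")
  if (is.null(bandwidth)) {
    bandwidth <- if (length(dwells) >= 2L && stats::sd(dwells) > 0)
      stats::bw.nrd0(dwells) else 0.5
  }
  bandwidth <- max(bandwidth, 1e-8)
  dens <- vapply(grid, function(g)
    mean(stats::dnorm(g, mean = dwells, sd = bandwidth)), numeric(1L))
  dens <- pmax(dens, floor_eps)
  dens / sum(dens)
}

#' Per-scan dynamics summaries for a decoded cohort
#'
#' Computes occupancy percentages, entry counts, and (edge-excluded) dwell
#' lists for every decoded scan, in a long-format table plus a dwell list.
#'
#' @param sequences named list of [state_sequence()], one per scan, in
#'   manifest order.
#' @param manifest the `cohort_manifest` the sequences belong to.
#' @param K number of states.
#' @return list with `table` (data.frame: participant_id, scan_id, group,
#'   state, occupancy_pct, transitions_in) and `dwells` (nested list
#'   `[[scan]][[state]]` of run lengths).
#' @export
summarize_dynamics <- function(sequences, manifest, K) {
  stopifnot(length(sequences) == nrow(manifest))
  tabs <- vector("list", length(sequences))
  dw <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    occ <- occupancy_time(sequences[[i]], K)
    tf <- transition_frequency(sequences[[i]], K)
    tabs[[i]] <- data.frame(
      participant_id = manifest$participant_id[i],
      scan_id = manifest$scan_id[i],
      group = manifest$group[i],
      state = seq_len(K),
      occupancy_pct = occ,
      transitions_in = tf,
      stringsAsFactors = FALSE
    )
    dw[[i]] <- dwell_times(sequences[[i]], K, exclude_edges = TRUE)
  }
  names(dw) <- paste(manifest$participant_id, manifest$scan_id, sep = "/")
  list(table = do.call(rbind, tabs), dwells = dw)
}
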