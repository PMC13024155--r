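#' Minimum pairwise distance between state means
#'
#' The state-distinctiveness score used for choosing the number of states:
#' the minimum Euclidean distance between any pair of state mean vectors
#' (computed on the raw means; set `scale = TRUE` to z-score regions first).
#'
#' @param params an [hsmm_params()] object with `K >= 2`.
#' @param scale z-score each region across states before computing distances?
#' @return nonnegative scalar.
#' @export
min_state_distance <- function(params, scale = FALSE) {
  if (params$K < 2L) stop("min_state_distance requires K >= 2")
  mu <- params$mu
  if (scale) mu <- base::scale(mu)
  min(stats::dist(mu))
}

#' Choose the number of states by the maximin-distance rule
#'
#' Fits every candidate K with [em_fit()] (same multi-start protocol and
#' master seed for comparability), records the minimum pairwise distance
#' between the fitted state means, and picks the candidate attaining the
#' largest minimum distance — the most clearly differentiated set of states.
#' Ties break toward the smaller K. A candidate whose fit fails is excluded
#' with a warning.
#'
#' @param scans list of [scan_series()] (or matrices).
#' @param k_range integer vector of candidate state counts (all >= 2);
#'   defaults to the configured range.
#' @param config a [run_config()].
#' @param scale passed to [min_state_distance()].
#' @return list of class `selection_report` with `candidates`,
#'   `min_pairwise_distance`, `chosen_K`, `fits`.
#' @export
select_k <- function(scans, k_range = NULL, config = run_config(),
                     scale = FALSE) {
  if (is.null(k_range)) k_range <- config$n_states_range
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L)) stop("candidate K values must be >= 2")
  fits <- vector("list", length(k_range))
  dists <- rep(NA_real_, length(k_range))
  names(fits) <- paste0("K", k_range)
  for (i in seq_along(k_range)) {
    fit <- tryCatch(em_fit(scans, k_range[i], config = config),
                    error = function(e) {
                      warning("fit failed for K = ", k_range[i], ": ",
                              conditionMessage(e))
                      NULL
                    })
    fits[[i]] <- fit
    if (!is.null(fit))
      dists[i] <- min_state_distance(fit$params, scale = scale)
  }
  if (all(is.na(dists))) stop("all candidate fits failed")
  chosen <- k_range[which.max(dists)]  # first max -> smaller K on ties
  structure(list(candidates = k_range, min_pairwise_distance = dists,
                 chosen_K = chosen, fits = fits),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("State-count selection (maximin pairwise mean distance):\n")
  for (i in seq_along(x$candidates))
    cat(sprintf("  K = %d: min distance %s%s\n", x$candidates[i],
                ifelse(is.na(x$min_pairwise_distance[i]), "fit failed",
                       sprintf("%.4f", x$min_pairwise_distance[i])),
                ifelse(x$candidates[i] == x$chosen_K, "  <- chosen", "")))
  invisible(x)
}
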