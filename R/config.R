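#' Pipeline run configuration
#'
#' Bundles the tunable settings of the analysis pipeline. The defaults
#' reproduce the study conditions: candidate state counts 3-7, 500
#' permutations, FDR level 0.05, modularity resolution gamma = 1, 10 leading
#' volumes trimmed then 3 timepoints from each end, and a dwell truncation of
#' 50 timepoints (100 s at TR = 2 s).
#'
#' @param n_states_range integer vector of candidate state counts.
#' @param n_permutations permutations per group test.
#' @param fdr_alpha FDR level in (0, 1).
#' @param modularity_gamma resolution parameter for community detection.
#' @param seed master seed; every stage derives its own stream from it.
#' @param trim_leading leading volumes removed before analysis.
#' @param trim_edges timepoints removed from each end after the leading trim.
#' @param max_dwell dwell-time truncation bound (timepoints).
#' @param n_starts EM restarts per fit (best final log-likelihood kept).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change declaring EM convergence.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_states_range = 3:7, n_permutations = 500L,
                       fdr_alpha = 0.05, modularity_gamma = 1, seed = 1L,
                       trim_leading = 10L, trim_edges = 3L, max_dwell = 50L,
                       n_starts = 5L, max_iter = 100L, tol = 1e-6) {
  stopifnot(n_permutations >= 1L, fdr_alpha > 0, fdr_alpha < 1,
            modularity_gamma > 0, trim_leading >= 0L, trim_edges >= 0L,
            max_dwell >= 1L, n_starts >= 1L, max_iter >= 1L, tol > 0)
  structure(list(
    n_states_range = as.integer(n_states_range),
    n_permutations = as.integer(n_permutations),
    fdr_alpha = fdr_alpha,
    modularity_gamma = modularity_gamma,
    seed = as.integer(seed),
    trim_leading = as.integer(trim_leading),
    trim_edges = as.integer(trim_edges),
    max_dwell = as.integer(max_dwell),
    n_starts = as.integer(n_starts),
    max_iter = as.integer(max_iter),
    tol = tol
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Fields in the file override the defaults of [run_config()]; unknown fields
#' are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

# Deterministic child seeds from one master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(offset)) %% 2147483629)
}
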