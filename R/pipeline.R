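#' Run the full state-dynamics pipeline
#'
#' Fits a single HSMM to the pooled scans (optionally selecting the number of
#' states by the maximin-distance rule first), Viterbi-decodes every scan,
#' summarizes occupancy / transition frequency / dwell times, tests group
#' differences with FDR correction, characterizes each state network, and
#' fits the dynamics-outcome mixed models.
#'
#' @param scans list of [scan_series()].
#' @param manifest the matching `cohort_manifest`.
#' @param config a [run_config()].
#' @param K number of states; `NULL` runs [select_k()] over the configured
#'   range.
#' @param trim apply the configured trimming to each scan first? Use `FALSE`
#'   when scans are already trimmed (e.g. simulated cohorts).
#' @param associate fit the outcome mixed models (requires `stress_score` and
#'   `avg_drinks` in the manifest)?
#' @return list of class `statedyn_pipeline` with `fit`, `selection` (or
#'   `NULL`), `sequences`, `summary`, `tests`, `characterization`,
#'   `association` (or `NULL`), `config`.
#' @export
run_pipeline <- function(scans, manifest, config = run_config(), K = NULL,
                         trim = FALSE, associate = TRUE) {
  stopifnot(length(scans) == nrow(manifest))
  if (trim)
    scans <- lapply(scans, trim_series, trim_leading = config$trim_leading,
                    trim_edges = config$trim_edges)
  selection <- NULL
  if (is.null(K)) {
    selection <- select_k(scans, config = config)
    K <- selection$chosen_K
    fit <- selection$fits[[paste0("K", K)]]
  } else {
    fit <- em_fit(scans, K, config = config)
  }
  sequences <- lapply(scans, function(s) viterbi_decode(fit$params, s))
  names(sequences) <- paste(manifest$participant_id, manifest$scan_id,
                            sep = "/")
  summary <- summarize_dynamics(sequences, manifest, K)
  tests <- group_tests(summary, K, config = config)
  characterization <- characterize_states(fit$params,
                                          gamma = config$modularity_gamma)
  association <- NULL
  if (associate && !all(is.na(manifest$stress_score)))
    association <- associate_dynamics(summary, manifest, K,
                                      alpha = config$fdr_alpha)
  structure(list(fit = fit, selection = selection, sequences = sequences,
                 summary = summary, tests = tests,
                 characterization = characterization,
                 association = association, config = config, K = K),
            class = "statedyn_pipeline")
}

#' @export
print.statedyn_pipeline <- function(x, ...) {
  cat(sprintf("statedyn pipeline: K = %d, %d scans\n", x$K,
              length(x$sequences)))
  cat("\nGroup tests (mindfulness minus control):\n")
  print(x$tests, digits = 4)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Writes the fitted parameters (JSON), the log-likelihood trace (CSV), one
#' decoded label CSV per scan, the dynamics summary table, the group-test
#' table, per-state module assignments and modularity scores, the activity
#' z-map, and the mixed-model coefficient table.
#'
#' @param result a `statedyn_pipeline` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_params(result$fit$params, file.path(dir, "params.json"))
  write_results(data.frame(iter = seq_along(result$fit$loglik_trace),
                           loglik = result$fit$loglik_trace),
                file.path(dir, "loglik_trace.csv"))
  lab_dir <- file.path(dir, "labels")
  if (!dir.exists(lab_dir)) dir.create(lab_dir)
  for (nm in names(result$sequences)) {
    fn <- file.path(lab_dir, paste0(gsub("/", "_", nm), ".csv"))
    utils::write.csv(data.frame(t = seq_along(result$sequences[[nm]]$labels) - 1L,
                                state = result$sequences[[nm]]$labels),
                     fn, row.names = FALSE)
  }
  write_results(result$summary$table, file.path(dir, "dynamics_summary.csv"))
  write_results(result$tests, file.path(dir, "group_tests.csv"))
  if (!is.null(result$selection))
    write_results(data.frame(K = result$selection$candidates,
                             min_distance = result$selection$min_pairwise_distance),
                  file.path(dir, "selection.csv"))
  ch <- result$characterization
  mods <- do.call(rbind, lapply(ch$networks, function(nw)
    data.frame(state = nw$state, region = seq_along(nw$modules),
               module = nw$modules)))
  write_results(mods, file.path(dir, "modules.csv"))
  write_results(data.frame(state = vapply(ch$networks, `[[`, 1L, "state"),
                           Q = vapply(ch$networks, `[[`, 1, "Q")),
                file.path(dir, "modularity.csv"))
  if (!is.null(ch$zmap))
    utils::write.csv(ch$zmap, file.path(dir, "activity_zmap.csv"))
  if (!is.null(result$association)) {
    write_results(result$association$screen$table,
                  file.path(dir, "mixed_models.csv"))
    st <- result$association$screen$stratified
    if (length(st)) {
      stab <- do.call(rbind, lapply(names(st), function(nm)
        cbind(model = nm, st[[nm]])))
      write_results(stab, file.path(dir, "stratified_models.csv"))
    }
  }
  invisible(dir)
}
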