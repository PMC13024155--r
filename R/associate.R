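#' Mixed-effects association of one state measure with the outcome score
#'
#' Fits `outcome ~ measure + group + measure:group + drinks + (1 |
#' participant)` by restricted maximum likelihood, with the mindfulness group
#' as the reference level. Wald t statistics use a residual degrees-of-freedom
#' approximation (`n_obs - n_fixed`). If every participant contributes a
#' single scan the random intercept is not identifiable and the model reduces
#' to ordinary least squares (with a warning), its exact boundary case.
#'
#' @param outcome per-scan outcome scores.
#' @param measure per-scan state summary (occupancy \% or entry count).
#' @param group per-scan group labels (`mindfulness`/`control`).
#' @param drinks per-scan covariate (average drinks per drinking day).
#' @param participant_ids per-scan participant identifiers.
#' @param measure_name label stored in the result.
#' @param state state index stored in the result.
#' @return list of class `mixed_model_result` with `coefficients` (data.frame:
#'   term, estimate, std_error, t, p), `n_obs`, `n_participants`,
#'   `singular` flag, `random_intercept_sd`, and the fitted model.
#' @export
fit_mixed <- function(outcome, measure, group, drinks, participant_ids,
                      measure_name = "occupancy", state = NA_integer_) {
  n <- length(outcome)
  stopifnot(length(measure) == n, length(group) == n, length(drinks) == n,
            length(participant_ids) == n)
  if (stats::var(measure) == 0) stop("measure has zero variance")
  group <- factor(normalize_group(group), levels = c("mindfulness", "control"))
  if (any(table(group[!duplicated(participant_ids)]) < 2L))
    stop("at least 2 participants per group are required")
  df <- data.frame(outcome = outcome, measure = measure, group = group,
                   drinks = drinks, pid = factor(participant_ids))
  single_scan <- nlevels(df$pid) == n
  if (single_scan) {
    warning("one scan per participant: random intercept not identifiable, ",
            "fitting by ordinary least squares")
    fit <- stats::lm(outcome ~ measure * group + drinks, data = df)
    cf <- summary(fit)$coefficients
    est <- cf[, 1L]; se <- cf[, 2L]
    ri_sd <- 0
    singular <- TRUE
  } else {
    fit <- suppressMessages(lme4::lmer(
      outcome ~ measure * group + drinks + (1 | pid), data = df, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    singular <- lme4::isSingular(fit)
    if (singular)
      warning("singular fit: random-intercept variance estimated at zero")
    cf <- summary(fit)$coefficients
    est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
    ri_sd <- sqrt(unlist(lme4::VarCorr(fit))[["pid"]])
  }
  tval <- est / se
  dfree <- n - length(est)
  pval <- 2 * stats::pt(-abs(tval), df = dfree)
  terms <- names(est)
  terms[terms == "(Intercept)"] <- "intercept"
  terms[terms == "measure"] <- measure_name
  terms[terms == "groupcontrol"] <- "group"
  terms[terms == "measure:groupcontrol"] <- paste0(measure_name, ":group")
  terms[terms == "drinks"] <- "avg_drinks"
  structure(list(
    state = state, measure = measure_name,
    coefficients = data.frame(term = terms, estimate = unname(est),
                              std_error = unname(se), t = unname(tval),
                              p = unname(pval), stringsAsFactors = FALSE),
    n_obs = n, n_participants = nlevels(df$pid),
    random_intercept_sd = ri_sd, singular = singular, fit = fit
  ), class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("Mixed model: state %s, measure %s (%d obs, %d participants%s)\n",
              x$state, x$measure, x$n_obs, x$n_participants,
              if (x$singular) ", singular RI" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Interaction screen with group-stratified follow-up
#'
#' FDR-corrects the measure-by-group interaction p-values across the supplied
#' family of models; for every flagged model, refits within each group with
#' terms `measure + drinks + (1 | participant)` and reports the stratified
#' coefficient tables.
#'
#' @param results list of `mixed_model_result` objects (one per state x
#'   measure).
#' @param data the per-scan data the models were fitted on: data.frame with
#'   `outcome`, `group`, `drinks`, `participant_id`, and one measure column
#'   per result named `"<measure><state>"` (as built by
#'   [associate_dynamics()]).
#' @param alpha FDR level for the interaction gate.
#' @return list with `table` (term-level data.frame over all models,
#'   including interaction q-values), `stratified` (named list, possibly
#'   empty, of per-group coefficient tables).
#' @export
interaction_screen_and_stratify <- function(results, data, alpha = 0.05) {
  ip <- vapply(results, function(r) {
    r$coefficients$p[grepl(":group$", r$coefficients$term)]
  }, numeric(1L))
  fc <- fdr_correct(ip, alpha = alpha)
  rows <- list()
  strat <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    tab <- r$coefficients
    tab$state <- r$state
    tab$measure <- r$measure
    tab$interaction_q <- NA_real_
    tab$interaction_q[grepl(":group$", tab$term)] <- fc$q_values[i]
    rows[[i]] <- tab
    if (fc$rejected[i]) {
      col <- paste0(r$measure, r$state)
      for (g in c("mindfulness", "control")) {
        sub <- data[data$group == g, ]
        sfit <- fit_stratified(sub$outcome, sub[[col]], sub$drinks,
                               sub$participant_id, measure_name = r$measure)
        strat[[paste0("state", r$state, "_", r$measure, "_", g)]] <- sfit
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, stratified = strat)
}

#' Within-group mixed model for one state measure
#'
#' The stratified follow-up model `outcome ~ measure + drinks +
#' (1 | participant)`, fitted by REML within a single group (ordinary least
#' squares when each participant contributes one scan).
#'
#' @param outcome,measure,drinks,participant_ids per-scan vectors for the
#'   group being analyzed.
#' @param measure_name label used for the measure term.
#' @return data.frame of coefficients (term, estimate, std_error, t, p).
#' @export
fit_stratified <- function(outcome, measure, drinks, participant_ids,
                           measure_name = "occupancy") {
  df <- data.frame(outcome = outcome, measure = measure, drinks = drinks,
                   pid = factor(participant_ids))
  n <- nrow(df)
  if (nlevels(df$pid) == n) {
    fit <- stats::lm(outcome ~ measure + drinks, data = df)
    cf <- summary(fit)$coefficients
  } else {
    fit <- suppressMessages(lme4::lmer(
      outcome ~ measure + drinks + (1 | pid), data = df, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    cf <- summary(fit)$coefficients
  }
  est <- cf[, 1L]; se <- cf[, 2L]
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = n - length(est))
  terms <- names(est)
  terms[terms == "(Intercept)"] <- "intercept"
  terms[terms == "measure"] <- measure_name
  terms[terms == "drinks"] <- "avg_drinks"
  data.frame(term = terms, estimate = unname(est), std_error = unname(se),
             t = unname(tval), p = unname(pval), stringsAsFactors = FALSE)
}

#' Fit the full family of dynamics-outcome mixed models
#'
#' For every state, fits the occupancy and transition-frequency mixed models
#' against the outcome score, then runs the interaction screen and
#' stratified follow-up.
#'
#' @param summary result of [summarize_dynamics()].
#' @param manifest the cohort manifest (provides `stress_score` and
#'   `avg_drinks` per scan).
#' @param K number of states.
#' @param alpha FDR level for the interaction gate.
#' @return list with `models` (list of `mixed_model_result`), `screen`
#'   (result of [interaction_screen_and_stratify()]).
#' @export
associate_dynamics <- function(summary, manifest, K, alpha = 0.05) {
  tab <- summary$table
  wide <- data.frame(participant_id = manifest$participant_id,
                     scan_id = manifest$scan_id,
                     group = manifest$group,
                     outcome = manifest$stress_score,
                     drinks = manifest$avg_drinks,
                     stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    sub <- tab[tab$state == k, ]
    key <- paste(sub$participant_id, sub$scan_id)
    ord <- match(paste(wide$participant_id, wide$scan_id), key)
    wide[[paste0("occupancy", k)]] <- sub$occupancy_pct[ord]
    wide[[paste0("transition_frequency", k)]] <- sub$transitions_in[ord]
  }
  models <- list()
  for (k in seq_len(K)) {
    for (ms in c("occupancy", "transition_frequency")) {
      col <- paste0(ms, k)
      m <- tryCatch(
        fit_mixed(wide$outcome, wide[[col]], wide$group, wide$drinks,
                  wide$participant_id, measure_name = ms, state = k),
        error = function(e) {
          warning("mixed model skipped for state ", k, " ", ms, ": ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(m)) models[[paste0("state", k, "_", ms)]] <- m
    }
  }
  screen <- interaction_screen_and_stratify(models, wide, alpha = alpha)
  list(models = models, screen = screen)
}
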