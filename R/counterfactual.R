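#' Tau-step-ahead counterfactual prediction under a treatment plan
#'
#' Estimates potential outcomes under a planned sequence of future
#' treatments: the one-step conditional forecaster is iterated, conditioning
#' each step on the next planned treatment token and appending the
#' prediction to the rolling history. Under the usual counterfactual
#' assumptions (consistency, positivity, sequential ignorability) plus the
#' conditional-mean-estimation assumption, each step approximates the
#' conditional mean of the next outcome given history and treatment.
#'
#' @param fit Fitted `"tcedit"`.
#' @param history A [trajectory] in raw units.
#' @param planned Character vector of length `tau`: treatment token per
#'   future step (`NA` for no treatment).
#' @param tau Projection horizon (>= 1); defaults to `length(planned)`.
#' @param hist_end History-end position (default end of trajectory).
#' @return V x tau matrix of predicted outcomes (raw units).
#' @export
tau_step_predict <- function(fit, history, planned, tau = length(planned),
                             hist_end = ncol(history$values)) {
  stopifnot(is_count(tau), tau >= 1L, length(planned) == tau)
  roll <- truncate_trajectory(history, hist_end)
  V <- nrow(roll$values)
  out <- matrix(NA_real_, V, tau, dimnames = list(roll$variables, NULL))
  for (k in seq_len(tau)) {
    t_next <- next_time(roll$times)
    cond <- if (is.na(planned[k])) NULL else planned[k]
    pr <- predict(fit, roll, target_time = t_next, condition = cond,
                  hist_end = ncol(roll$values))
    out[, k] <- pr$prediction
    roll <- append_step(roll, pr$prediction, t_next, condition = planned[k])
  }
  out
}

#' Specify a direct intervention on temporal concepts
#'
#' @param factors Named numeric vector of strictly positive multiplicative
#'   factors, names = target variables (e.g. `c(glucose = 0.5)` to halve
#'   the glucose rate).
#' @param steps Rollout length T for [intervened_rollout()].
#' @return Object of class `"intervention_spec"`.
#' @export
intervention_spec <- function(factors, steps = 10L) {
  stopifnot(is.numeric(factors), length(factors) >= 1L, all(factors > 0),
            !is.null(names(factors)), is_count(steps), steps >= 1L)
  structure(list(factors = factors, steps = as.integer(steps)),
            class = "intervention_spec")
}

#' Read / write an intervention spec as JSON
#' @param spec An `"intervention_spec"`.
#' @param path File path.
#' @return `write_intervention_spec` returns `path`; `read_intervention_spec`
#'   the spec.
#' @export
write_intervention_spec <- function(spec, path) {
  jsonlite::write_json(list(factors = as.list(spec$factors), steps = spec$steps),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intervention_spec
#' @export
read_intervention_spec <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  intervention_spec(unlist(s$factors), steps = s$steps)
}

#' Intervene directly on a temporal concept
#'
#' Multiplies the targeted concept entries by their factors; untargeted
#' entries are returned bit-unchanged. Because the decoder is
#' multiplicative, a factor f on variable k scales k's one-step prediction
#' by exactly f.
#'
#' @param concept Named (or variable-ordered) numeric concept vector.
#' @param spec An [intervention_spec()].
#' @param variables Variable names aligning `concept` when it is unnamed.
#' @return The intervened concept `c^I`.
#' @export
intervene_concept <- function(concept, spec, variables = names(concept)) {
  if (is.null(variables)) stop_tce("concept has no variable names; pass `variables`")
  idx <- match(names(spec$factors), variables)
  if (anyNA(idx))
    stop_tce("unknown intervention variable(s): %s",
             paste(names(spec$factors)[is.na(idx)], collapse = ", "))
  out <- concept
  out[idx] <- out[idx] * spec$factors
  out
}

#' Generate a counterfactual trajectory by sustained concept intervention
#'
#' For each of `steps` rollout steps: the concept is recomputed from the
#' current rolling history, the intervention factors are re-applied
#' (persistent intervention), the decoder generates the next values, and
#' the step is appended. The input history is never modified.
#'
#' @param fit Fitted `"tcedit"`.
#' @param history A [trajectory] in raw units.
#' @param spec An [intervention_spec()], or `NULL` for an unintervened
#'   rollout.
#' @param steps Number of generated steps (defaults to `spec$steps`).
#' @param condition Optional condition token supplied at every step.
#' @param hist_end History-end position.
#' @return A [trajectory] of the `steps` generated values (raw units).
#' @export
intervened_rollout <- function(fit, history, spec = NULL, steps = spec$steps %||% 10L,
                               condition = NULL, hist_end = ncol(history$values)) {
  stopifnot(is_count(steps), steps >= 1L)
  roll <- truncate_trajectory(history, hist_end)
  scaled_spec <- fit$scaling
  vars <- fit$config$variables
  gen_vals <- matrix(NA_real_, length(vars), steps, dimnames = list(vars, NULL))
  gen_times <- roll$times[0L]
  for (k in seq_len(steps)) {
    t_next <- next_time(roll$times)
    scaled <- apply_scaling(scaled_spec, roll)
    fc <- forecast(fit, scaled, hist_end = ncol(roll$values),
                   condition = condition, target_time = t_next)
    cI <- fc$concept
    names(cI) <- vars
    if (!is.null(spec)) cI <- intervene_concept(cI, spec, variables = vars)
    x_last <- last_observed(scaled, ncol(roll$values))
    pred_w <- decode_concept(cI, x_last, counters = fit$counters)
    pred <- invert_scaling(scaled_spec, pred_w)
    gen_vals[, k] <- pred
    gen_times <- c(gen_times, t_next)
    roll <- append_step(roll, pred, t_next)
  }
  trajectory(paste0(history$entity_id, ":generated"), gen_vals,
             times = gen_times, variables = vars)
}

#' R-squared similarity between a generated and a reference trajectory
#'
#' Aligns the two trajectories by step index (truncating to the common
#' length), variance-normalizes each shared variable by the reference's
#' mean and standard deviation, then pools cells into a single coefficient
#' of determination of the reference against the generated values. Higher
#' is more similar; 1 means identical, 0 matches predicting the reference's
#' per-variable mean, negative values indicate anti-correlation. A
#' zero-variance reference yields `NA` (undefined), not an error.
#'
#' @param generated,reference [trajectory] objects.
#' @param variables Shared variables to compare (default: intersection).
#' @return Scalar R-squared similarity.
#' @export
cohort_similarity <- function(generated, reference,
                              variables = intersect(generated$variables,
                                                    reference$variables)) {
  if (!length(variables)) stop_tce("no shared variables to compare")
  L <- min(ncol(generated$values), ncol(reference$values))
  num <- 0; den <- 0; any_var <- FALSE
  for (v in variables) {
    g <- generated$values[match(v, generated$variables), seq_len(L)]
    r <- reference$values[match(v, reference$variables), seq_len(L)]
    mu <- mean(r); sdr <- stats::sd(r)
    if (!is.finite(sdr) || sdr == 0) next
    any_var <- TRUE
    gz <- (g - mu) / sdr; rz <- (r - mu) / sdr
    num <- num + sum((rz - gz)^2)
    den <- den + sum((rz - mean(rz))^2)
  }
  if (!any_var || den <= 0) return(NA_real_)
  1 - num / den
}
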