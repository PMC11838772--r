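#' SimpleLinear ablation: last observation carried forward
#'
#' The ablated editor whose temporal concepts are all ones: the prediction
#' equals the latest observation for any target time and any condition.
#' Exactly equivalent to [decode_concept()] with a unit concept.
#'
#' @param x_last Numeric length-V vector of latest observed values.
#' @return `x_last`, unchanged.
#' @export
simple_linear_forecast <- function(x_last) {
  decode_concept(rep(1, length(x_last)), x_last)
}

#' Fit a vector-autoregression baseline
#'
#' Pooled ordinary-least-squares VAR(p): `x_t = nu + A_1 x_(t-1) + ... +
#' A_p x_(t-p) + e_t`, one-step squared error minimized jointly across
#' entities. Requires fully observed, regularly sampled trajectories. The
#' baseline ignores conditions entirely.
#'
#' @param trajectories List of fully observed [trajectory] objects.
#' @param p Lag order (default 1).
#' @return Object of class `"var_model"` with `A` (list of p V x V
#'   coefficient matrices), `intercept`, `p`, `variables`.
#' @export
fit_var <- function(trajectories, p = 1L) {
  stopifnot(is_count(p), p >= 1L)
  vars <- trajectories[[1L]]$variables
  V <- length(vars)
  Xs <- list(); Ys <- list()
  for (tr in trajectories) {
    if (!all(tr$mask)) stop_tce("VAR requires fully observed trajectories")
    T_ <- ncol(tr$values)
    if (T_ < p + 1L) stop_tce("lag order p=%d needs at least p+1=%d time steps (entity '%s' has %d)",
                              p, p + 1L, tr$entity_id, T_)
    for (t in (p + 1L):T_) {
      Xs[[length(Xs) + 1L]] <- c(1, unlist(lapply(seq_len(p), function(l) tr$values[, t - l])))
      Ys[[length(Ys) + 1L]] <- tr$values[, t]
    }
  }
  X <- do.call(rbind, Xs); Y <- do.call(rbind, Ys)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient VAR design; using pseudo-inverse", call. = FALSE)
    B <- MASS::ginv(X) %*% Y
  } else {
    B <- qr.coef(qx, Y)
  }
  A <- lapply(seq_len(p), function(l) {
    m <- t(B[(2L + (l - 1L) * V):(1L + l * V), , drop = FALSE])
    dimnames(m) <- list(vars, vars); m
  })
  structure(list(A = A, intercept = as.numeric(B[1L, ]), p = as.integer(p),
                 variables = vars), class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model: VAR(%d), %d variables>\n", x$p, length(x$variables)))
  invisible(x)
}

#' Iterate a fitted VAR forward
#'
#' Feeds predictions back into the recurrence for `steps` steps. Divergence
#' (overflow) is reported as infinite predictions and iteration continues --
#' the instability of rolled-out linear models at long horizons is itself a
#' documented behaviour, not an error.
#'
#' @param model A `"var_model"`.
#' @param history V x L numeric matrix (L >= p) of the most recent values.
#' @param steps Number of steps to roll out.
#' @return V x steps matrix of predictions.
#' @export
var_rollout <- function(model, history, steps) {
  stopifnot(is_count(steps), steps >= 1L)
  history <- as.matrix(history)
  if (ncol(history) < model$p) stop_tce("history shorter than lag order p=%d", model$p)
  V <- length(model$variables)
  buf <- history[, ncol(history) - seq_len(model$p) + 1L, drop = FALSE]  # lag 1 first
  out <- matrix(NA_real_, V, steps, dimnames = list(model$variables, NULL))
  for (k in seq_len(steps)) {
    x <- model$intercept
    for (l in seq_len(model$p)) x <- x + model$A[[l]] %*% buf[, l]
    x <- as.numeric(x)
    x[!is.finite(x)] <- Inf * sign(x[!is.finite(x)] + 0)  # keep sign of overflow
    x[is.nan(x)] <- Inf
    out[, k] <- x
    if (model$p > 1L) buf[, 2L:model$p] <- buf[, 1L:(model$p - 1L), drop = FALSE]
    buf[, 1L] <- x
  }
  out
}

#' Serialize / restore a VAR baseline as JSON
#'
#' @param model A `"var_model"`.
#' @param path File path.
#' @return `write_var` returns `path` invisibly; `read_var` the model.
#' @export
write_var <- function(model, path) {
  jsonlite::write_json(list(p = model$p, variables = model$variables,
                            intercept = model$intercept,
                            A = lapply(model$A, function(m) as.numeric(m))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_var
#' @export
read_var <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  V <- length(s$variables)
  if (!is.list(s$A)) s$A <- list(as.numeric(s$A))
  A <- lapply(seq_len(s$p), function(l) {
    m <- matrix(as.numeric(s$A[[l]]), V, V)
    dimnames(m) <- list(s$variables, s$variables); m
  })
  structure(list(A = A, intercept = as.numeric(s$intercept), p = as.integer(s$p),
                 variables = s$variables), class = "var_model")
}

#' Autoregressive conditional rollout of a one-step forecaster
#'
#' The non-concept comparator path: to reach a target `gap` steps ahead, the
#' one-step forecaster is applied `gap` times, each prediction appended to
#' the rolling history (times advance by one step), with the condition token
#' supplied at every step. The input history is never mutated.
#'
#' @param fit A fitted `"tcedit"` (typically `head = "direct"`, but any
#'   one-step conditional forecaster works).
#' @param history A [trajectory] in raw units.
#' @param condition Condition token or `NULL`.
#' @param gap Number of steps to roll forward (>= 1).
#' @param hist_end History-end position (default: end of trajectory).
#' @return List with `prediction` (raw units, the final step) and
#'   `intermediates` (V x gap matrix of all rolled steps, raw units).
#' @export
autoregressive_conditional_forecast <- function(fit, history, condition = NULL,
                                                gap, hist_end = ncol(history$values)) {
  stopifnot(is_count(gap), gap >= 1L)
  roll <- truncate_trajectory(history, hist_end)
  V <- nrow(roll$values)
  out <- matrix(NA_real_, V, gap, dimnames = list(roll$variables, NULL))
  for (k in seq_len(gap)) {
    t_next <- next_time(roll$times)
    pr <- predict(fit, roll, target_time = t_next, condition = condition,
                  hist_end = ncol(roll$values))
    out[, k] <- pr$prediction
    roll <- append_step(roll, pr$prediction, t_next)
  }
  list(prediction = out[, gap], intermediates = out)
}

## ---- small trajectory helpers shared with the counterfactual module -------

truncate_trajectory <- function(tr, i) {
  trajectory(tr$entity_id, tr$values[, seq_len(i), drop = FALSE],
             times = tr$times[seq_len(i)],
             mask = tr$mask[, seq_len(i), drop = FALSE],
             variables = tr$variables,
             conditions = if (is.null(tr$conditions)) NULL else tr$conditions[seq_len(i)])
}

## next timestamp: step index + 1, or last time + median spacing
next_time <- function(times) {
  if (inherits(times, "POSIXct")) {
    times[length(times)] + stats::median(diff(as.numeric(times)))
  } else {
    times[length(times)] + if (length(times) > 1L) stats::median(diff(times)) else 1
  }
}

append_step <- function(tr, values, time, condition = NA_character_) {
  trajectory(tr$entity_id, cbind(tr$values, values),
             times = c(tr$times, time),
             mask = cbind(tr$mask, rep(TRUE, nrow(tr$values))),
             variables = tr$variables,
             conditions = if (is.null(tr$conditions)) NULL else c(tr$conditions, condition))
}
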