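#' @export
print.tcedit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Temporal-concept sequence editor (%s encoder%s)\n",
              cfg$encoder, if (cfg$head == "direct") ", direct regression head" else ""))
  cat(sprintf("  variables: %s\n", paste(cfg$variables, collapse = ", ")))
  cat(sprintf("  d_h = %d, ffn = %s, horizons = {%s}%s\n", cfg$d_h, cfg$ffn,
              paste(x$horizons, collapse = ","),
              if (x$lambda > 0) sprintf(", balancing lambda = %g", x$lambda) else ""))
  cat(sprintf("  trained %d epochs (best %d), best validation Huber loss %.6f\n",
              length(x$report$train_loss), x$report$best_epoch, x$report$best_val_loss))
  invisible(x)
}

#' @export
summary.tcedit <- function(object, ...) {
  out <- list(fit = object, metrics = object$report$metrics,
              n_train = length(object$entities$train),
              n_val = length(object$entities$validation))
  class(out) <- "summary.tcedit"
  out
}

#' @export
print.summary.tcedit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  entities: %d train / %d validation\n", x$n_train, x$n_val))
  cat("Held-out validation metrics (raw units):\n")
  print(round(x$metrics$overall, 5))
  if (nrow(x$metrics$per_gap) > 1L) { cat("Per gap:\n"); print(round(x$metrics$per_gap, 5)) }
  invisible(x)
}

#' @export
coef.tcedit <- function(object, component = NULL, ...) {
  if (is.null(component)) return(object$params)
  object$params[[component]]
}

#' Predict (edit) a trajectory at a future time
#'
#' One-step conditional generation: given a history window, a condition
#' token and a target time, returns the raw-unit prediction together with
#' the temporal concept used, its raw-unit counterpart (the implied
#' per-variable rate of change `x_hat / x_last` in data units), and the
#' working-range values. Exactly one decoder application regardless of the
#' horizon.
#'
#' @param object Fitted `"tcedit"`.
#' @param newdata A [trajectory] in raw units.
#' @param target_time Time to forecast at (strictly after the history end).
#' @param condition Condition token id or `NULL`.
#' @param hist_end History-end position (default: last position whose time
#'   precedes `target_time`).
#' @param ... Unused.
#' @return List with `prediction` (raw units, named by variable), `concept`
#'   (working range), `implied_rate` (raw-unit rate `prediction / x_last`),
#'   `h_x`.
#' @export
predict.tcedit <- function(object, newdata, target_time, condition = NULL,
                           hist_end = NULL, ...) {
  stopifnot(inherits(newdata, "trajectory"))
  if (is.null(hist_end)) {
    hist_end <- max(which(as.numeric(newdata$times) < as.numeric(target_time)))
    if (!is.finite(hist_end)) stop_tce("target_time precedes all history times")
  }
  scaled <- apply_scaling(object$scaling, newdata)
  fc <- forecast(object, scaled, hist_end = hist_end, condition = condition,
                 target_time = target_time)
  x_last_raw <- invert_scaling(object$scaling, last_observed(scaled, hist_end))
  pred_raw <- invert_scaling(object$scaling, fc$prediction)
  names(pred_raw) <- object$config$variables
  list(prediction = pred_raw, concept = fc$concept,
       implied_rate = pred_raw / x_last_raw, h_x = fc$h_x,
       prediction_working = fc$prediction)
}

#' @export
residuals.tcedit <- function(object, trajectories = NULL, ...) {
  m <- object$report$metrics
  if (is.null(trajectories)) {
    ## residual summary is only stored via metrics; recompute requires data
    stop_tce("supply the validation trajectories to compute residuals")
  }
  w <- collect_windows(trajectories, object$min_history, object$horizons)
  pw <- predict_windows(object, trajectories, w)
  r <- pw$truth - pw$pred
  r[pw$mask == 0] <- NA
  colnames(r) <- object$config$variables
  r
}

#' @export
plot.tcedit <- function(x, ...) {
  tl <- x$report$train_loss; vl <- x$report$val_loss
  graphics::matplot(cbind(tl, vl), type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "Huber loss", ...)
  graphics::abline(v = x$report$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Simulate forward from a fitted editor
#'
#' Rolls the one-step editor forward `steps` steps from the end of
#' `trajectory`, optionally under a condition token and/or a concept
#' intervention (see [intervened_rollout()], which this wraps).
#'
#' @param object Fitted `"tcedit"`.
#' @param nsim Number of replicate rollouts (the model is deterministic, so
#'   replicates are identical; provided for generic compatibility).
#' @param seed Ignored (deterministic model); present for the generic.
#' @param trajectory Seed history in raw units.
#' @param steps Number of steps to generate.
#' @param condition Condition token or `NULL`.
#' @param spec Optional [intervention_spec()].
#' @param ... Unused.
#' @return A [trajectory] of the generated steps (raw units).
#' @export
simulate.tcedit <- function(object, nsim = 1, seed = NULL, trajectory, steps = 10L,
                            condition = NULL, spec = NULL, ...) {
  intervened_rollout(object, trajectory, spec = spec, steps = steps,
                     condition = condition)
}
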