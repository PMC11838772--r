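## batched prediction over explicit windows; returns raw-unit predictions,
## truths, masks, working-range concepts, and h_x rows
predict_windows <- function(fit, trajectories, windows) {
  scaled <- lapply(trajectories, function(tr) apply_scaling(fit$scaling, tr))
  pack <- pack_trajectories(scaled)
  w <- windows
  w$zi <- match(ifelse(is.na(w$condition), fit$table$null_token, w$condition),
                fit$table$tokens)
  if (anyNA(w$zi)) stop_tce("unknown condition token in evaluation windows")
  w$row <- seq_len(nrow(w))
  V <- fit$config$V
  pred <- matrix(NA_real_, nrow(w), V); conc <- matrix(NA_real_, nrow(w), V)
  hx <- matrix(NA_real_, nrow(w), fit$config$d_h)
  truth <- matrix(NA_real_, nrow(w), V); msk <- matrix(0, nrow(w), V)
  for (b in batch_plan(w, 4096L)) {
    bb <- make_batch(pack, fit$table$Z, b)
    fw <- tce_forward(fit$params, fit$config, bb, grad = FALSE)
    pred_raw <- t(invert_scaling(fit$scaling, t(fw$pred)))
    truth_raw <- t(invert_scaling(fit$scaling, t(bb$Y)))
    pred[b$row, ] <- pred_raw
    if (!is.null(fw$concept)) conc[b$row, ] <- fw$concept
    hx[b$row, ] <- fw$hx
    truth[b$row, ] <- truth_raw
    msk[b$row, ] <- bb$Wm
    if (fit$config$head == "concept")
      fit$counters$n_decode <- (fit$counters$n_decode %||% 0L) + bb$n
  }
  list(windows = w, pred = pred, truth = truth, mask = msk, concept = conc, hx = hx)
}

metric_row <- function(truth, pred, mask) {
  keep <- mask > 0
  t_ <- truth[keep]; p_ <- pred[keep]
  mae <- mean(abs(t_ - p_))
  rmse <- sqrt(mean((t_ - p_)^2))
  sst <- sum((t_ - mean(t_))^2)
  r2 <- if (sst <= 0) NA_real_ else 1 - sum((t_ - p_)^2) / sst
  c(MAE = mae, RMSE = rmse, R2 = r2, n = sum(keep))
}

#' Evaluate editing accuracy of a fitted model
#'
#' Computes MAE, RMSE and R-squared over mask-true target cells in raw
#' (unscaled) units, overall and broken down by gap (immediate vs each
#' delayed horizon) and by target position. R-squared on zero-variance truth
#' is reported as `NA` (undefined), not an error.
#'
#' @param fit A fitted `"tcedit"` object.
#' @param trajectories Trajectories to evaluate on (raw units; should be
#'   disjoint from training entities for honest estimates).
#' @param horizons Gaps to enumerate (ignored when `windows` is given).
#' @param min_history Minimum history length.
#' @param windows Optional explicit window data.frame from
#'   [make_edit_windows()] (with a `traj` index column).
#' @return An object of class `"tce_metrics"`: list with `overall`,
#'   `per_gap` and `per_time` data.frames.
#' @export
evaluate_edits <- function(fit, trajectories, horizons = fit$horizons,
                           min_history = fit$min_history, windows = NULL) {
  if (is.null(windows)) windows <- collect_windows(trajectories, min_history, horizons)
  pw <- predict_windows(fit, trajectories, windows)
  overall <- as.data.frame(t(metric_row(pw$truth, pw$pred, pw$mask)))
  per_gap <- do.call(rbind, lapply(split(seq_len(nrow(windows)), pw$windows$gap), function(i) {
    data.frame(gap = pw$windows$gap[i[1L]],
               t(metric_row(pw$truth[i, , drop = FALSE], pw$pred[i, , drop = FALSE],
                            pw$mask[i, , drop = FALSE])))
  }))
  per_time <- do.call(rbind, lapply(split(seq_len(nrow(windows)), pw$windows$target), function(i) {
    data.frame(target = pw$windows$target[i[1L]],
               t(metric_row(pw$truth[i, , drop = FALSE], pw$pred[i, , drop = FALSE],
                            pw$mask[i, , drop = FALSE])))
  }))
  structure(list(overall = overall, per_gap = per_gap, per_time = per_time),
            class = "tce_metrics")
}

#' @export
print.tce_metrics <- function(x, ...) {
  cat("Editing metrics (raw units):\n")
  print(round(x$overall, 5))
  if (nrow(x$per_gap) > 1L) {
    cat("Per gap:\n"); print(round(x$per_gap, 5))
  }
  invisible(x)
}

#' Prediction metrics for arbitrary forecasts
#'
#' Convenience wrapper for pooled MAE / RMSE / R-squared over mask-true
#' cells.
#'
#' @param truth,pred Numeric vectors or matrices of equal shape.
#' @param mask Logical/numeric of the same shape (default all observed).
#' @return Named numeric vector `MAE`, `RMSE`, `R2`, `n`.
#' @export
edit_metrics <- function(truth, pred, mask = NULL) {
  if (is.null(mask)) mask <- array(1, dim = dim(as.matrix(truth)) %||% length(truth))
  metric_row(as.numeric(truth), as.numeric(pred), as.numeric(mask))
}
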