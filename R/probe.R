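#' Held-out treatment-probe accuracy of a fitted encoder
#'
#' Measures how much information about the assigned next treatment remains
#' in the sequence representation `h_x`: a fresh multinomial-logistic probe
#' is fitted on training-entity representations and scored on held-out
#' entities. Under successful gradient-reversal balancing the accuracy
#' drops toward the majority-class rate (the co-trained adversarial head
#' itself is anti-informative and is not a fair readout).
#'
#' @param fit Fitted `"tcedit"`.
#' @param trajectories The full trajectory collection the fit was trained
#'   on (condition labels attached).
#' @param min_history Minimum history length for probe windows.
#' @return Named vector: `accuracy` (held-out probe accuracy) and
#'   `majority` (held-out majority-class rate).
#' @export
treatment_probe_accuracy <- function(fit, trajectories, min_history = fit$min_history) {
  ids <- vapply(trajectories, `[[`, "", "entity_id")
  get_hx <- function(which_ids) {
    trs <- trajectories[match(which_ids, ids)]
    w <- collect_windows(trs, min_history, 1L)
    pw <- predict_windows(fit, trs, w)
    lab <- ifelse(is.na(w$condition), fit$table$null_token, w$condition)
    list(hx = pw$hx, lab = lab)
  }
  tr <- get_hx(fit$entities$train)
  va <- get_hx(fit$entities$validation)
  lv <- sort(unique(c(tr$lab, va$lab)))
  df_tr <- data.frame(lab = factor(tr$lab, levels = lv), tr$hx)
  fitted <- utils::capture.output(
    m <- nnet::multinom(lab ~ ., data = df_tr, maxit = 200L,
                        MaxNWts = 100000L, trace = FALSE))
  pred <- stats::predict(m, newdata = data.frame(va$hx))
  c(accuracy = mean(as.character(pred) == va$lab),
    majority = max(table(va$lab)) / length(va$lab))
}
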