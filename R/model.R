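#' Build an untrained temporal-concept editing model
#'
#' The model composes four parts: a sequence encoder F (gated recurrent or
#' single-head self-attention) summarizing the history window into `h_x`; a
#' condition adapter H mapping a frozen condition embedding `z_s` to `h_s`; a
#' concept encoder E producing the temporal concept
#' `c = GELU(FFN(h_x * (delta + h_s)))` (element-wise product; the
#' feedforward projection maps `d_h` to V and may be disabled, in which case
#' `d_h` must equal V); and a multiplicative concept decoder G with
#' `x_hat = c * x_last`. An optional treatment-classifier head on `h_x`
#' supports gradient-reversal balancing.
#'
#' @param variables Character vector of the V variable names the model edits.
#' @param table A [condition_table()] of frozen condition embeddings.
#' @param d_h Hidden dimension (even; shared across submodules).
#' @param encoder `"gru"` (default) or `"attention"`.
#' @param ffn Keep the feedforward projection in the concept encoder
#'   (default `TRUE`). Without it `d_h` must equal `length(variables)`.
#' @param head `"concept"` (the temporal-concept bottleneck) or `"direct"`
#'   (a plain regression head used by the autoregressive comparator).
#' @param n_class Number of treatment classes for the balancing classifier
#'   head; 0 (default) omits the head.
#' @param huber_delta Huber-loss knee, default 1.
#' @param seed Integer seed for parameter initialization (fan-in uniform).
#' @return An object of class `"tce_model"`.
#' @export
tce_model <- function(variables, table, d_h = 64L, encoder = c("gru", "attention"),
                      ffn = TRUE, head = c("concept", "direct"), n_class = 0L,
                      huber_delta = 1, seed = 1L) {
  encoder <- match.arg(encoder)
  head <- match.arg(head)
  V <- length(variables)
  stopifnot(V >= 1L, is_count(d_h), d_h >= 2L)
  if (d_h %% 2L != 0L) stop_tce("d_h must be even (sinusoidal year component)")
  if (!ffn && head == "concept" && d_h != V)
    stop_tce("without the FFN projection d_h (%d) must equal V (%d)", d_h, V)
  d_in <- 2L * V + d_h
  cfg <- list(V = V, d_h = as.integer(d_h), d_z = table$d_z, d_in = d_in,
              encoder = encoder, ffn = isTRUE(ffn), head = head,
              n_class = as.integer(n_class), huber_delta = huber_delta,
              variables = variables)
  set.seed(seed)
  params <- list()
  if (encoder == "gru") {
    for (nm in c("Wz", "Wr", "Wn")) params[[nm]] <- init_mat(d_in, d_h)
    for (nm in c("Uz", "Ur", "Un")) params[[nm]] <- init_mat(d_h, d_h)
    for (nm in c("bz", "br", "bn")) params[[nm]] <- numeric(d_h)
  } else {
    for (nm in c("Wq", "Wk", "Wv")) params[[nm]] <- init_mat(d_in, d_h)
    params$Wo <- init_mat(d_h, d_h)
    params$bo <- numeric(d_h)
  }
  params$Wa <- init_mat(table$d_z, d_h)
  params$ba <- numeric(d_h)
  params$Emonth <- init_embed(12L, d_h)
  params$Edate <- init_embed(31L, d_h)
  params$Ehour <- init_embed(24L, d_h)
  if (ffn || head == "direct") {
    params$Wf <- init_mat(d_h, V)
    ## start at the identity concept (GELU(z)=1 at z ~ 1.1447), i.e. the
    ## model begins as last-observation-carried-forward
    params$bf <- if (head == "concept") rep(gelu_unit_preimage(), V) else numeric(V)
  }
  if (n_class > 0L) {
    set.seed(seed + 1000003L)  # independent stream: head init must not
    params$Wc <- init_mat(d_h, n_class)  # perturb the main parameter draws
    params$bc <- numeric(n_class)
  }
  structure(list(params = params, config = cfg, table = table,
                 counters = new.env(parent = emptyenv())),
            class = "tce_model")
}

## z with GELU(z) = 1, solved once numerically
gelu_unit_preimage <- function() {
  stats::uniroot(function(z) gelu(z) - 1, c(1, 2), tol = 1e-12)$root
}

#' @export
print.tce_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<tce_model: V=%d, d_h=%d, encoder=%s, head=%s, ffn=%s%s>\n",
              cfg$V, cfg$d_h, cfg$encoder, cfg$head, cfg$ffn,
              if (cfg$n_class > 0L) sprintf(", %d-class balancing head", cfg$n_class) else ""))
  invisible(x)
}

## ---- user-facing forward primitives ---------------------------------------

## build a single-sample batch from a trajectory window (scaled values)
single_batch <- function(model, traj_scaled, hist_end, target_time, z_row,
                         y = NULL, ymask = NULL) {
  V <- model$config$V
  L <- hist_end
  X <- lapply(seq_len(L), function(t) matrix(traj_scaled$values[, t], 1L, V))
  M <- lapply(seq_len(L), function(t) matrix(as.numeric(traj_scaled$mask[, t]), 1L, V))
  comp <- lapply(seq_len(L), function(t) time_components(traj_scaled$times[t]))
  xlast <- last_observed(traj_scaled, hist_end)
  list(n = 1L, L = L, X = X, M = M, comp = comp,
       comp_i = comp[[L]], comp_j = time_components(target_time),
       Z = z_row, Xlast = matrix(xlast, 1L, V),
       Y = if (is.null(y)) matrix(0, 1L, V) else matrix(y, 1L, V),
       Wm = if (is.null(ymask)) matrix(0, 1L, V) else matrix(as.numeric(ymask), 1L, V),
       cls = NULL)
}

## per-variable last observed value at or before position i (0 if none)
last_observed <- function(traj, i) {
  vapply(seq_len(nrow(traj$values)), function(v) {
    obs <- which(traj$mask[v, seq_len(i)])
    if (length(obs)) traj$values[v, max(obs)] else 0
  }, numeric(1L))
}

#' Encode a history window into a sequence representation
#'
#' @param model A `"tce_model"` or fitted `"tcedit"`.
#' @param history A [trajectory] (already in the model's working range if it
#'   came from raw data; see [apply_scaling()]).
#' @param hist_end Last history position (defaults to the full trajectory).
#' @return Numeric vector `h_x` of dimension `d_h`.
#' @export
encode_sequence <- function(model, history, hist_end = ncol(history$values)) {
  if (hist_end < 1L) stop_tce("empty history window")
  if (!any(history$mask[, seq_len(hist_end)])) stop_tce("history window has no observed step")
  b <- single_batch(model, history, hist_end, history$times[hist_end],
                    matrix(0, 1L, model$config$d_z))
  drop(encoder_forward(model$params, model$config, b)$hx)
}

#' Encode a temporal concept from its three ingredients
#'
#' `c = GELU(FFN(h_x * (delta + h_s)))`; without the FFN, `c = GELU(h_x *
#' (delta + h_s))`. Every entry is bounded below by the GELU infimum
#' (about -0.17).
#'
#' @inheritParams encode_sequence
#' @param h_x Sequence representation.
#' @param delta Time-delta embedding.
#' @param h_s Adapted condition representation.
#' @return Numeric length-V concept vector.
#' @export
encode_concept <- function(model, h_x, delta, h_s) {
  p <- h_x * combine_time_condition(delta, h_s)
  if (model$config$ffn) p <- drop(p %*% model$params$Wf) + model$params$bf
  gelu(p)
}

#' Apply a temporal concept to the latest observation
#'
#' The concept decoder G: `x_hat = c * x_last`, element-wise and exact. An
#' all-ones concept reproduces `x_last` (last observation carried forward).
#'
#' @param concept Numeric length-V concept vector.
#' @param x_last Numeric length-V vector of values at the end of history
#'   (working range).
#' @param counters Optional environment whose `n_decode` field is
#'   incremented (invocation instrumentation).
#' @return Numeric length-V prediction.
#' @export
decode_concept <- function(concept, x_last, counters = NULL) {
  if (length(concept) != length(x_last))
    stop_tce("concept length %d != x_last length %d", length(concept), length(x_last))
  if (!is.null(counters))
    counters$n_decode <- (counters$n_decode %||% 0L) + 1L
  concept * x_last
}

#' One-step conditional forecast at an arbitrary future time
#'
#' Composes the sequence encoder, time-delta embedding, condition adapter
#' and concept encoder/decoder: a single decoder application regardless of
#' how far `target_time` lies beyond the history (one-step delayed editing).
#' Operates in the working range; the fitted [predict.tcedit()] method wraps
#' this with scaling and returns raw units.
#'
#' @inheritParams encode_sequence
#' @param condition Condition token id, or `NULL` for the null condition.
#' @param target_time Time `t_j`, strictly after the history-end time.
#' @return List with `prediction` (length-V, working range), `concept`, and
#'   `h_x`.
#' @export
forecast <- function(model, history, hist_end = ncol(history$values),
                     condition = NULL, target_time) {
  if (as.numeric(target_time) <= as.numeric(history$times[hist_end]))
    stop_tce("target_time must be strictly after the history-end time")
  model$counters$n_forecast <- (model$counters$n_forecast %||% 0L) + 1L
  h_x <- encode_sequence(model, history, hist_end)
  delta <- drop(time_delta(model, history$times[hist_end], target_time))
  h_s <- adapt_condition(model, condition)
  concept <- encode_concept(model, h_x, delta, h_s)
  x_last <- last_observed(history, hist_end)
  pred <- decode_concept(concept, x_last, counters = model$counters)
  list(prediction = pred, concept = concept, h_x = h_x)
}

#' Huber loss over mask-true coordinates
#'
#' Per coordinate, with residual `a = truth - prediction`: `0.5 a^2` when
#' `|a| <= delta`, else `delta (|a| - 0.5 delta)`; averaged over mask-true
#' coordinates. Continuous and once-differentiable at the knee.
#'
#' @param truth,prediction Numeric vectors of equal length.
#' @param mask Logical vector; at least one `TRUE`.
#' @param delta Knee parameter, default 1.
#' @return Scalar loss.
#' @export
huber_loss <- function(truth, prediction, mask = rep(TRUE, length(truth)), delta = 1) {
  stopifnot(delta > 0, length(truth) == length(prediction))
  if (!any(mask)) stop_tce("all-false mask: no supervised targets")
  a <- (truth - prediction)[mask]
  l <- ifelse(abs(a) <= delta, 0.5 * a^2, delta * (abs(a) - 0.5 * delta))
  mean(l)
}
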