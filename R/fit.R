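## Packing a trajectory collection into dense arrays for batched training.
## A[k, t, v] layout; shorter trajectories are right-padded (padding is never
## addressed because windows only reference valid positions).
pack_trajectories <- function(trajs_scaled) {
  nK <- length(trajs_scaled)
  V <- nrow(trajs_scaled[[1L]]$values)
  Tmax <- max(vapply(trajs_scaled, function(tr) ncol(tr$values), 1L))
  X <- array(0, c(nK, Tmax, V)); M <- array(0, c(nK, Tmax, V)); Lo <- array(0, c(nK, Tmax, V))
  Mo <- matrix(1L, nK, Tmax); Da <- matrix(1L, nK, Tmax)
  Ho <- matrix(1L, nK, Tmax); Yr <- matrix(0, nK, Tmax)
  for (k in seq_len(nK)) {
    tr <- trajs_scaled[[k]]
    T_ <- ncol(tr$values)
    X[k, seq_len(T_), ] <- t(tr$values)
    M[k, seq_len(T_), ] <- t(tr$mask) * 1
    ## last-observation-carried-forward values for the decoder input
    locf <- tr$values
    for (t in seq_len(T_)[-1L])
      locf[, t] <- ifelse(tr$mask[, t], tr$values[, t], locf[, t - 1L])
    Lo[k, seq_len(T_), ] <- t(locf)
    cp <- time_components(tr$times)
    Mo[k, seq_len(T_)] <- cp$month; Da[k, seq_len(T_)] <- cp$date
    Ho[k, seq_len(T_)] <- cp$hour; Yr[k, seq_len(T_)] <- cp$year
  }
  list(X = X, M = M, Lo = Lo, Mo = Mo, Da = Da, Ho = Ho, Yr = Yr, V = V, nK = nK)
}

## assemble one batch from window rows sharing the same hist_end
make_batch <- function(pack, Ztab, w) {
  n <- nrow(w); L <- w$hist_end[1L]; V <- pack$V
  ks <- w$traj; js <- w$target
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, n, V)
  X <- vector("list", L); M <- vector("list", L); comp <- vector("list", L)
  for (t in seq_len(L)) {
    X[[t]] <- as_mat(pack$X[ks, t, ])
    M[[t]] <- as_mat(pack$M[ks, t, ])
    comp[[t]] <- list(month = pack$Mo[ks, t], date = pack$Da[ks, t],
                      hour = pack$Ho[ks, t], year = pack$Yr[ks, t])
  }
  tri <- function(a, tt) vapply(seq_len(V), function(v) a[cbind(ks, tt, v)], numeric(n))
  list(n = n, L = L, X = X, M = M, comp = comp,
       comp_i = comp[[L]],
       comp_j = list(month = pack$Mo[cbind(ks, js)], date = pack$Da[cbind(ks, js)],
                     hour = pack$Ho[cbind(ks, js)], year = pack$Yr[cbind(ks, js)]),
       Z = Ztab[w$zi, , drop = FALSE],
       Xlast = as_mat(tri(pack$Lo, w$hist_end)),
       Y = as_mat(tri(pack$X, js)),
       Wm = as_mat(tri(pack$M, js)),
       cls = if ("cls" %in% names(w)) w$cls else NULL)
}

## split window rows into batches: group by history length, chunk by size
batch_plan <- function(windows, batch_size, order = seq_len(nrow(windows))) {
  w <- windows[order, , drop = FALSE]
  groups <- split(seq_len(nrow(w)), w$hist_end)
  plan <- list()
  for (g in groups) {
    nb <- ceiling(length(g) / batch_size)
    chunk <- split(g, rep(seq_len(nb), each = batch_size, length.out = length(g)))
    plan <- c(plan, lapply(chunk, function(idx) w[idx, , drop = FALSE]))
  }
  plan
}

#' Training control parameters
#'
#' @param lr Adam learning rate.
#' @param batch_size Maximum batch size.
#' @param epochs Maximum epochs.
#' @param patience Consecutive non-improving validation epochs tolerated
#'   before stopping (0 stops at the first non-improving epoch).
#' @param val_fraction Fraction of entities held out for validation (split
#'   is by entity; validation entities never enter training batches).
#' @param huber_delta Huber-loss knee.
#' @param seed Master seed for every random draw (split, initialization,
#'   shuffling, horizon sampling).
#' @return A list of class `"tce_control"`.
#' @export
tce_control <- function(lr = 3e-3, batch_size = 256L, epochs = 40L, patience = 8L,
                        val_fraction = 0.2, huber_delta = 1, seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1L, epochs >= 1L, patience >= 0L,
            val_fraction > 0, val_fraction < 1, huber_delta > 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, huber_delta = huber_delta,
                 seed = as.integer(seed)), class = "tce_control")
}

#' Fit a temporal-concept sequence-editing model
#'
#' Trains the concept-bottleneck forecaster on immediate and/or delayed edit
#' windows drawn from a collection of trajectories: the model learns, for a
#' history window, target time and condition token, a per-variable
#' multiplicative rate (the temporal concept) that maps the latest
#' observation to the target in one generation step. Training minimizes the
#' Huber loss over observed target coordinates (Adam, early stopping on
#' entity-held-out validation loss). Delayed horizons are resampled
#' uniformly from `horizons` per window each epoch. Runs are deterministic
#' given `control$seed`.
#'
#' @param trajectories List of [trajectory] objects (raw units; scaling onto
#'   the positive working range is fitted internally on training entities).
#' @param table A [condition_table()]; built automatically from the tokens
#'   present in the data when `NULL`.
#' @param horizons Integer gaps to train on (1 = immediate editing).
#' @param min_history Minimum history length per window.
#' @param d_h Hidden dimension.
#' @param encoder `"gru"` or `"attention"`.
#' @param ffn Keep the feedforward projection in the concept encoder.
#' @param head `"concept"` (default) or `"direct"` (plain regression head;
#'   used for the autoregressive comparator).
#' @param eps_pos Lower end of the scaled working range.
#' @param balance `NULL`, or `list(lambda = ...)` to co-train a treatment
#'   classifier on `h_x` through a gradient-reversal connection scaled by
#'   `lambda` (`lambda = 0` trains the classifier without influencing the
#'   encoder, bit-identical to an unbalanced run).
#' @param control A [tce_control()] list.
#' @param verbose Print per-epoch losses.
#' @return An object of class `c("tcedit", "tce_model")` with elements
#'   `params`, `config`, `table`, `scaling`, `report` (loss curves, best
#'   epoch, validation metrics) and the entity split.
#' @export
tcedit <- function(trajectories, table = NULL, horizons = 1L, min_history = 4L,
                   d_h = 64L, encoder = "gru", ffn = TRUE,
                   head = c("concept", "direct"), eps_pos = 0.01,
                   balance = NULL, control = tce_control(), verbose = FALSE) {
  head <- match.arg(head)
  stopifnot(length(trajectories) >= 2L)
  lapply(trajectories, validate_trajectory)
  vars <- trajectories[[1L]]$variables
  horizons <- sort(unique(as.integer(horizons)))

  if (is.null(table)) {
    toks <- unique(stats::na.omit(unlist(lapply(trajectories, `[[`, "conditions"))))
    table <- condition_table(toks, seed = control$seed)
  }

  ## entity-level train/validation split
  set.seed(control$seed)
  nK <- length(trajectories)
  n_val <- max(1L, round(control$val_fraction * nK))
  val_idx <- sort(sample.int(nK, n_val))
  train_idx <- setdiff(seq_len(nK), val_idx)
  if (!length(train_idx)) stop_tce("no training entities left after validation split")

  scaling <- fit_scaling(trajectories[train_idx], eps_pos = eps_pos)
  scaled <- lapply(trajectories, function(tr) apply_scaling(scaling, tr))
  pack <- pack_trajectories(scaled)

  lambda <- 0
  n_class <- 0L
  ramp <- TRUE
  if (!is.null(balance)) {
    lambda <- balance$lambda %||% 1
    ramp <- balance$ramp %||% TRUE
    n_class <- length(table$tokens)
    if (n_class < 2L) {
      warning("single-treatment dataset: balancing skipped", call. = FALSE)
      lambda <- 0; n_class <- 0L
    }
  }

  model <- tce_model(vars, table, d_h = d_h, encoder = encoder, ffn = ffn,
                     head = head, n_class = n_class,
                     huber_delta = control$huber_delta, seed = control$seed + 1L)
  cfg <- model$config
  params <- model$params

  windows_for <- function(idx, hset) {
    w <- collect_windows(trajectories[idx], min_history, hset)
    w$traj <- idx[w$traj]
    w$zi <- match(ifelse(is.na(w$condition), table$null_token, w$condition), table$tokens)
    if (anyNA(w$zi)) stop_tce("condition token in data missing from table")
    if (n_class > 0L) w$cls <- w$zi
    w
  }
  ## training uses base windows; a gap is resampled per window each epoch
  train_base <- windows_for(train_idx, 1L)   # gap column rewritten per epoch
  val_w <- windows_for(val_idx, horizons)

  feasible <- lapply(seq_len(nrow(train_base)), function(r) {
    T_ <- ncol(trajectories[[train_base$traj[r]]]$values)
    horizons[train_base$hist_end[r] + horizons <= T_]
  })
  keep <- lengths(feasible) > 0L
  train_base <- train_base[keep, , drop = FALSE]
  feasible <- feasible[keep]
  if (!nrow(train_base)) stop_tce("no feasible training windows for the given horizons")

  resample_gaps <- function() {
    g <- vapply(feasible, function(f) if (length(f) == 1L) f else sample(f, 1L), 1L)
    w <- train_base
    w$gap <- g
    w$target <- w$hist_end + g
    ## condition token in force on arrival at the (resampled) target
    w$condition <- vapply(seq_len(nrow(w)), function(r) {
      cond <- trajectories[[w$traj[r]]]$conditions
      if (is.null(cond)) NA_character_ else cond[w$target[r] - 1L]
    }, character(1L))
    w$zi <- match(ifelse(is.na(w$condition), table$null_token, w$condition), table$tokens)
    if (n_class > 0L) w$cls <- w$zi
    w
  }

  val_plan <- batch_plan(val_w, control$batch_size)
  val_loss_of <- function(p) {
    tot <- 0; wt <- 0; cls_ok <- 0; cls_n <- 0
    for (b in val_plan) {
      bb <- make_batch(pack, table$Z, b)
      fw <- tce_forward(p, cfg, bb, lambda = 0, grad = FALSE)
      tot <- tot + fw$loss * sum(bb$Wm); wt <- wt + sum(bb$Wm)
      if (!is.na(fw$acc_cls)) { cls_ok <- cls_ok + fw$acc_cls * bb$n; cls_n <- cls_n + bb$n }
    }
    list(loss = tot / wt, cls_acc = if (cls_n > 0) cls_ok / cls_n else NA_real_)
  }

  opt <- adam_init(params)
  set.seed(control$seed + 2L)
  train_curve <- numeric(0); val_curve <- numeric(0); cls_curve <- numeric(0)
  best <- list(loss = Inf, params = params, epoch = 0L)
  bad <- 0L
  for (ep in seq_len(control$epochs)) {
    ## adversarial strength warm-up (standard gradient-reversal schedule):
    ## the reversed gradient ramps from 0 to lambda so the encoder first
    ## learns the dynamics, then sheds treatment information
    lambda_ep <- if (ramp && lambda > 0)
      lambda * (2 / (1 + exp(-10 * ep / control$epochs)) - 1) else lambda
    w_ep <- resample_gaps()
    plan <- batch_plan(w_ep, control$batch_size, order = sample.int(nrow(w_ep)))
    tot <- 0; wt <- 0
    for (bi in seq_along(plan)) {
      bb <- make_batch(pack, table$Z, plan[[bi]])
      fw <- tce_forward(params, cfg, bb, lambda = lambda_ep, grad = TRUE)
      if (!is.finite(fw$loss))
        stop_tce("non-finite training loss at epoch %d, batch %d (entities %s)",
                 ep, bi, paste(unique(plan[[bi]]$entity_id), collapse = ","))
      ## the classifier head trains at a faster rate than the encoder so
      ## its held-out accuracy reflects the information in h_x, not its
      ## own convergence lag
      st <- adam_step(params, fw$grads, opt, lr = control$lr,
                      lr_mult = if (n_class > 0L) list(Wc = 8, bc = 8) else NULL)
      params <- st$params; opt <- st$state
      tot <- tot + fw$loss * sum(bb$Wm); wt <- wt + sum(bb$Wm)
    }
    vl <- val_loss_of(params)
    train_curve[ep] <- tot / wt
    val_curve[ep] <- vl$loss
    cls_curve[ep] <- vl$cls_acc
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f%s", ep, train_curve[ep], vl$loss,
                      if (!is.na(vl$cls_acc)) sprintf("  cls-acc %.3f", vl$cls_acc) else ""))
    if (vl$loss < best$loss - 1e-12) {
      best <- list(loss = vl$loss, params = params, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > control$patience) break
    }
  }

  fit <- structure(list(
    params = best$params, config = cfg, table = table, scaling = scaling,
    counters = model$counters,
    control = control, horizons = horizons, min_history = as.integer(min_history),
    lambda = lambda,
    entities = list(train = vapply(trajectories[train_idx], `[[`, "", "entity_id"),
                    validation = vapply(trajectories[val_idx], `[[`, "", "entity_id")),
    report = list(train_loss = train_curve, val_loss = val_curve,
                  val_cls_acc = cls_curve, best_epoch = best$epoch,
                  best_val_loss = best$loss)),
    class = c("tcedit", "tce_model"))
  fit$report$metrics <- evaluate_edits(fit, trajectories[val_idx], horizons = horizons,
                                       min_history = min_history)
  fit
}
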