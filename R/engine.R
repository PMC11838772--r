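## Batched forward/backward engine.
##
## All networks here are written against BLAS matrix ops with the batch in
## rows: a batch of n edit windows sharing history length L is processed as L
## sequential (n x d) matrix updates for the gated recurrent encoder, or a
## per-sample attention pass for the self-attention encoder. Gradients are
## derived by hand (reverse-mode) and checked against finite differences in
## the test suite.

## per-step encoder input: [values, mask, time embedding]
step_input <- function(params, cfg, Xt, Mt, comp) {
  cbind(Xt * Mt, Mt, time_embed(params, comp, cfg$d_h))
}

encoder_forward <- function(params, cfg, batch, keep_cache = FALSE) {
  if (cfg$encoder == "gru") gru_forward(params, cfg, batch, keep_cache)
  else attn_forward(params, cfg, batch, keep_cache)
}

gru_forward <- function(params, cfg, batch, keep_cache) {
  n <- batch$n; L <- batch$L; d_h <- cfg$d_h
  h <- matrix(0, n, d_h)
  cache <- if (keep_cache) vector("list", L) else NULL
  for (t in seq_len(L)) {
    U <- step_input(params, cfg, batch$X[[t]], batch$M[[t]], batch$comp[[t]])
    z <- sigmoid(U %*% params$Wz + h %*% params$Uz + rep(params$bz, each = n))
    r <- sigmoid(U %*% params$Wr + h %*% params$Ur + rep(params$br, each = n))
    g <- tanh(U %*% params$Wn + (r * h) %*% params$Un + rep(params$bn, each = n))
    hn <- (1 - z) * h + z * g
    if (keep_cache) cache[[t]] <- list(U = U, hprev = h, z = z, r = r, g = g)
    h <- hn
  }
  list(hx = h, cache = cache)
}

gru_backward <- function(params, cfg, batch, cache, dhx, gr) {
  n <- batch$n; V <- cfg$V; d_h <- cfg$d_h
  dh <- dhx
  for (t in rev(seq_len(batch$L))) {
    cc <- cache[[t]]
    dz <- dh * (cc$g - cc$hprev)
    dg <- dh * cc$z
    dhprev <- dh * (1 - cc$z)
    dgpre <- dg * (1 - cc$g^2)
    gr$Wn <- gr$Wn + crossprod(cc$U, dgpre)
    gr$Un <- gr$Un + crossprod(cc$r * cc$hprev, dgpre)
    gr$bn <- gr$bn + colSums(dgpre)
    drh <- dgpre %*% t(params$Un)
    dr <- drh * cc$hprev
    dhprev <- dhprev + drh * cc$r
    dzpre <- dz * cc$z * (1 - cc$z)
    drpre <- dr * cc$r * (1 - cc$r)
    gr$Wz <- gr$Wz + crossprod(cc$U, dzpre)
    gr$Uz <- gr$Uz + crossprod(cc$hprev, dzpre)
    gr$bz <- gr$bz + colSums(dzpre)
    gr$Wr <- gr$Wr + crossprod(cc$U, drpre)
    gr$Ur <- gr$Ur + crossprod(cc$hprev, drpre)
    gr$br <- gr$br + colSums(drpre)
    dhprev <- dhprev + dzpre %*% t(params$Uz) + drpre %*% t(params$Ur)
    dU <- dzpre %*% t(params$Wz) + drpre %*% t(params$Wr) + dgpre %*% t(params$Wn)
    gr <- time_grad(gr, batch$comp[[t]], dU[, (2L * V + 1L):(2L * V + d_h), drop = FALSE])
    dh <- dhprev
  }
  gr
}

## single-head scaled dot-product self-attention with mean-pooled readout;
## per-sample loop (used for small batches / as the alternative encoder)
attn_forward <- function(params, cfg, batch, keep_cache) {
  n <- batch$n; L <- batch$L; d_h <- cfg$d_h
  Us <- lapply(seq_len(L), function(t)
    step_input(params, cfg, batch$X[[t]], batch$M[[t]], batch$comp[[t]]))
  hx <- matrix(0, n, d_h)
  cache <- if (keep_cache) vector("list", n) else NULL
  for (s in seq_len(n)) {
    U <- do.call(rbind, lapply(Us, function(u) u[s, ]))   # L x d_in
    Q <- U %*% params$Wq; K <- U %*% params$Wk; Vm <- U %*% params$Wv
    A <- softmax_rows(Q %*% t(K) / sqrt(d_h))
    Zc <- A %*% Vm
    pooled <- colMeans(Zc)
    pre <- drop(pooled %*% params$Wo) + params$bo
    hx[s, ] <- gelu(pre)
    if (keep_cache) cache[[s]] <- list(U = U, Q = Q, K = K, Vm = Vm, A = A,
                                       Zc = Zc, pooled = pooled, pre = pre)
  }
  list(hx = hx, cache = list(per_sample = cache, Us = Us))
}

attn_backward <- function(params, cfg, batch, cache, dhx, gr) {
  n <- batch$n; L <- batch$L; V <- cfg$V; d_h <- cfg$d_h
  dUs <- lapply(seq_len(L), function(t) matrix(0, n, 2L * V + d_h))
  for (s in seq_len(n)) {
    cc <- cache$per_sample[[s]]
    dpre <- dhx[s, ] * gelu_prime(cc$pre)
    gr$Wo <- gr$Wo + tcrossprod(cc$pooled, dpre)
    gr$bo <- gr$bo + dpre
    dpooled <- drop(params$Wo %*% dpre)
    dZc <- matrix(rep(dpooled / L, each = L), L, d_h)
    dA <- dZc %*% t(cc$Vm)
    dVm <- crossprod(cc$A, dZc)
    ## softmax rows backward
    dS <- cc$A * (dA - rowSums(dA * cc$A))
    dS <- dS / sqrt(d_h)
    dQ <- dS %*% cc$K
    dK <- crossprod(dS, cc$Q)
    gr$Wq <- gr$Wq + crossprod(cc$U, dQ)
    gr$Wk <- gr$Wk + crossprod(cc$U, dK)
    gr$Wv <- gr$Wv + crossprod(cc$U, dVm)
    dU <- dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dVm %*% t(params$Wv)
    for (t in seq_len(L)) dUs[[t]][s, ] <- dU[t, ]
  }
  for (t in seq_len(L))
    gr <- time_grad(gr, batch$comp[[t]], dUs[[t]][, (2L * V + 1L):(2L * V + d_h), drop = FALSE])
  gr
}

## accumulate time-embedding-table gradients (year component is fixed)
time_grad <- function(gr, comp, dH) {
  gr$Emonth <- accumulate_rows(gr$Emonth, comp$month, dH)
  gr$Edate <- accumulate_rows(gr$Edate, comp$date, dH)
  gr$Ehour <- accumulate_rows(gr$Ehour, comp$hour, dH)
  gr
}

zero_grads <- function(params) lapply(params, function(p) p * 0)

## full forward (+ optional backward) over one batch.
## Returns main Huber loss, classifier loss/accuracy when labels present,
## predictions and concepts (working range), and gradients.
tce_forward <- function(params, cfg, batch, lambda = 0, grad = FALSE) {
  n <- batch$n; d_h <- cfg$d_h
  enc <- encoder_forward(params, cfg, batch, keep_cache = grad)
  hx <- enc$hx
  Apre <- batch$Z %*% params$Wa + rep(params$ba, each = n)
  Hs <- gelu(Apre)
  Hi <- time_embed(params, batch$comp_i, d_h)
  Hj <- time_embed(params, batch$comp_j, d_h)
  S <- (Hj - Hi) + Hs
  P <- hx * S
  if (cfg$head == "concept") {
    if (cfg$ffn) {
      Cpre <- P %*% params$Wf + rep(params$bf, each = n)
    } else {
      Cpre <- P
    }
    Cn <- gelu(Cpre)
    pred <- Cn * batch$Xlast
  } else {
    Cpre <- NULL; Cn <- NULL
    pred <- P %*% params$Wf + rep(params$bf, each = n)
  }

  ## Huber objective over mask-true coordinates
  a <- batch$Y - pred
  quad <- abs(a) <= cfg$huber_delta
  l <- ifelse(quad, 0.5 * a^2, cfg$huber_delta * (abs(a) - 0.5 * cfg$huber_delta))
  wsum <- sum(batch$Wm)
  if (wsum == 0) stop_tce("no supervised targets in batch (all-false mask)")
  loss <- sum(l * batch$Wm) / wsum

  loss_cls <- NA_real_; acc_cls <- NA_real_; probs <- NULL
  if (!is.null(batch$cls)) {
    logits <- hx %*% params$Wc + rep(params$bc, each = n)
    probs <- softmax_rows(logits)
    pt <- probs[cbind(seq_len(n), batch$cls)]
    loss_cls <- -mean(log(pmax(pt, 1e-12)))
    acc_cls <- mean(max.col(probs, ties.method = "first") == batch$cls)
  }

  out <- list(loss = loss, loss_cls = loss_cls, acc_cls = acc_cls,
              pred = pred, concept = Cn, hx = hx)
  if (!grad) return(out)

  gr <- zero_grads(params)
  psi <- ifelse(quad, a, cfg$huber_delta * sign(a))
  dpred <- -(psi * batch$Wm) / wsum
  if (cfg$head == "concept") {
    dC <- dpred * batch$Xlast
    dCpre <- dC * gelu_prime(Cpre)
    if (cfg$ffn) {
      gr$Wf <- gr$Wf + crossprod(P, dCpre)
      gr$bf <- gr$bf + colSums(dCpre)
      dP <- dCpre %*% t(params$Wf)
    } else {
      dP <- dCpre
    }
  } else {
    gr$Wf <- gr$Wf + crossprod(P, dpred)
    gr$bf <- gr$bf + colSums(dpred)
    dP <- dpred %*% t(params$Wf)
  }
  dhx <- dP * S
  dS <- dP * hx
  dApre <- dS * gelu_prime(Apre)
  gr$Wa <- gr$Wa + crossprod(batch$Z, dApre)
  gr$ba <- gr$ba + colSums(dApre)
  gr <- time_grad(gr, batch$comp_j, dS)
  gr <- time_grad(gr, batch$comp_i, -dS)

  if (!is.null(batch$cls)) {
    onehot <- matrix(0, n, cfg$n_class)
    onehot[cbind(seq_len(n), batch$cls)] <- 1
    dlogits <- (probs - onehot) / n
    gr$Wc <- gr$Wc + crossprod(hx, dlogits)
    gr$bc <- gr$bc + colSums(dlogits)
    ## gradient reversal: identity forward, negated (scaled) gradient into
    ## the encoder representation
    ## the reversed gradient is renormalized so that lambda expresses the
    ## adversarial force relative to the editing gradient (lambda = 1 means
    ## equal strength), keeping the objectives commensurate regardless of
    ## the working-range loss scale or the head's weight scale
    if (lambda != 0) {
      dhx_cls <- dlogits %*% t(params$Wc)
      n_main <- sqrt(sum(dhx^2)); n_cls <- sqrt(sum(dhx_cls^2))
      if (n_cls > 0)
        dhx <- dhx - (lambda * n_main / n_cls) * dhx_cls
    }
  }

  gr <- if (cfg$encoder == "gru") gru_backward(params, cfg, batch, enc$cache, dhx, gr)
        else attn_backward(params, cfg, batch, enc$cache, dhx, gr)
  out$grads <- gr
  out
}

## Adam optimizer state + step
adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      lr_mult = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    lr_nm <- if (!is.null(lr_mult) && nm %in% names(lr_mult)) lr * lr_mult[[nm]] else lr
    params[[nm]] <- params[[nm]] -
      lr_nm * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
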