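test_that("sequence encoding is deterministic, order-sensitive, finite", {
  m <- tce_model(paste0("V", 1:3), condition_table("c1", d_z = 4L), d_h = 12L, seed = 3L)
  tr <- random_trajectory(V = 3, T_steps = 6, seed = 2)
  expect_identical(encode_sequence(m, tr), encode_sequence(m, tr))
  ## permuting two distinct steps changes h_x for the recurrent encoder
  tr2 <- tr
  tr2$values[, c(2, 4)] <- tr2$values[, c(4, 2)]
  expect_false(isTRUE(all.equal(encode_sequence(m, tr), encode_sequence(m, tr2))))
  ## single-step window is accepted
  h1 <- encode_sequence(m, tr, hist_end = 1L)
  expect_true(all(is.finite(h1)))
  ## an all-unobserved window is rejected
  tr3 <- tr
  tr3$mask[] <- FALSE
  expect_error(encode_sequence(m, tr3), "no observed step")
})

test_that("concepts respect the GELU floor and zero propagation", {
  expect_identical(gelu(0), 0)
  m <- tce_model(paste0("V", 1:4), condition_table("c1", d_z = 4L), d_h = 8L, seed = 5L)
  set.seed(6)
  for (r in 1:50) {
    cc <- encode_concept(m, rnorm(8, sd = 3), rnorm(8, sd = 3), rnorm(8, sd = 3))
    expect_gte(min(cc), -0.17)
  }
  ## identity-FFN trace: h_s = 0, delta = 0 -> c = GELU(0) = 0
  mi <- tce_model(paste0("V", 1:4), condition_table("c1", d_z = 4L), d_h = 4L, seed = 5L)
  mi$params$Wf <- diag(4)
  mi$params$bf <- rep(0, 4)
  expect_identical(encode_concept(mi, c(1, 2, 3, 4), rep(0, 4), rep(0, 4)), rep(0, 4))
  ## no-FFN configuration requires d_h == V
  expect_error(tce_model(paste0("V", 1:3), condition_table("c1", d_z = 4L),
                         d_h = 8L, ffn = FALSE), "must equal V")
})

test_that("the concept decoder is exact element-wise multiplication", {
  x <- c(3, 8)
  expect_identical(decode_concept(c(2, 0.5), x), c(6, 4))
  expect_identical(decode_concept(rep(1, 2), x), x)
  expect_error(decode_concept(c(1, 1, 1), x), "length")
  ## oracle-concept inverse property
  set.seed(4)
  for (r in 1:20) {
    x_last <- runif(6, 0.01, 1)
    x_target <- runif(6, 0.01, 1)
    out <- decode_concept(x_target / x_last, x_last)
    expect_rel_equal(out, x_target, 1e-12)
  }
})

test_that("forecast composes the modules in one decoder application", {
  tf <- tiny_fit()
  fit <- tf$fit
  tr <- apply_scaling(fit$scaling, tf$sim$trajectories[[2]])
  before <- tr$values
  fit$counters$n_decode <- 0L
  fc <- forecast(fit, tr, hist_end = 4L, condition = "cond1", target_time = tr$times[12])
  expect_identical(fit$counters$n_decode, 1L)   # far target, single decode
  expect_identical(tr$values, before)           # history never mutated
  ## a different condition yields a different concept and prediction
  fc2 <- forecast(fit, tr, hist_end = 4L, condition = "cond2", target_time = tr$times[12])
  expect_false(isTRUE(all.equal(fc$concept, fc2$concept)))
  expect_false(isTRUE(all.equal(fc$prediction, fc2$prediction)))
  ## target at or before history end is invalid
  expect_error(forecast(fit, tr, hist_end = 4L, target_time = tr$times[4]),
               "strictly after")
})

test_that("Huber loss matches closed forms and is smooth at the knee", {
  expect_equal(huber_loss(0.5, 0), 0.125)
  expect_equal(huber_loss(2, 0), 1.5)
  expect_equal(huber_loss(1, 0), 0.5)
  ## continuity and once-differentiability at |a| = delta
  h <- function(a) huber_loss(a, 0)
  eps <- 1e-7
  expect_equal(h(1 - eps), h(1 + eps), tolerance = 1e-6)
  slope_lo <- (h(1) - h(1 - eps)) / eps
  slope_hi <- (h(1 + eps) - h(1)) / eps
  expect_equal(slope_lo, slope_hi, tolerance = 1e-5)
  expect_equal(slope_lo, 1, tolerance = 1e-5)
  ## masking and validation
  expect_equal(huber_loss(c(1, 100), c(0.5, 0), mask = c(TRUE, FALSE)), 0.125)
  expect_error(huber_loss(1, 0, mask = FALSE), "all-false mask")
})

test_that("analytic gradients match finite differences for both encoders", {
  ns <- asNamespace("tcedit")
  set.seed(42)
  mk_batch <- function(V, dh, L = 3L, n = 2L, dz = 4L) {
    comp <- function() list(month = sample(1:12, n, TRUE), date = sample(1:31, n, TRUE),
                            hour = sample(1:24, n, TRUE), year = sample(0:3, n, TRUE))
    list(n = n, L = L,
         X = lapply(1:L, function(t) matrix(runif(n * V, .2, .9), n, V)),
         M = lapply(1:L, function(t) matrix(1, n, V)),
         comp = cmp <- lapply(1:L, function(t) comp()),
         comp_i = cmp[[L]], comp_j = comp(),
         Z = matrix(rnorm(n * dz), n, dz),
         Xlast = matrix(runif(n * V, .2, .9), n, V),
         Y = matrix(runif(n * V, .2, .9), n, V),
         Wm = matrix(1, n, V), cls = NULL)
  }
  for (encdr in c("gru", "attention")) {
    for (head in c("concept", "direct")) {
      m <- tce_model(c("V1", "V2"), condition_table(c("a", "b"), d_z = 4L, seed = 3L),
                     d_h = 6L, encoder = encdr, head = head, seed = 9L)
      b <- mk_batch(2L, 6L)
      fw <- ns$tce_forward(m$params, m$config, b, grad = TRUE)
      for (nm in names(m$params)) {
        idx <- sample(length(m$params[[nm]]), min(4L, length(m$params[[nm]])))
        for (i in idx) {
          eps <- 1e-6
          pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
          pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
          num <- (ns$tce_forward(pp, m$config, b)$loss -
                    ns$tce_forward(pm, m$config, b)$loss) / (2 * eps)
          expect_equal(fw$grads[[nm]][i], num, tolerance = 1e-4,
                       label = sprintf("%s/%s grad %s[%d]", encdr, head, nm, i))
        }
      }
    }
  }
})

test_that("the gradient-reversal unit is identity forward, negated backward", {
  x <- 1.7
  expect_identical(gr_forward(x), x)
  ## scalar toy: L(y) = y^2 with y = gr_forward(x)
  L <- function(x) gr_forward(x)^2
  fd <- (L(x + 1e-6) - L(x - 1e-6)) / 2e-6
  expect_equal(gr_backward(fd, lambda = 0.7), -0.7 * 2 * x, tolerance = 1e-5)
  expect_identical(gr_backward(c(1, -2), lambda = 1), c(-1, 2))
})
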