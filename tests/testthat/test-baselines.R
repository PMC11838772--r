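test_that("SimpleLinear is exactly last observation carried forward", {
  expect_identical(simple_linear_forecast(c(1.5, 2.5)), c(1.5, 2.5))
  set.seed(8)
  for (r in 1:20) {
    x <- runif(5, 0.01, 1)
    expect_identical(simple_linear_forecast(x), decode_concept(rep(1, 5), x))
  }
  ## on a world with unit rates and no noise its error is exactly zero
  sim <- simulate_multiplicative(multiplicative_world(
    n_variables = 3L, n_entities = 5L, T_steps = 8L, rate_range = c(1, 1),
    sigma = 0, seed = 2L))
  for (tr in sim$trajectories)
    expect_identical(max(abs(tr$values[, 8L] - simple_linear_forecast(tr$values[, 7L]))), 0)
})

test_that("VAR least squares identifies exact linear dynamics", {
  A <- matrix(c(0.7, 0.2, -0.1, 0.5), 2, 2)
  mk <- function(seed) {
    set.seed(seed)
    x <- matrix(0, 2, 40); x[, 1] <- rnorm(2)
    for (t in 1:39) x[, t + 1] <- A %*% x[, t]
    trajectory(paste0("v", seed), x)
  }
  vm <- fit_var(lapply(1:5, mk), p = 1)
  expect_lt(max(abs(vm$A[[1]] - A)), 1e-6)
  expect_lt(max(abs(vm$intercept)), 1e-6)
  ## white noise: coefficients shrink toward zero at large samples
  set.seed(3)
  wn <- trajectory("wn", matrix(rnorm(2 * 10000), 2))
  vw <- fit_var(list(wn), p = 1)
  expect_lt(max(abs(vw$A[[1]])), 0.05)
  ## validation
  short <- trajectory("s", matrix(rnorm(6), 2, 3))
  expect_error(fit_var(list(short), p = 3), "at least p\\+1")
  masked <- trajectory("m", matrix(1:4 + 0, 2, 2),
                       mask = matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  expect_error(fit_var(list(masked)), "fully observed")
  ## JSON round trip
  f <- tempfile(fileext = ".json")
  write_var(vm, f)
  vm2 <- read_var(f)
  expect_equal(vm2$A[[1]], vm$A[[1]], tolerance = 1e-12)
})

test_that("VAR rollout follows linear-systems theory", {
  hist <- matrix(c(1, -0.5), 2, 1)
  ## base case: one step equals the fitted one-step map
  A <- matrix(c(0.7, 0.2, -0.1, 0.5), 2, 2)
  vm <- structure(list(A = list(A), intercept = c(0, 0), p = 1L,
                       variables = c("V1", "V2")), class = "var_model")
  expect_equal(var_rollout(vm, hist, 1)[, 1], drop(A %*% hist), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## spectral radius < 1, zero intercept: decay toward zero
  ro <- var_rollout(vm, hist, 60)
  expect_lt(sqrt(sum(ro[, 60]^2)), 1e-3)
  ## spectral radius > 1: norms eventually grow without bound
  Au <- matrix(c(1.2, 0.1, 0, 1.1), 2, 2)
  vu <- structure(list(A = list(Au), intercept = c(0, 0), p = 1L,
                       variables = c("V1", "V2")), class = "var_model")
  nr <- apply(var_rollout(vu, hist, 50), 2, function(x) sqrt(sum(x^2)))
  expect_true(all(diff(nr[10:50]) > 0))
  expect_gt(nr[50], nr[1] * 10)
})

test_that("autoregressive conditional rollout calls the model once per step", {
  tf <- tiny_fit()
  fit <- tf$fit
  tr <- tf$sim$trajectories[[3]]
  before <- tr$values
  fit$counters$n_forecast <- 0L
  out <- autoregressive_conditional_forecast(fit, tr, condition = "cond1",
                                             gap = 4L, hist_end = 5L)
  expect_identical(fit$counters$n_forecast, 4L)
  expect_identical(tr$values, before)   # purity
  expect_identical(dim(out$intermediates), c(5L, 4L))
  ## gap = 1 reduces to a single forward call
  fit$counters$n_forecast <- 0L
  one <- autoregressive_conditional_forecast(fit, tr, condition = "cond1",
                                             gap = 1L, hist_end = 5L)
  expect_identical(fit$counters$n_forecast, 1L)
  p1 <- predict(fit, tr, target_time = tr$times[6], condition = "cond1", hist_end = 5L)
  expect_equal(one$prediction, p1$prediction, tolerance = 1e-12)
})

test_that("rolled-out one-step error compounds on a ramp, unlike one-shot decoding", {
  ## LOCF has one-step error exactly e on a linear ramp; rolling it k steps
  ## accumulates k*e, while the oracle one-shot concept is exact at any k
  slope <- 0.3
  x <- matrix(seq(1, by = slope, length.out = 12), 1)
  roll <- x[, 5]
  errs <- numeric(5)
  for (k in 1:5) {
    pred <- simple_linear_forecast(roll)
    errs[k] <- abs(x[, 5 + k] - pred)
    roll <- pred
  }
  expect_equal(errs, slope * (1:5), tolerance = 1e-12)
  one_shot <- decode_concept(x[, 10] / x[, 5], x[, 5])
  expect_equal(unname(one_shot), x[, 10], tolerance = 1e-12)
})
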