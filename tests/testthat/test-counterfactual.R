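test_that("tau-step prediction composes and reacts to the treatment plan", {
  tf <- tiny_fit()
  fit <- tf$fit
  tr <- tf$sim$trajectories[[1]]
  ## base case: tau = 1 equals one conditional forecast
  t1 <- tau_step_predict(fit, tr, planned = "cond1", hist_end = 6L)
  p1 <- predict(fit, tr, target_time = tr$times[7], condition = "cond1", hist_end = 6L)
  expect_equal(t1[, 1], p1$prediction, tolerance = 1e-12)
  ## composition: running a+b equals running a, then b from the extended history
  full <- tau_step_predict(fit, tr, planned = rep("cond2", 5), hist_end = 6L)
  partA <- tau_step_predict(fit, tr, planned = rep("cond2", 2), hist_end = 6L)
  roll <- tcedit:::truncate_trajectory(tr, 6L)
  for (k in 1:2)
    roll <- tcedit:::append_step(roll, partA[, k], tcedit:::next_time(roll$times),
                                 condition = "cond2")
  partB <- tau_step_predict(fit, roll, planned = rep("cond2", 3), hist_end = 8L)
  expect_equal(cbind(partA, partB), full, tolerance = 1e-12)
  ## two plans from the same history diverge
  alt <- tau_step_predict(fit, tr, planned = rep("cond1", 5), hist_end = 6L)
  expect_gt(max(abs(alt - full)), 0)
})

test_that("concept intervention is local, multiplicative and validated", {
  cc <- c(glucose = 1.3, wbc = 0.9, sodium = 1.05)
  spec <- intervention_spec(c(glucose = 0.5), steps = 10L)
  ci <- intervene_concept(cc, spec)
  expect_identical(ci[["glucose"]], 0.5 * cc[["glucose"]])
  expect_identical(ci[c("wbc", "sodium")], cc[c("wbc", "sodium")])  # bit-local
  expect_identical(intervene_concept(cc, intervention_spec(c(glucose = 1))), cc)
  expect_error(intervene_concept(cc, intervention_spec(c(insulin = 2))),
               "unknown intervention variable")
  ## halving a concept halves exactly that variable's decoded prediction
  x_last <- c(2.4, 1.1, 0.7)
  expect_identical(decode_concept(unname(ci), x_last)[1L],
                   0.5 * decode_concept(unname(cc), x_last)[1L])
  ## spec JSON round trip
  f <- tempfile(fileext = ".json")
  write_intervention_spec(spec, f)
  s2 <- read_intervention_spec(f)
  expect_identical(s2$factors, spec$factors)
  expect_identical(s2$steps, spec$steps)
})

test_that("sustained halving under unit concepts decays geometrically", {
  fit <- identity_fit(c("A", "B"))
  tr <- random_trajectory(V = 2, T_steps = 5, seed = 6)
  ro <- intervened_rollout(fit, tr, spec = intervention_spec(c(A = 0.5), steps = 6L))
  x0 <- tr$values[, 5L]
  expect_equal(unname(ro$values["A", ]), unname(x0[1] * 0.5^(1:6)), tolerance = 1e-8)
  expect_equal(unname(ro$values["B", ]), rep(unname(x0[2]), 6), tolerance = 1e-8)
  ## identity intervention equals the unintervened rollout; history untouched
  before <- tr$values
  r0 <- intervened_rollout(fit, tr, spec = NULL, steps = 4L)
  r1 <- intervened_rollout(fit, tr, spec = intervention_spec(c(A = 1, B = 1)), steps = 4L)
  expect_identical(r1$values, r0$values)
  expect_identical(tr$values, before)
})

test_that("intervening on a driver variable changes the driven variable", {
  cw <- memo("coupled_fit", {
    sim <- simulate_coupled_world(n_entities = 40L, T_steps = 14L, seed = 9L)
    list(sim = sim,
         fit = tcedit(sim$trajectories, horizons = 1L, min_history = 3L, d_h = 16L,
                      control = tce_control(seed = 10L, epochs = 12L, patience = 6L)))
  })
  tr <- cw$sim$trajectories[[5]]
  r0 <- intervened_rollout(cw$fit, tr, spec = NULL, steps = 6L)
  rA <- intervened_rollout(cw$fit, tr, spec = intervention_spec(c(A = 0.5)), steps = 6L)
  expect_gt(max(abs(rA$values["B", ] - r0$values["B", ])), 0)  # indirect effect
  expect_lt(max(abs(rA$values["A", 1])), r0$values["A", 1])    # direct effect down
})

test_that("lambda = 0 balancing is bit-identical to plain training", {
  sim <- tiny_sim(seed = 29)
  ctl <- tce_control(seed = 11L, epochs = 4L, patience = 2L)
  plain <- tcedit(sim$trajectories, table = sim$table, horizons = 1L,
                  min_history = 3L, d_h = 8L, control = ctl)
  bal0 <- tcedit(sim$trajectories, table = sim$table, horizons = 1L,
                 min_history = 3L, d_h = 8L, balance = list(lambda = 0), control = ctl)
  expect_identical(bal0$report$train_loss, plain$report$train_loss)
  expect_identical(bal0$report$val_loss, plain$report$val_loss)
  for (nm in names(plain$params))
    expect_identical(bal0$params[[nm]], plain$params[[nm]])
  ## the balanced run additionally carries a trained classifier head
  expect_true(all(c("Wc", "bc") %in% names(bal0$params)))
  expect_false(all(c("Wc", "bc") %in% names(plain$params)))
})

test_that("cohort similarity matches its defining cases", {
  ref <- random_trajectory("ref", V = 2, T_steps = 6, seed = 3)
  expect_equal(cohort_similarity(ref, ref), 1)
  ## per-variable mean of the reference scores exactly zero
  gen <- ref
  gen$values[] <- rowMeans(ref$values)
  expect_equal(cohort_similarity(gen, ref), 0, tolerance = 1e-12)
  ## anti-correlated pair scores negative
  anti <- ref
  anti$values <- 2 * rowMeans(ref$values) - ref$values
  expect_lt(cohort_similarity(anti, ref), 0)
  ## zero-variance reference is an undefined marker
  flat <- trajectory("flat", matrix(1, 2, 6), variables = ref$variables)
  expect_true(is.na(cohort_similarity(ref, flat)))
  expect_error(cohort_similarity(ref, trajectory("o", matrix(1:4, 2, 2),
                                                 variables = c("q1", "q2"))),
               "no shared variables")
})
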