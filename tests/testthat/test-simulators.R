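test_that("noise-free multiplicative worlds realize their rates exactly", {
  sim <- tiny_sim(seed = 5, sigma = 0)
  tr <- sim$trajectories[[4]]
  for (t in 1:(ncol(tr$values) - 1L)) {
    tok <- ifelse(is.na(tr$conditions[t]), "<none>", tr$conditions[t])
    expect_equal(tr$values[, t + 1L] / tr$values[, t], sim$rates[[tok]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  ## k-step ground-truth concept is the product of per-step rates
  k <- 4L
  expect_equal(tr$values[, 9L] / tr$values[, 5L], true_concept(sim, 4L, 5L, 9L),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## before the onset the null rate applies
  on <- sim$world$onset
  expect_true(all(is.na(tr$conditions[seq_len(on - 1L)])))
  ## determinism: identical worlds give bit-identical data
  sim2 <- tiny_sim(seed = 5, sigma = 0)
  expect_identical(sim2$trajectories[[4]]$values, tr$values)
})

test_that("counterfactual pairs share history and noise exactly", {
  w <- multiplicative_world(n_variables = 3L, n_entities = 2L, T_steps = 12L,
                            sigma = 0.1, seed = 31L)
  pr <- simulate_counterfactual_pair(w, entity_seed = 7L, "cond1", "cond2")
  d <- pr$divergence_time
  expect_identical(pr$a$values[, seq_len(d - 1L)], pr$b$values[, seq_len(d - 1L)])
  expect_gt(max(abs(pr$a$values[, 12L] - pr$b$values[, 12L])), 0)
  ## identical conditions give identical arms everywhere
  same <- simulate_counterfactual_pair(w, entity_seed = 7L, "cond1", "cond1")
  expect_identical(same$a$values, same$b$values)
  ## noise-free arms obey the closed-form log-ratio
  w0 <- multiplicative_world(n_variables = 3L, n_entities = 2L, T_steps = 12L,
                             sigma = 0, seed = 31L)
  p0 <- simulate_counterfactual_pair(w0, entity_seed = 3L, "cond1", "cond2")
  rates <- tcedit:::world_rates(w0)
  for (k in 1:3) {
    lr <- log(p0$a$values[, p0$divergence_time + k]) -
      log(p0$b$values[, p0$divergence_time + k])
    expect_equal(lr, k * (log(rates$cond1) - log(rates$cond2)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(simulate_counterfactual_pair(w, 1L, "cond1", "nope"), "unknown condition")
})

test_that("tumor dynamics: logistic regrowth, clamped underflow, determinism", {
  ## no treatment, no noise: volume rises monotonically toward K
  w0 <- tumor_world(n_patients = 2L, T_steps = 40L, gamma = 0, sigma = 0, seed = 3L)
  sim0 <- suppressMessages(simulate_tumor(w0))
  cf <- resimulate_tumor(sim0, 1L, plan = rep("notx", 39L), from = 1L)
  vol <- cf$values["volume", ]
  expect_true(all(diff(vol) > 0))
  expect_lt(max(vol), sim0$params$K[1L])
  ## determinism
  simb <- suppressMessages(simulate_tumor(w0))
  expect_identical(simb$trajectories[[1L]]$values, sim0$trajectories[[1L]]$values)
  ## brutal chemo sensitivity forces the positive floor to engage
  wf <- tumor_world(n_patients = 3L, T_steps = 20L, gamma = 0, p_treat = 0.9,
                    beta_c_mean = 3, beta_c_sd = 0.01, seed = 5L)
  expect_message(simf <- simulate_tumor(wf), "underflow")
  expect_gt(simf$n_clamped, 0L)
  expect_gte(min(vapply(simf$trajectories, function(tr) min(tr$values["volume", ]), 0)),
             wf$floor)
})

test_that("treatment assignment is unconfounded at gamma 0 and biased at high gamma", {
  sim0 <- suppressMessages(simulate_tumor(
    tumor_world(n_patients = 40L, T_steps = 30L, gamma = 0, seed = 31L)))
  expect_lt(abs(assignment_volume_correlation(sim0)), 0.05)
  sim4 <- suppressMessages(simulate_tumor(
    tumor_world(n_patients = 40L, T_steps = 30L, gamma = 4, seed = 31L)))
  expect_gt(assignment_volume_correlation(sim4), 0.3)
  ## treated steps have systematically larger recent volumes (one-sided)
  treated <- c(); recent <- c()
  for (tr in sim4$trajectories) {
    vol <- tr$values["volume", ]
    for (t in seq_len(length(vol) - 1L)) {
      treated <- c(treated, tr$conditions[t] != "notx")
      recent <- c(recent, mean(vol[max(1L, t - 4L):t]))
    }
  }
  wt <- wilcox.test(recent[treated], recent[!treated], alternative = "greater")
  expect_lt(wt$p.value, 1e-10)
})

test_that("benchmark tasks pair plans with re-simulated ground truth", {
  w <- tumor_world(n_patients = 4L, T_steps = 15L, gamma = 1, seed = 13L)
  sim <- suppressMessages(simulate_tumor(w))
  ## single-sliding: one plan per offset in the tau window
  ss <- make_benchmark_split(sim, "single-sliding", tau_max = 5L)
  expect_length(ss, 4L * 5L)
  offs <- vapply(ss[1:5], function(tk) which(tk$plan == "chemo"), 1L)
  expect_identical(sort(offs), 1:5)
  ## tau_max = 1 reduces to immediate prediction with a single treatment
  s1 <- make_benchmark_split(sim, "single-sliding", tau_max = 1L)
  expect_true(all(vapply(s1, function(tk) length(tk$plan) == 1L, TRUE)))
  ## ground truth is bit-equal to an independent re-simulation of the plan
  tk <- ss[[7L]]
  again <- resimulate_tumor(sim, tk$entity, plan = tk$plan, from = tk$hist_end)
  expect_identical(tk$truth,
                   again$values[, (tk$hist_end + 1L):(tk$hist_end + 5L)])
  ## random regime draws plans over the full token set; horizon validated
  rr <- make_benchmark_split(sim, "random", tau_max = 3L, n_random = 2L, seed = 4L)
  expect_length(rr, 4L * 2L)
  expect_true(all(unlist(lapply(rr, `[[`, "plan")) %in% tcedit:::TUMOR_TOKENS))
  expect_error(make_benchmark_split(sim, "random", tau_max = 99L), "exceeds")
})
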