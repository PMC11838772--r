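#' Define a multiplicative-dynamics world
#'
#' A synthetic generator whose ground-truth temporal concepts are known by
#' construction: per step, `x_(t+1) = r_(s_t) * x_t * exp(sigma * eta_t)`
#' with `eta_t` standard normal, where `s_t` is the condition in force on
#' the step from t to t+1. Before the (fixed) condition onset every entity
#' evolves under the null-condition rate; from the onset on, under its
#' assigned condition's rate. The true concept over a gap is the element-wise
#' product of the per-step rates.
#'
#' @param n_variables Number of variables V.
#' @param n_entities Number of entities N.
#' @param T_steps Sequence length T.
#' @param n_conditions Number of condition tokens (besides the null).
#' @param rate_range Range the per-variable rates are drawn from
#'   (multiplicative per-step rates; default 0.9 to 1.1, bounded away
#'   from 0).
#' @param sigma Log-normal observation-noise scale (0 = noise-free).
#' @param onset 1-based step index at which the assigned condition replaces
#'   the null condition (fixed onset; default just past T/3).
#' @param x0_range Range of initial values.
#' @param seed World seed; every draw is derived from it.
#' @return A list of class `"multiplicative_world"`.
#' @export
multiplicative_world <- function(n_variables = 5L, n_entities = 200L, T_steps = 30L,
                                 n_conditions = 3L, rate_range = c(0.9, 1.1),
                                 sigma = 0, onset = floor(T_steps / 3) + 1L,
                                 x0_range = c(0.8, 1.25), seed = 1L) {
  stopifnot(rate_range[1L] > 0, sigma >= 0, T_steps >= 2L, onset >= 1L)
  structure(list(V = as.integer(n_variables), N = as.integer(n_entities),
                 T_steps = as.integer(T_steps), n_conditions = as.integer(n_conditions),
                 rate_range = rate_range, sigma = sigma, onset = as.integer(onset),
                 x0_range = x0_range, seed = as.integer(seed)),
            class = "multiplicative_world")
}

## draw the per-token rate vectors for a world (null token first)
world_rates <- function(world) {
  set.seed(world$seed)
  toks <- c("<none>", paste0("cond", seq_len(world$n_conditions)))
  rates <- lapply(toks, function(tok)
    stats::runif(world$V, world$rate_range[1L], world$rate_range[2L]))
  names(rates) <- toks
  rates
}

#' Simulate a multiplicative world
#'
#' @param world A [multiplicative_world()].
#' @return A list with `trajectories` (condition labels attached: entry t of
#'   a trajectory's `conditions` is the token governing the step from t to
#'   t+1), `rates` (named list token -> true per-step rate vector), `table`
#'   (a [condition_table()] of fixed random embeddings for the tokens),
#'   `assigned` (entity -> condition token), and the `world`.
#' @export
simulate_multiplicative <- function(world) {
  rates <- world_rates(world)
  toks <- names(rates)
  table <- condition_table(setdiff(toks, "<none>"), seed = world$seed + 7L)
  set.seed(world$seed + 1L)
  assigned <- sample(setdiff(toks, "<none>"), world$N, replace = TRUE)
  vars <- paste0("V", seq_len(world$V))
  trajs <- vector("list", world$N)
  for (k in seq_len(world$N)) {
    set.seed(world$seed + 100L + k)
    s_t <- c(rep("<none>", min(world$onset - 1L, world$T_steps - 1L)),
             rep(assigned[k], max(0L, world$T_steps - world$onset)))[seq_len(world$T_steps - 1L)]
    x <- matrix(NA_real_, world$V, world$T_steps, dimnames = list(vars, NULL))
    x[, 1L] <- stats::runif(world$V, world$x0_range[1L], world$x0_range[2L])
    eta <- matrix(stats::rnorm(world$V * (world$T_steps - 1L)), world$V)
    for (t in seq_len(world$T_steps - 1L))
      x[, t + 1L] <- rates[[s_t[t]]] * x[, t] * exp(world$sigma * eta[, t])
    conds <- c(ifelse(s_t == "<none>", NA_character_, s_t), NA_character_)
    trajs[[k]] <- trajectory(sprintf("e%04d", k), x, variables = vars, conditions = conds)
  }
  names(trajs) <- vapply(trajs, `[[`, "", "entity_id")
  list(trajectories = trajs, rates = rates, table = table,
       assigned = stats::setNames(assigned, names(trajs)), world = world)
}

#' Ground-truth k-step concept of a simulated window
#'
#' The element-wise product of the generating per-step rates from position
#' `i` to position `j` (the exact rate of change `x_j / x_i` when
#' `sigma = 0`).
#'
#' @param sim Output of [simulate_multiplicative()].
#' @param entity Entity id or index.
#' @param i,j 1-based history-end and target positions, `j > i`.
#' @return Length-V numeric vector.
#' @export
true_concept <- function(sim, entity, i, j) {
  stopifnot(j > i)
  tr <- sim$trajectories[[entity]]
  steps <- i:(j - 1L)
  toks <- ifelse(is.na(tr$conditions[steps]), "<none>", tr$conditions[steps])
  Reduce(`*`, sim$rates[toks], accumulate = FALSE, init = rep(1, nrow(tr$values)))
}

#' Simulate a matched factual/counterfactual pair
#'
#' Two arms of the same entity sharing one noise stream: bit-identical under
#' the null condition before `divergence_time`, then evolving under
#' `condition_a` versus `condition_b` with the same post-divergence noise
#' draws. With `condition_a == condition_b` the arms are identical
#' everywhere.
#'
#' @param world A [multiplicative_world()].
#' @param entity_seed Per-entity seed (combined with the world seed).
#' @param condition_a,condition_b Condition tokens (must exist in the
#'   world).
#' @param divergence_time 1-based step index at which the conditions take
#'   over from the null condition.
#' @return List with trajectories `a` and `b` (condition labels attached).
#' @export
simulate_counterfactual_pair <- function(world, entity_seed, condition_a, condition_b,
                                         divergence_time = world$onset) {
  stopifnot(divergence_time >= 1L, divergence_time <= world$T_steps)
  rates <- world_rates(world)
  for (cc in c(condition_a, condition_b))
    if (!cc %in% names(rates)) stop_tce("unknown condition '%s'", cc)
  vars <- paste0("V", seq_len(world$V))
  set.seed(world$seed + 100000L + entity_seed)
  x0 <- stats::runif(world$V, world$x0_range[1L], world$x0_range[2L])
  eta <- matrix(stats::rnorm(world$V * (world$T_steps - 1L)), world$V)
  arm <- function(cond, tag) {
    s_t <- ifelse(seq_len(world$T_steps - 1L) < divergence_time, "<none>", cond)
    x <- matrix(NA_real_, world$V, world$T_steps, dimnames = list(vars, NULL))
    x[, 1L] <- x0
    for (t in seq_len(world$T_steps - 1L))
      x[, t + 1L] <- rates[[s_t[t]]] * x[, t] * exp(world$sigma * eta[, t])
    conds <- c(ifelse(s_t == "<none>", NA_character_, s_t), NA_character_)
    trajectory(sprintf("cf%05d:%s", entity_seed, tag), x, variables = vars,
               conditions = conds)
  }
  list(a = arm(condition_a, "a"), b = arm(condition_b, "b"),
       divergence_time = divergence_time)
}

#' Define and simulate a coupled driver/driven world
#'
#' A two-variable world in which variable `B` is generated from lagged
#' variable `A` (`B_(t+1) = sqrt(B_t * A_t) * exp(sigma eta)`, while `A`
#' evolves multiplicatively), used to exercise indirect effects of concept
#' interventions: editing only `A`'s concept must change `B`'s rollout
#' through the learned dynamics.
#'
#' @param n_entities,T_steps,sigma,seed As in [multiplicative_world()].
#' @param rate_a Per-step rate of the driver variable.
#' @return List with `trajectories` and the generating parameters.
#' @export
simulate_coupled_world <- function(n_entities = 60L, T_steps = 16L, sigma = 0.02,
                                   rate_a = 1.04, seed = 1L) {
  trajs <- vector("list", n_entities)
  for (k in seq_len(n_entities)) {
    set.seed(seed + 500L + k)
    x <- matrix(NA_real_, 2L, T_steps, dimnames = list(c("A", "B"), NULL))
    x[, 1L] <- stats::runif(2L, 0.8, 1.25)
    eta <- matrix(stats::rnorm(2L * (T_steps - 1L)), 2L)
    for (t in seq_len(T_steps - 1L)) {
      x[1L, t + 1L] <- rate_a * x[1L, t] * exp(sigma * eta[1L, t])
      x[2L, t + 1L] <- sqrt(x[2L, t] * x[1L, t]) * exp(sigma * eta[2L, t])
    }
    trajs[[k]] <- trajectory(sprintf("cp%04d", k), x)
  }
  names(trajs) <- vapply(trajs, `[[`, "", "entity_id")
  list(trajectories = trajs, rate_a = rate_a, sigma = sigma, seed = seed)
}

## ---- PK-PD tumor-growth benchmark -----------------------------------------

#' Define a tumor-growth world with time-varying confounding
#'
#' Daily tumor-volume dynamics under chemotherapy and radiotherapy in the
#' standard pharmacokinetic-pharmacodynamic form: logistic-type regrowth
#' plus multiplicative kill terms,
#' `V(t+1) = V(t) * (1 + rho log(K / V(t)) - beta_c C(t) - (alpha_r d(t) +
#' beta_r d(t)^2) + eps_t)`,
#' with chemo concentration `C` following single-compartment exponential
#' decay after each administration and radiotherapy dose `d` applied at
#' treatment times (linear-quadratic kill, alpha/beta = 10). Treatment
#' assignment at each step is a coin flip whose log-odds shift with the
#' recent average volume scaled by the confounding strength `gamma`
#' (`gamma = 0` is unconfounded randomization). Per-patient growth
#' parameters are drawn from the stated priors; every constant is recorded
#' in the returned world config.
#'
#' @param n_patients Number of patients.
#' @param T_steps Days simulated.
#' @param gamma Time-varying confounding strength (>= 0).
#' @param sigma Additive Gaussian noise on the growth increment.
#' @param p_treat Baseline assignment probability per therapy per day.
#' @param chemo_half_life Chemo concentration half-life in days.
#' @param radio_dose Radiotherapy dose (Gy) per administration.
#' @param K_range,rho_mean,rho_sd,beta_c_mean,beta_c_sd,alpha_r_mean,alpha_r_sd
#'   Parameter priors.
#' @param v0_range Initial-volume range.
#' @param v_ref,v_scale Center and scale of the assignment rule's volume
#'   dependence (log-odds shift `gamma * (recent - v_ref) / v_scale`).
#' @param floor Positive lower clamp for volumes (underflows are counted).
#' @param seed World seed.
#' @return A list of class `"tumor_world"` recording every constant.
#' @export
tumor_world <- function(n_patients = 200L, T_steps = 30L, gamma = 0, sigma = 0.01,
                        p_treat = 0.25, chemo_half_life = 1, radio_dose = 2,
                        K_range = c(25, 35), rho_mean = 0.07, rho_sd = 0.01,
                        beta_c_mean = 0.08, beta_c_sd = 0.01,
                        alpha_r_mean = 0.04, alpha_r_sd = 0.008,
                        v0_range = c(1, 10), v_ref = 4, v_scale = 2,
                        floor = 0.05, seed = 1L) {
  stopifnot(gamma >= 0, sigma >= 0, T_steps >= 3L)
  structure(as.list(environment()), class = "tumor_world")
}

TUMOR_TOKENS <- c("notx", "chemo", "radio", "chemo+radio")

tumor_params <- function(world) {
  set.seed(world$seed)
  n <- world$n_patients
  data.frame(
    K = stats::runif(n, world$K_range[1L], world$K_range[2L]),
    rho = pmax(0.01, stats::rnorm(n, world$rho_mean, world$rho_sd)),
    beta_c = pmax(0.01, stats::rnorm(n, world$beta_c_mean, world$beta_c_sd)),
    alpha_r = pmax(0.01, stats::rnorm(n, world$alpha_r_mean, world$alpha_r_sd)),
    v0 = stats::runif(n, world$v0_range[1L], world$v0_range[2L]))
}

## one-patient forward pass; treatments either NULL (assign by the
## confounded rule, consuming `u` uniforms) or a fixed token plan
## One-patient forward pass. Timing convention (the usual one for
## time-varying-treatment data): the treatment assigned on day t acts on the
## transition t -> t+1; the observed covariates at day t reflect treatments
## only up to day t-1 (`conc_obs[t]` is the pre-administration concentration,
## `dose_obs[t]` the radiotherapy dose given on day t-1), so the next
## assignment is never deterministically encoded in the history.
tumor_path <- function(world, par, eps, u, treatments = NULL) {
  T_ <- world$T_steps
  vol <- numeric(T_); conc_obs <- numeric(T_); dose_obs <- numeric(T_)
  tok <- character(T_ - 1L)
  vol[1L] <- par$v0
  beta_r <- par$alpha_r / 10
  n_clamp <- 0L
  decay <- exp(-log(2) / world$chemo_half_life)
  C_int <- 0  # active concentration including the day's administration
  for (t in seq_len(T_ - 1L)) {
    conc_obs[t] <- C_int * decay
    if (is.null(treatments)) {
      ## assignment log-odds shift with the recent average volume relative
      ## to the cohort's operating range, scaled by the confounding strength
      recent <- mean(vol[max(1L, t - 4L):t])
      shift <- world$gamma * (recent - world$v_ref) / world$v_scale
      p <- stats::plogis(stats::qlogis(world$p_treat) + shift)
      chemo <- u[t, 1L] < p
      radio <- u[t, 2L] < p
    } else {
      chemo <- treatments[t] %in% c("chemo", "chemo+radio")
      radio <- treatments[t] %in% c("radio", "chemo+radio")
    }
    tok[t] <- if (chemo && radio) "chemo+radio" else if (chemo) "chemo"
              else if (radio) "radio" else "notx"
    C_int <- C_int * decay + as.numeric(chemo)
    d_t <- world$radio_dose * as.numeric(radio)
    dose_obs[t + 1L] <- d_t
    growth <- par$rho * log(par$K / vol[t])
    kill <- par$beta_c * C_int + par$alpha_r * d_t + beta_r * d_t^2
    v_next <- vol[t] * (1 + growth - kill + eps[t])
    if (v_next < world$floor) { v_next <- world$floor; n_clamp <- n_clamp + 1L }
    vol[t + 1L] <- v_next
  }
  conc_obs[T_] <- C_int * decay
  list(volume = vol, conc = conc_obs, dose = dose_obs, tokens = tok, n_clamp = n_clamp)
}

#' Simulate the tumor-growth benchmark
#'
#' @param world A [tumor_world()].
#' @return A list with `trajectories` (variables `volume`, `chemo_conc`,
#'   `radio_dose`; per-step treatment tokens in `conditions`), `table`
#'   (condition embeddings for the four treatment tokens), `params`
#'   (per-patient parameters), the retained noise streams (so counterfactual
#'   arms can share them), `n_clamped`, and the `world`.
#' @export
simulate_tumor <- function(world) {
  pars <- tumor_params(world)
  n <- world$n_patients; T_ <- world$T_steps
  set.seed(world$seed + 1L)
  eps <- matrix(stats::rnorm(n * (T_ - 1L), 0, world$sigma), n)
  u <- array(stats::runif(n * (T_ - 1L) * 2L), c(n, T_ - 1L, 2L))
  table <- condition_table(TUMOR_TOKENS, seed = world$seed + 7L)
  trajs <- vector("list", n)
  n_clamped <- 0L
  for (k in seq_len(n)) {
    pp <- tumor_path(world, pars[k, ], eps[k, ], matrix(u[k, , ], ncol = 2L))
    n_clamped <- n_clamped + pp$n_clamp
    vals <- rbind(volume = pp$volume, chemo_conc = pp$conc, radio_dose = pp$dose)
    trajs[[k]] <- trajectory(sprintf("p%04d", k), vals,
                             conditions = c(pp$tokens, NA_character_))
  }
  names(trajs) <- vapply(trajs, `[[`, "", "entity_id")
  if (n_clamped > 0L)
    message(sprintf("tumor simulator: %d volume underflow(s) clamped at %g",
                    n_clamped, world$floor))
  list(trajectories = trajs, table = table, params = pars, eps = eps, u = u,
       n_clamped = n_clamped, world = world)
}

#' Re-simulate one patient under an alternative treatment plan
#'
#' Counterfactual arm: same patient parameters and the same noise stream as
#' the factual simulation, with treatments from `plan` from step
#' `from` onward (factual assignments before `from`).
#'
#' @param sim Output of [simulate_tumor()].
#' @param patient Patient index or id.
#' @param plan Character vector of treatment tokens for steps
#'   `from, from+1, ...` (recycled/truncated to the remaining steps).
#' @param from 1-based step index at which the plan replaces the factual
#'   assignments.
#' @return The counterfactual [trajectory].
#' @export
resimulate_tumor <- function(sim, patient, plan, from = 1L) {
  k <- if (is.character(patient)) match(patient, names(sim$trajectories)) else patient
  world <- sim$world
  fact <- sim$trajectories[[k]]$conditions[seq_len(world$T_steps - 1L)]
  treatments <- fact
  upto <- min(world$T_steps - 1L, from + length(plan) - 1L)
  if (from <= world$T_steps - 1L)
    treatments[from:upto] <- plan[seq_len(upto - from + 1L)]
  pp <- tumor_path(world, sim$params[k, ], sim$eps[k, ],
                   matrix(sim$u[k, , ], ncol = 2L), treatments = treatments)
  vals <- rbind(volume = pp$volume, chemo_conc = pp$conc, radio_dose = pp$dose)
  trajectory(paste0(names(sim$trajectories)[k], ":cf"), vals,
             conditions = c(pp$tokens, NA_character_))
}

#' Build counterfactual evaluation tasks from a simulated tumor cohort
#'
#' Single-sliding regime: for each history cutoff, one planned sequence per
#' offset in the tau window, applying the sliding treatment at exactly that
#' offset (no treatment elsewhere). Random regime: planned sequences drawn
#' uniformly over the treatment tokens. Every task carries the ground-truth
#' counterfactual outcomes re-simulated under its plan with the shared
#' noise stream.
#'
#' @param sim Output of [simulate_tumor()].
#' @param regime `"single-sliding"` or `"random"`.
#' @param tau_max Projection horizon.
#' @param hist_end History cutoff(s); default one cutoff at `T - tau_max`.
#' @param sliding_token Treatment applied in the single-sliding regime.
#' @param n_random Plans per (patient, cutoff) in the random regime.
#' @param seed Seed for the random regime.
#' @return List of tasks: `entity`, `hist_end`, `plan`, `truth` (V x tau
#'   matrix, raw units).
#' @export
make_benchmark_split <- function(sim, regime = c("single-sliding", "random"),
                                 tau_max, hist_end = NULL, sliding_token = "chemo",
                                 n_random = 2L, seed = 1L) {
  regime <- match.arg(regime)
  world <- sim$world
  stopifnot(is_count(tau_max), tau_max >= 1L)
  if (tau_max > world$T_steps - 1L)
    stop_tce("tau_max=%d exceeds the simulated horizon (T-1=%d)", tau_max, world$T_steps - 1L)
  if (is.null(hist_end)) hist_end <- world$T_steps - tau_max
  stopifnot(all(hist_end + tau_max <= world$T_steps), all(hist_end >= 2L))
  set.seed(seed)
  tasks <- list()
  for (k in seq_along(sim$trajectories)) {
    for (i in hist_end) {
      plans <- if (regime == "single-sliding") {
        lapply(seq_len(tau_max), function(off) {
          p <- rep("notx", tau_max); p[off] <- sliding_token; p
        })
      } else {
        lapply(seq_len(n_random), function(r)
          sample(TUMOR_TOKENS, tau_max, replace = TRUE))
      }
      for (p in plans) {
        cf <- resimulate_tumor(sim, k, plan = p, from = i)
        tasks[[length(tasks) + 1L]] <- list(
          entity = names(sim$trajectories)[k], hist_end = i, plan = p,
          truth = cf$values[, (i + 1L):(i + tau_max), drop = FALSE])
      }
    }
  }
  tasks
}

#' Assignment-volume dependence of a simulated tumor cohort
#'
#' Point-biserial correlation between the per-step indicator that any
#' treatment was assigned and the recent (5-day) average volume, pooled
#' over patient-steps. Near zero under unconfounded randomization
#' (`gamma = 0`); increasing in `gamma`.
#'
#' @param sim Output of [simulate_tumor()].
#' @return Scalar correlation.
#' @export
assignment_volume_correlation <- function(sim) {
  treated <- c(); recent <- c()
  for (tr in sim$trajectories) {
    vol <- tr$values["volume", ]
    T_ <- length(vol)
    tok <- tr$conditions[seq_len(T_ - 1L)]
    rec <- vapply(seq_len(T_ - 1L), function(t) mean(vol[max(1L, t - 4L):t]), 0)
    treated <- c(treated, as.numeric(tok != "notx"))
    recent <- c(recent, rec)
  }
  stats::cor(treated, recent)
}
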