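## Shared fixture builders. Everything is generated in code at test time;
## heavy fits used by several acceptance checks are memoised for the run.

.tce_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .tce_cache)) assign(key, force(expr), envir = .tce_cache)
  get(key, envir = .tce_cache)
}

## a tiny noise-free multiplicative world for fast unit tests
tiny_sim <- function(seed = 3L, sigma = 0, n = 20L, T_steps = 12L) {
  simulate_multiplicative(multiplicative_world(
    n_variables = 5L, n_entities = n, T_steps = T_steps, n_conditions = 3L,
    sigma = sigma, seed = seed))
}

## a quickly trained small editor on the tiny world (memoised)
tiny_fit <- function() {
  memo("tiny_fit", {
    sim <- tiny_sim()
    list(sim = sim,
         fit = tcedit(sim$trajectories, table = sim$table, horizons = 1L,
                      min_history = 3L, d_h = 16L,
                      control = tce_control(seed = 4L, epochs = 6L, patience = 3L)))
  })
}

## a hand-built identity editor: concept is exactly the unit concept
## (Wf = 0 so c = GELU(bf) = 1 up to root-finding tolerance), scaling is the
## identity map -- useful for algebraic rollout checks
identity_fit <- function(variables = c("A", "B")) {
  tab <- condition_table(character(0), d_z = 4L, seed = 1L)
  m <- tce_model(variables, tab, d_h = 8L, seed = 1L)
  m$params$Wf[] <- 0
  scaling <- structure(list(variables = variables,
                            offset = rep(0, length(variables)),
                            scale = rep(1, length(variables)), eps_pos = 0.01),
                       class = "scaling_spec")
  structure(list(params = m$params, config = m$config, table = tab,
                 scaling = scaling, counters = m$counters,
                 control = tce_control(), horizons = 1L, min_history = 1L,
                 lambda = 0,
                 entities = list(train = character(), validation = character()),
                 report = list()),
            class = c("tcedit", "tce_model"))
}

## random trajectory in raw units
random_trajectory <- function(id = "r1", V = 3L, T_steps = 8L, seed = 1L,
                              variables = NULL) {
  set.seed(seed)
  trajectory(id, matrix(runif(V * T_steps, 0.5, 2), V, T_steps),
             variables = variables)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
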