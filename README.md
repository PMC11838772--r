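# tcedit — controllable editing of multivariate longitudinal trajectories

`tcedit` is an R package for *sequence editing*: applying a condition (a
clinical intervention, a cellular perturbation) to one entity's
multivariate time series at a chosen — possibly far-future — time, and
generating the edited continuation in **one step** while preserving
history and unaffected variables.

It is built around **temporal concepts**: for a history window
`x[, t0:ti]`, a condition token `s`, and a target time `tj > ti`, the
model produces a length-`V` vector `c` of per-variable multiplicative
rates of change and decodes

```
x̂[, tj | s] = c ⊙ x[, ti],    c = GELU(FFN(h_x ⊙ (Δ(ti, tj) + h_s)))
```

where `h_x` comes from a sequence encoder (gated-recurrent by default,
self-attention as an alternative), `h_s` from a condition adapter over a
frozen condition-embedding table, and `Δ(ti, tj) = h_tj − h_ti` from a
calendar-aware time encoder. Because decoding is an element-wise product:

* a forecast at *any* horizon costs exactly one decoder call — no
  autoregressive rollout, no compounded error;
* the concept is interpretable as the rate of change `x[, tj] / x[, ti]`,
  and an all-ones concept is exactly last observation carried forward
  (the built-in `SimpleLinear` ablation);
* editing the concept directly (e.g. halving one lab test's entry)
  scales exactly that variable's prediction — the basis for
  counterfactual "what-if" trajectory generation.

The package also provides τ-step-ahead counterfactual prediction under
planned treatment sequences with optional gradient-reversal balancing, a
pooled least-squares VAR baseline and an autoregressive comparator, and
two fully synthetic benchmark generators (a multiplicative-dynamics
world with known ground-truth concepts and matched factual/counterfactual
pairs, and a pharmacokinetic–pharmacodynamic tumor-growth world with
tunable time-varying confounding), so every component is testable with no
external data. See the vignette
(`vignettes/temporal-concept-editing.Rmd`) for the model, its
assumptions, and all numerical conventions.

## Worked example

Simulate a small world whose per-condition rates are known, fit the
editor on immediate (gap 1) and delayed (gap 5) windows, then schedule a
condition five steps ahead on a held-out entity:

```r
library(tcedit)

world <- multiplicative_world(n_variables = 3, n_entities = 60, T_steps = 20,
                              n_conditions = 2, sigma = 0.02, seed = 42)
sim <- simulate_multiplicative(world)

fit <- tcedit(sim$trajectories, table = sim$table, horizons = c(1, 5),
              min_history = 4, d_h = 32,
              control = tce_control(seed = 1, epochs = 25, patience = 6))
summary(fit)
#> Temporal-concept sequence editor (gru encoder)
#>   variables: V1, V2, V3
#>   d_h = 32, ffn = TRUE, horizons = {1,5}
#>   trained 25 epochs (best 25), best validation Huber loss 0.000955
#>   entities: 48 train / 12 validation
#> Held-out validation metrics (raw units):
#>       MAE    RMSE      R2    n
#> 1 0.08425 0.11844 0.97439 1008
#> Per gap:
#>   gap     MAE    RMSE      R2   n
#> 1   1 0.05733 0.07975 0.98749 576
#> 5   5 0.12013 0.15572 0.95927 432

tr <- sim$trajectories[[fit$entities$validation[1]]]
edit <- predict(fit, tr, target_time = tr$times[13], condition = "cond2",
                hist_end = 8)
round(edit$prediction, 4)     # edited values five steps ahead, raw units
#>     V1     V2     V3
#> 2.5060 1.0065 1.0716
round(edit$implied_rate, 4)   # the learned 5-step rate of change
#>     V1     V2     V3
#> 1.2538 0.7811 1.1413
round(true_concept(sim, tr$entity_id, 8, 13), 4)  # generating ground truth
#> [1] 1.2601 0.6843 1.1672
```

The held-out `R2` of 0.96–0.99 says the editor explains most of the
variance the generator produces; the implied 5-step rates track the
ground-truth rate products variable by variable. Counterfactual
generation and direct concept surgery follow the same pattern:

```r
# halve variable V1's rate for ten generated steps
ro <- intervened_rollout(fit, tr, spec = intervention_spec(c(V1 = 0.5), steps = 10))

# τ-step potential outcomes under a planned treatment sequence
tau_step_predict(fit, tr, planned = c("cond1", "cond1", "cond2"), hist_end = 8)
```

A thin command-line interface wrapping the same functions ships at
`inst/cli/tcedit.R` (subcommands `simulate | train | edit |
counterfactual | intervene | evaluate`).

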