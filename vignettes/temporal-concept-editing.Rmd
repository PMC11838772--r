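---
title: "Temporal concepts for controllable editing of longitudinal trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal concepts for controllable editing of longitudinal trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcedit)
```

## The problem

Clinical and biological time series often need *edits*, not just forecasts:
apply an intervention (a drug, a perturbation) to one patient's or one
cell's multivariate trajectory at some chosen time — possibly far in the
future — and generate the edited continuation while leaving history and
unaffected variables alone. Autoregressive forecasters must be rolled
forward step by step to reach a delayed edit, compounding their one-step
errors; whole-sequence generative models overwrite history.

`tcedit` implements a concept-bottleneck editor. For a history window
$x_{:,t_0:t_i}$, a condition token $s$ and a target time $t_j > t_i$, the
model produces a **temporal concept** $c \in \mathbb{R}^V$ — one
multiplicative rate of change per variable — and decodes the edit in a
single generation step:

$$\hat{x}_{:,t_j}^s = c \odot x_{:,t_i}, \qquad
  c = \mathrm{GELU}\!\big(\mathrm{FFN}\big(h_x \odot (\Delta_{t_i,t_j} + h_s)\big)\big)$$

with $h_x = F(x_{:,t_0:t_i})$ from a sequence encoder,
$h_s = H(z_s)$ from a condition adapter over a *frozen* condition
embedding, and $\Delta_{t_i,t_j} = h_{t_j} - h_{t_i}$ a time-delta
embedding. Because the decoder is a plain element-wise product, the
concept is interpretable as the rate of change $x_{:,t_j}/x_{:,t_i}$, an
all-ones concept is exactly last observation carried forward (LOCF), and a
forecast at any horizon costs exactly one decoder application.

Training minimizes a Huber loss ($\delta = 1$) between
$\hat{x}_{:,t_j}^s$ and the observed target over mask-true coordinates.

## Architecture choices

* **Sequence encoder.** Two minimal members of the families commonly
  benchmarked for this task are shipped behind one contract: a
  single-layer gated recurrent unit over per-step inputs
  (values, observation mask, time embedding) with final-state readout
  (the default), and a single-head scaled-dot-product self-attention
  encoder with mean-pooled readout. Any encoder emitting a $d_h$ vector
  could be substituted.
* **Time encoder.** $h_t$ is the element-wise sum of a fixed sinusoidal
  year component (alternating sin/cos, geometric wavelengths, base
  10,000) and learned lookup tables for month (12), day of month (31) and
  hour (24). Resolution is one hour. Antisymmetry and
  $\Delta_{t,t} = 0$ hold bit-exactly; additivity
  $\Delta_{a,c} = \Delta_{a,b} + \Delta_{b,c}$ holds to machine precision
  (IEEE subtraction telescopes only up to rounding). Plain integer step
  indices are interpreted as hours from a fixed epoch and rolled over
  into the day and month indices by divmod; pinning the non-hour
  components instead would alias any sequence longer than 24 steps.
* **Condition adapter.** One affine layer plus GELU. Condition
  embeddings are supplied as a table (standing in for a frozen pretrained
  embedding model) and are never updated — the package asserts
  bit-identity across training. A reserved null token with its own fixed
  embedding represents "no condition", so pure forecasting is
  distinguishable from an all-zero embedding; keeping it frozen (the
  adapter supplies the learned part) lets the freezing contract cover the
  whole table.
* **Concept head.** The FFN is one affine layer $d_h \to V$; a
  configuration flag removes it, in which case $d_h = V$ is enforced at
  build time. The head's bias is initialized at the GELU preimage of 1,
  so an untrained model starts exactly at LOCF and learns departures from
  it — this materially speeds convergence and makes the ablation
  (`SimpleLinear`, the permanent all-ones concept) the literal starting
  point of training.
* **Working range.** The GELU bounds concepts below at
  $\approx -0.17$, and a multiplicative decoder cannot cross zero, so raw
  values are affinely mapped per variable onto $[\varepsilon, 1]$
  ($\varepsilon = 0.01$) before modelling; constant variables map to 0.5.
  The map is fitted on training entities only, inverts to $10^{-9}$
  relative error, and all reported metrics are computed after inversion.
  Concept interpretability as a raw-unit rate is exact only in the
  working range; where we compare learned concepts against generating
  rates we therefore measure the *implied raw rate*
  $\hat{x}/x_{\text{last}}$, which is the concept definition applied in
  data units.
* **Indexing.** The R API uses 1-based positions (`hist_end = i` means
  the history covers positions `1..i`), matching R convention.

## Training

Adam (default learning rate $3\times10^{-3}$, batches grouped by history
length up to 256 windows), early stopping on entity-held-out validation
Huber loss with configurable patience, and the best-validation checkpoint
returned. Validation is split *by entity*, so no entity contributes to
both sides. Delayed-editing windows share the immediate-editing code path
(only the gap differs); when several horizons are configured, each base
window resamples its gap uniformly per epoch. Every random draw — split,
initialization, shuffling, gap resampling — derives from one seed, and
reruns are bit-identical.

Missing data: unobserved cells enter the encoder as a zeroed value
channel plus an explicit mask channel, the decoder anchors on the last
*observed* value per variable, and losses/metrics are computed over
mask-true cells only.

## Counterfactual prediction and balancing

Viewing the condition token as the next treatment, iterating the one-step
editor along a planned treatment sequence estimates $\tau$-step-ahead
potential outcomes under the usual assumptions (consistency, positivity,
sequential ignorability) plus the assumption that the decoded concept
approximates the conditional mean of the next outcome. `tau_step_predict`
implements this rolling estimate; `balanced_train`-style adversarial
balancing is available through `tcedit(balance = list(lambda = ...))`:

* a softmax classifier head predicts the assigned next treatment from
  $h_x$;
* its gradient reaches the encoder through a gradient-reversal
  connection (identity forward, negated backward);
* the reversed gradient is renormalized per batch so that `lambda`
  expresses the adversarial force *relative to* the editing gradient
  (`lambda = 1` means equal strength). Without this, the cross-entropy
  scale (order 1) would swamp the working-range Huber scale and any
  fixed weight would be fragile to the head's weight norm;
* the adversarial strength follows the standard warm-up ramp
  $\lambda_p = \lambda\,(2/(1+e^{-10p}) - 1)$ over training progress $p$,
  so the encoder learns the dynamics before shedding treatment
  information;
* the classifier head trains at $8\times$ the encoder's learning rate so
  that, at `lambda = 0`, its held-out accuracy reflects the information
  present in $h_x$ rather than its own convergence lag. `lambda = 0` is
  bit-identical to unbalanced training (the head is initialized from an
  independent random stream and its gradients never reach the encoder).

Because $\tau$-step rolled error is sensitive to training randomness at
roughly the same order as the effects being measured, the balancing
comparison in the test suite averages five training seeds — the same
protocol as multi-seed benchmark reporting with confidence intervals.
`treatment_probe_accuracy()` additionally offers a fresh multinomial
probe on frozen $h_x$ as an adversary-independent readout (a co-trained
head under a strong adversary becomes *anti*-informative, which is not a
fair measure of residual information).

## Direct concept intervention

`intervene_concept` multiplies selected concept entries by user factors
(e.g. halve one lab test's rate); because the decoder is multiplicative,
a factor $f$ on variable $k$ scales $k$'s one-step prediction by exactly
$f$, and untargeted entries are bit-unchanged. `intervened_rollout`
recomputes the concept from the growing generated history each step and
re-applies the factors — a *persistent* intervention, our reading of a
sustained counterfactual regime simulated for $T$ steps; a
once-only intervention would be the first step of the same rollout.
`cohort_similarity` scores a generated trajectory against reference
individuals by pooling variance-normalized variables (normalized by the
reference's mean and standard deviation) into one coefficient of
determination; zero-variance references yield `NA`.

## Synthetic worlds: what they emulate and what they do not

**Multiplicative world** (`multiplicative_world`). Ground truth for
concept learning: $x_{t+1} = r_{s_t} \odot x_t \odot e^{\sigma\eta_t}$,
null-condition rate before a fixed onset (default just past $T/3$), the
entity's assigned condition after it. Defaults: $V = 5$, $N = 200$,
$T = 30$, three conditions, per-variable rates drawn uniformly from
$[0.9, 1.1]$ (bounded away from zero; compounding stays within a sane
dynamic range over 30 steps), initial values in $[0.8, 1.25]$, log-normal
noise. The true $k$-step concept is the element-wise product of per-step
rates. `simulate_counterfactual_pair` shares one noise stream between two
arms so the factual/counterfactual contrast is exact and pre-divergence
history is bit-identical.

**Tumor world** (`tumor_world`). Daily volumes under chemo/radiotherapy
in the standard pharmacokinetic–pharmacodynamic form: logistic-type
regrowth $\rho\log(K/V)$ plus kill terms $\beta_c C(t)$ (chemo
concentration with one-day half-life, single-compartment decay) and
$\alpha_r d + \beta_r d^2$ (linear–quadratic radiotherapy,
$\alpha/\beta = 10$), additive Gaussian noise on the increment, volumes
clamped at a positive floor with a logged count. Day-$t$ covariates
(volume, pre-administration chemo concentration, previous-day radio
dose) reflect treatments only up to day $t-1$, so the next assignment is
never deterministically encoded in the history. Assignment each day is a
coin flip per therapy whose log-odds shift by
$\gamma\,(\bar V_{5} - v_{\text{ref}})/v_{\text{scale}}$ with the 5-day
average volume — $\gamma = 0$ is unconfounded randomization, larger
$\gamma$ ties treatment to the evolving history. The defaults (kill
rates, $v_{\text{ref}} = 4$, $v_{\text{scale}} = 2$, baseline rate 0.25)
were calibrated once so that the confounded-assignment signal persists
across the whole trajectory instead of collapsing after the first few
days, and then frozen; all constants ride along in the world config for
provenance. Counterfactual arms re-run a patient's own noise stream under
an alternative plan; `make_benchmark_split` builds the single-sliding
(one treatment at each offset of the $\tau$ window) and random-plan
evaluation regimes.

**Coupled world** (`simulate_coupled_world`). Two variables where B is
generated from lagged A — the minimal test bed for *indirect* effects of
a concept intervention on a driver variable.

None of these emulate irregular sampling, informative missingness,
measurement-dependent noise, categorical covariates, or distribution
shift between entities; conclusions from passing tests are about the
mechanisms (concept recovery, one-step delayed editing, confounding
response, intervention algebra), not about clinical-grade performance on
real records.

## Baselines

`simple_linear_forecast` is the all-ones-concept ablation (LOCF), exact
by construction. `fit_var`/`var_rollout` give a pooled least-squares
VAR($p$) baseline (default $p = 1$; conditions ignored; rank-deficient
designs fall back to a pseudo-inverse with a warning; rollouts report
overflow as infinite markers rather than failing — divergence of rolled
linear models is a documented behaviour). The autoregressive comparator
reuses the same encoder with a plain regression head and must be rolled
out step by step, so comparisons against it isolate the concept
bottleneck itself.

## Problem sizes and numerical conventions used by the shipped checks

The test suite and `scripts/acceptance.R` run the worlds at
$N = 150$–$200$ entities and $T = 30$ steps, hidden sizes 32–64, and at
most 40 epochs; the balancing comparison averages five training seeds.
These sizes were chosen as the smallest at which the studied effects are
stable. Decoder exactness is asserted at $10^{-12}$ relative error,
scaling inversion at $10^{-9}$, time-delta additivity at $10^{-12}$;
equality of seeded reruns is asserted bit-wise (file hashes and
parameter identity). The target timestamp of an edit is treated as
exactly $t_j$ (no measurement-lag offset), and `NA` is the universal
undefined-statistic marker (e.g. $R^2$ on zero-variance truth).

## Known limitations

* Concepts cannot express sign changes; the positive working range is a
  modelling device, not a removal of the limitation.
* The GELU floor truncates extreme negative rates.
* Balancing strength trades against $\tau$-step accuracy; the default
  (`lambda = 1`, relative normalization, warm-up ramp) removes a
  measurable share of treatment information at small accuracy cost, but
  strong adversaries demonstrably destroy the representation (the
  unbalanced editor is typically the most accurate, consistent with
  concept bottlenecks already separating history from treatment).
* The VAR baseline has no exogenous-condition term by design.
* Calendar handling assumes UTC; sub-hour structure is not encoded.
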