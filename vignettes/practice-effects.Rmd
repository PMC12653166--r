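---
title: "Modelling within-test practice effects with oslm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling within-test practice effects with oslm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Progressive-matrices tests built from an explicit rule taxonomy (the
Carpenter rules: constant in a row, pairwise progression, figure
addition/subtraction, distribution of three, distribution of two; plus the
figural drawing properties overlay, distortion, fusion) allow item
difficulty to be decomposed into component difficulties. Because every
item's rule content is known, they also permit a sharper question: does a
component get easier (learning) or harder (fatigue, loss of attention) as
an examinee practices it across the items of a single session — and does
that change differ between examinees?

`oslm` implements a family of Bayesian item response models for this
question, together with model comparison, posterior predictive checking,
individual-level classification, and a synthetic-data generator, so the
entire pipeline can be developed and validated without access to any
proprietary test data.

## The model family

For person $i$ and item $j$ (in administration order),

$$\mathrm{logit}\, P(X_{ij}=1) \;=\; \theta_i \;-\; \sum_{m=1}^M w_{jm}\,\alpha_m
\;+\; \sum_{m=1}^M v_{jm}\,\delta_{im},$$

where $W = (w_{jm})$ is the hypothesized item-by-component weight matrix
(fixed in advance, not estimated), $\alpha_m$ the initial difficulty of
component $m$, $\theta_i$ the ability, and $\delta_{im}$ the practice
effect: the change in difficulty of component $m$ per unit of accumulated
prior weight. The practice weights accumulate as
$v_{jm} = w_{jm} \sum_{k<j} w_{km}$ (`build_practice_matrix()`), so a
component carries no practice weight at its first appearance. Positive
$\delta$ means difficulty decreases with practice (learning); negative
means it increases (fatigue). The same quantity can be read as a
difficulty trajectory
$\alpha_{ijm} = \alpha_m - \delta_{im}\sum_{k<j} w_{km}$
(`rule_difficulty_trajectory()`); the two formulations are algebraically
identical and the test suite checks this to $10^{-10}$.

Five variants are exposed through `model_spec()`:

| variant | difficulty | practice |
|---|---|---|
| `LLTM` | fixed $\eta_m$ | none |
| `RWLLTM` | random $\eta_{im}$ | none |
| `OSLM` | fixed $\alpha_m$ | fixed $\delta_m$ |
| `RWOSLM` | fixed $\alpha_m$ | random $\delta_{im}$ |
| `RWOSLM_const` | fixed $\alpha_m$ | mixed (default: random for A/S and distortion) |

Random effects are multivariate normal,
$\delta_i \sim N(\mu_\delta, \Sigma_\delta)$ with
$\Sigma_\delta = \mathrm{diag}(\sigma_\delta)\,\Omega_\delta\,
\mathrm{diag}(\sigma_\delta)$. Priors: $\theta_i \sim N(0,1)$ (this fixed
scale identifies the difficulty parameters), fixed effects $\sim N(0,100)$,
$\mu_{\delta m} \sim N(0,1)$, $\sigma_{\delta m} \sim
\mathrm{half\text{-}Cauchy}(0,5)$, $\Omega_\delta \sim \mathrm{LKJ}(2)$.
**Convention:** normal priors written $N(a,b)$ are read with $b$ = variance
throughout, so $N(0,100)$ has SD 10. Both readings are diffuse; the choice
is documented here once and used consistently.

Identification (`check_identification()`) requires $W$, the augmented
practice matrix $V^+=(V,\mathbf 1)$ and $[W\,|\,V^+]$ to have full column
rank, and $2M+1 \le J$. Numerical rank uses the standard singular-value
threshold $\max(J,M)\,\varepsilon\,\sigma_{\max}$.

## Inference

No Stan-style backend is assumed: the package ships its own No-U-Turn
sampler (RcppArmadillo) with analytic gradients of the joint log posterior
for every variant. Implementation choices:

* **Non-centred random effects.** $\delta_i = \mu_\delta +
  \mathrm{diag}(\sigma_\delta) L_\Omega z_i$ with $z_i \sim N(0,I)$; the
  implied distribution is exactly the multivariate normal above, and the
  parameterization avoids the funnel when $\sigma_\delta$ is small (the
  A/S-like component in the default generating world has
  $\sigma \approx 0.05$, so this matters).
* **Correlation matrices** are sampled through the Cholesky factor of
  $\Omega$, built from tanh-transformed canonical partial correlations with
  the exact transform Jacobian and the LKJ(2) density on the factor. Draws
  are therefore positive definite by construction.
* **Adaptation.** Dual-averaging step size (target acceptance 0.8) and a
  windowed diagonal metric estimated from warmup draws, in the style of
  mature HMC implementations; multinomial sampling across the trajectory;
  divergences are counted and reported, never dropped silently.
* **Determinism.** Each chain derives its RNG stream from the
  configuration seed; the same seed, configuration and platform give
  byte-identical draws. (Across different C++ standard libraries the
  normal-deviate stream may differ; within one container image results are
  exactly reproducible.)
* Analytic gradients are validated against central finite differences for
  all five variants in the test suite; the sampler is validated against
  analytic prior moments (prior-only fits) and parameter-recovery
  simulations.

The default `sampler_config()` mirrors the reference analysis scale (4
chains × 5000 iterations, half warmup); `fast_profile()` (2 × 1000) is the
desk-scale setting used in tests. Convergence is summarized by
rank-normalized split R-hat (bulk and folded, maximum reported) with a 1.01
flag threshold — the modern, more conservative form of the potential scale
reduction statistic; no threshold is inherited from elsewhere, 1.01 is this
package's choice.

## Model comparison and checking

`waic()` and `psis_loo()` work on the pointwise log-likelihood draws
(person × item cells). PSIS-LOO smooths the largest importance weights for
each held-out cell with a generalized Pareto fit (Zhang–Stephens quadrature
estimator with weak shrinkage of the shape toward 1/2) and reports the
Pareto-$k$ diagnostics. WAIC is tested against a naive unstabilized
implementation; PSIS-LOO against exact leave-one-cell-out refits on a small
problem.

`ppmc()` uses a pairwise odds-ratio statistic: for every unordered item
pair the 2×2 success table's odds ratio, with 0.5 added to all four cells
of tables containing a zero. **Aggregation choice:** the scalar statistic
is the *sum* of the pairwise odds ratios over all $J(J-1)/2$ pairs. A
single scalar is needed for a posterior predictive $p$-value and the sum is
consistent with reported magnitudes for tests of this size, but the
aggregation is genuinely underdetermined; it is isolated in
`or_statistic()` so alternatives are pluggable, and `pairwise = TRUE`
exposes the raw matrix. The $p$-value direction is
$p_\mathrm{post} = P(T^\mathrm{rep} \ge T^\mathrm{obs})$: models that fail
to capture the positive item association induced by unmodelled
person-varying effects give $p_\mathrm{post}$ near 0.

## The synthetic world

The generator exists because the motivating dataset is not distributable.
Its defaults are a stated world, not tuning knobs:

* **Design**: 34 items, 8 components (5 rules, 3 figural properties);
  weights are small integers (0–2 per rule, 1–3 rules per item, 0–1 per
  figural property) emulating Carpenter-style structures; items are ordered
  by predicted difficulty, easiest first; designs are rejection-sampled
  until the identification check passes.
* **Effects**: the packaged fixture
  (`inst/extdata/art_generating_parameters.json`) holds initial
  difficulties and practice effects at published effect magnitudes for
  rule-based matrices data: e.g. constant-in-a-row is easy
  ($\alpha = -1.585$) but fatigues ($\delta = -0.090$), pairwise
  progression is hard ($\alpha = 1.017$) but is learned
  ($\delta = +0.095$); A/S and distortion carry person-varying effects
  with SDs 0.055 and 0.205.
* **$\Omega_\delta$ between the two random components is the identity**:
  no reference value for this correlation exists, and independence is the
  neutral default. Stated once here; not revisited.
* **Sample**: $n = 765$ examinees by default, standard-normal abilities.
* **Latencies** are lognormal (median 5 s), generated solely to exercise
  the exclusion filter and never modelled; 6.5% of simulated persons
  receive at least one sub-second latency, matching the reference
  exclusion rate. The filter excludes a *person* with any sub-threshold
  latency (the natural reading of an exclusion "due to response latencies
  less than one second"); response-level masking is deliberately not
  offered.
* **External measures** (a cognitive-battery-like score and
  personality-like scales) are linear-Gaussian in the standardized true
  person parameters with weights solved so population correlations hit the
  targets (e.g. 0.513 with ability).

What a green test does *not* establish: the generator draws from exactly
the fitted model family, so recovery and self-consistency results say the
implementation is correct, not that the model describes any real test;
real data bring multi-form administration, item-position effects not
reducible to practice, non-normal abilities and rule interactions, all of
which are absent here.

## Downstream analyses

* `classify_individuals()` gives per-person practice-effect EAPs and the
  fraction positive — the individual-level learning summary.
  EAP shrinkage pulls person effects toward $\mu_\delta$, so the positive
  fraction is conservative relative to the latent fraction when
  $\mu_\delta < 0$.
* `correlate_effects()` produces the external-correlation table from EAP
  point estimates with exact-$t$ two-tailed $p$-values. Shrinkage
  attenuates these correlations; no correction is applied, matching common
  reporting practice, and no multiplicity adjustment is made.
* `rasch_difficulties()` + `variance_explained()` implement the design
  validation regression: Rasch difficulties (fitted as the $W = I$ special
  case of this same family) regressed on the structure matrix, with an
  incremental F-test for item position.
* Deciding *which* components deserve random effects ("substantial
  variability") has no quantified criterion; the package reports the
  $\sigma_\delta$ posteriors and leaves the constraint choice to the user.
  A reasonable heuristic: treat a component as substantially variable when
  the 2.5% quantile of $\sigma_{\delta m}$ exceeds a scientifically minimal
  value.

## Numerical and testing notes

* Missing responses are rejected rather than silently marginalized; the
  internal cell-exclusion mask used by the exact-LOO oracle is not a
  missing-data interface.
* Degenerate inputs: all-0/all-1 items are refused by the Rasch helper;
  zero-variance items enter the odds-ratio statistic through the corrected
  table; constant draws give an NA R-hat with a warning.
* Replication-based acceptance tests (parameter-recovery coverage, model
  selection, PPMC calibration) run at reduced problem size (n = 120–200
  persons and 2 × 300–1000 iterations per replication, on the full
  34-item design) to fit a desk-scale budget; replication counts and pass
  thresholds are unchanged, only the per-replication size is scaled.

## Known limitations

Single pooled form only (no multi-form/anchor equating); linear practice
trajectories (no saturation curves); no rule-interaction components; no
guessing/discrimination parameters; no response-time modelling; EAP-based
downstream correlations are attenuated by shrinkage.
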