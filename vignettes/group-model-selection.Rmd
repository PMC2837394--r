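---
title: "Group Bayesian model selection, family inference and model averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group Bayesian model selection, family inference and model averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupbms)
```

## The inference problem

A group study fits each of $M$ candidate models to each of $N$ subjects'
data and retains, for every (subject, model) pair, an approximation to the
log model evidence $\log p(y_n \mid m)$ — typically a variational free
energy computed upstream by the model-fitting software. Everything in this
package starts from that $N \times M$ table; the package never fits the
models themselves.

Two group-level questions are supported:

* **Which model (or family of models) best explains the group?** —
  fixed-effects (FFX) and random-effects (RFX) model selection.
* **Given a family, what are its parameters?** — Bayesian model averaging
  (BMA) of per-model Gaussian parameter posteriors.

### Fixed effects

FFX assumes one common generating model for all subjects. Because subjects
are independent, the group evidence of model $m$ is the product of
per-subject evidences, so its log is a column sum of the evidence table,
and the posterior follows from Bayes rule:
$$
p(m \mid Y) \propto p(m)\, \prod_n p(y_n \mid m).
$$
Pairs of models are compared by the group Bayes factor — the product of
per-subject Bayes factors. With two models and a uniform prior, a Bayes
factor of 20 (the conventional "strong evidence" boundary) corresponds to
a posterior of $20/21 \approx 0.952$.

All FFX arithmetic stays in natural-log space until probabilities are
materialised. This is not cosmetic: realistic group log-evidence
differences reach hundreds of log units, and family posteriors for losing
families underflow to exactly zero in linear space. `bms_ffx()` therefore
aggregates families via log-sum-exp and reports a display `log_posterior`
normalised so the best family sits at 0.

### Random effects

RFX treats the model used by each subject as a draw from unknown
population frequencies $r = (r_1, \dots, r_M)$ with a Dirichlet prior
$r \sim \mathrm{Dir}(\alpha_0)$, and one-hot multinomial assignment
vectors per subject. `gibbs_sample()` iterates the conditional updates:

1. per-subject assignment weights $g_{nm} \propto e^{L_{nm}} r_m$,
   normalised per subject in log space (the row maximum of
   $L_{nm} + \log r_m$ is subtracted before exponentiation);
2. a one-hot assignment draw per subject;
3. assignment counts $\beta_m$;
4. a conjugate draw $r \sim \mathrm{Dir}(\alpha_0 + \beta)$.

The initial $r$ is drawn from the prior. Retained draws yield expected
frequencies $\langle r_m \rangle$, exceedance probabilities (the fraction
of draws in which a model's frequency is strictly the largest), and the
averaged $g$ matrix that later drives subject-specific model averaging.

**Sampler defaults.** 30,000 total sweeps with the first 10,000 discarded.
The burn-in is deliberately generous: the chain mixes quickly (the
conditionals are conjugate), but burn-in is cheap relative to the cost of
a misleading early-chain transient. The chain is not thinned;
autocorrelation is instead absorbed into Monte-Carlo standard errors
computed from non-overlapping batch means (`mcse` columns in `tidy()`
output). Exceedance ties — possible only for degenerate duplicated draws —
count toward no model.

**Exact reproducibility.** Every stochastic function takes a `seed`
argument, records it in its result, and restores the caller's RNG state
afterwards (`withr::with_seed`); identical inputs and seed give
bit-identical output.

### Families

A family partition groups the models into disjoint, exhaustive named
subsets (by input pattern, by forward/backward flow, or user-defined with
an automatic remainder family). Two priors matter:

* **FFX family-uniform model prior**: $p(m) = 1/(K N_k)$ for a model in
  family $k$ of size $N_k$, giving every family prior mass $1/K$.
* **RFX family-uniform Dirichlet counts**: $\alpha_m = 1/N_k$, so each
  family's total prior count is 1 and the aggregated prior over family
  frequencies is the flat $\mathrm{Dir}(1, \dots, 1)$. This is the unique
  count assignment with that property, and it is what makes family
  inference unbiased when family sizes are unequal — a uniform *model*
  prior would hand a 6-model family three times the prior mass of a
  2-model family.

Family posteriors are computed by aggregating each retained frequency draw
within families and summarising the aggregated draws; under FFX they are
sums of member model posteriors, reported with the *alternative
probability* (one minus the family posterior) because family posteriors
are often indistinguishable from 1 at display precision.

### Why not always report the best model?

The package ships a worked example (`worked_example_comparison_set()`)
showing that RFX best-model identity is brittle: 17 subjects split 7/10
between two models rank model 2 first, but adding a third model that
splits model 2's supporters 6/4 makes model 1 the top-ranked model —
while the FFX ranking of models 1 and 2 is provably unchanged because the
enlarged table restricted to those two columns is identical. Inference
about a shared characteristic (a family) is robust to exactly this kind
of comparison-set perturbation, which is the package's reason for
existing.

The example's construction deserves one note: the third model's four
supporters prefer it over model 2 by the same decisive margin while their
model-2 evidence is left untouched. This is the only construction that
honours both halves of the story (RFX counts 7/6/4 *and* exact FFX
invariance); giving the switchers a zero model-2 evidence would change
the FFX comparison too, which the thought experiment explicitly holds
fixed.

### Variational alternative

`vb_update()` implements the standard digamma fixed point
($g_{nm} \propto \exp(L_{nm} + \psi(\alpha_m) - \psi(\sum \alpha))$,
$\alpha = \alpha_0 + \sum_n g_{nm}$). It is fast and agrees with Gibbs
when all prior counts are $\ge 1$, but it is known to be inaccurate for
the fractional counts family-uniform priors require; any call with
$\min \alpha_0 < 1$ emits a prominent warning recommending Gibbs. The
method is provided for small flat-prior model sets, not as the default.

## Bayesian model averaging

Within a chosen family, the marginal posterior over parameters is a
mixture over models of per-subject Gaussian posteriors, with point mass at
zero contributed by models that fix a parameter a priori. The mixture is
evaluated by sampling:

1. draw a model — per subject from their windowed $g$ row under RFX, or
   one shared draw for all subjects under FFX (the FFX assumption is that
   all subjects use the same model, so a shared draw is the faithful
   sampling scheme);
2. draw a parameter vector from that subject/model Gaussian (exact zeros
   for fixed parameters);
3. average over subjects for the group-average density, or skip the
   average for within-subject densities whose summaries can feed classical
   second-level tests.

**Occam's window** prunes models whose posterior odds against the best
model fall below a minimal ratio $\pi$; default $\pi = 1/20$, matching the
strong-evidence odds convention, and configurable. Windowing is purely
computational: $\pi \to 0$ recovers full-family BMA, $\pi = 1$ keeps only
the best model, and setting the family to a single model reproduces
conventional single-model parameter inference. Under RFX the window is
applied per subject, so subjects can have different window sizes (the
`window_sizes` field records them).

**Zero mass** is tracked analytically from the realised model draws — a
group-average sample is exactly zero for a parameter only when *every*
subject drew a model fixing it — rather than by comparing floating-point
samples to zero.

**Numerical choices.** Gaussian draws use a symmetric eigendecomposition
square root; eigenvalues more negative than $-10^{-6} \times$ the spectral
radius are an error (the covariance is genuinely indefinite), smaller
negatives are clamped to zero because variational covariances are often
numerically indefinite at round-off level. Dirichlet draws with shapes
below 1 (family-uniform priors over 64-model families have
$\alpha = 1/64$) use the shape-boosting identity
$\Gamma(a) \equiv \Gamma(a+1)\,U^{1/a}$ evaluated in log space, which
avoids the underflow-to-exact-zero that plain gamma sampling suffers at
tiny shapes; any residual zero is clamped to the smallest positive double
before normalisation.

## The synthetic-data generator

`simulate_group_evidence()` mirrors the Dirichlet–multinomial generative
model: each subject's generating model is drawn from known frequencies
(or fixed explicitly), receives a log-evidence advantage `margin`, and
independent Gaussian noise may be added. Non-generating models share a
baseline of 0 because every inference in the package depends only on
within-subject evidence *differences*. A margin of 10 log units makes the
per-subject preference decisive (posterior weight above 0.9999), which is
what makes the closed-form conjugate Dirichlet oracle exact and is used
as the default throughout.

What the generator does **not** emulate: correlated evidences across
models (real model spaces are full of near-duplicates), subject-level
heterogeneity in evidence precision, and any connection between a model's
*structure* and its evidence. Passing tests therefore demonstrate that the
inference machinery is correct under its own generative assumptions — not
that free-energy approximations of real DCM fits are well calibrated,
which is an upstream question.

`simulate_parameter_posteriors()` builds the complete subjects × models
grid of Gaussian posteriors over a model space's parameter grid
(`"B:src->dst:u1"` modulatory and `"C:region:u1"` driving parameters),
freeing exactly the parameters each model's patterns license. The
between-subject jitter of posterior means defaults to the posterior
standard deviation itself, so `post_sd = 0` gives an exactly noise-free
grid for analytic checks.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run at deliberately modest sizes
chosen so the Monte-Carlo error of each check is an order of magnitude
below the tolerance it asserts: conjugate-oracle comparisons use 20,000
retained sweeps; the comparison-set example 15,000 sweeps with 5,000
burn-in; frequency recovery averages ten independent 60-subject cohorts
(averaging across cohorts is what removes the $\pm 0.06$ multinomial
noise a single 60-subject cohort carries — a single cohort cannot beat
that floor, whatever the sampler does); BMA moment checks use 20,000
mixture samples. Production analyses should simply use the defaults.

## Known limitations

* Evidence tables must be complete; missing (subject, model) cells are an
  error by design, not imputed.
* The variational method is a convenience for small flat-prior problems
  only; its free-energy diagnostics are not implemented.
* BMA consumes Gaussian per-model posteriors with a free-parameter mask;
  posteriors from other tools must be converted to the package's JSON
  archive layout (`write_subject_posteriors()` documents it).
* Family exceedance probabilities compare a family against *all* others
  jointly; they are not pairwise comparisons except in the two-family
  case, where the two exceedances are complementary.
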