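---
title: "Bayesian molecular-clock dating with chronodate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian molecular-clock dating with chronodate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronodate)
```

## The estimation problem

Molecular sequences measure branch lengths in expected substitutions per
site, the product of a substitution rate and an elapsed time. Fossils
constrain times directly but imprecisely. Bayesian divergence-time
estimation combines the two: a prior on node ages built from fossil
calibration densities and a birth–death kernel, a prior on branch rates from
a molecular-clock model, and the sequence likelihood. Because rate and time
enter the likelihood only through their product, the data alone cannot
identify the ages — even infinite sequence data leaves posterior uncertainty
bounded below by the fossil uncertainty. That limit is what the
infinite-sites diagnostics in this package visualise.

All ages are measured in units of 100 My and rates in substitutions per
site per 100 My. Tips are assumed extant (age 0); non-contemporaneous
sampling is out of scope.

## Calibration densities

Six families are supported (see `?calibration`):

* **B(t~L~, t~U~, p~L~, p~U~)** — soft-bounded uniform between a minimum and
  maximum age. The uniform core carries mass 1 − p~L~ − p~U~; a power
  density on (0, t~L~) carries p~L~ and an exponential tail above t~U~
  carries p~U~, both matched for continuity at the bounds. Typical practice
  sets p~L~ = 0.01 (minimum bounds rest on actual fossils) and p~U~ = 0.05
  to 0.20 (maximum bounds rest on absence of evidence).
* **L(t~L~, p, c, p~L~)** — a Cauchy with location t~L~(1 + p) and scale
  c·t~L~ truncated at a minimum age, for nodes with only a lower bound; the
  heavy tail deliberately allows much older ages. Defaults p = 0.1, c = 2,
  p~L~ = 0.05.
* **ST(ξ, ω, α, ν)** — skew-t (location, scale, shape, degrees of freedom),
  the family used to transfer marginal posteriors between analyses.
* **S2N(w, ξ₁, ω₁, α₁, ξ₂, ω₂, α₂)** — a two-component skew-normal mixture,
  used for densities produced by external fossil-process modelling. The
  seven printed parameters are interpreted as a weight followed by two
  (location, scale, shape) triples; the original source does not spell the
  order out, so it is documented here as this package's reading.
* **G(a, b)** — gamma with shape a and rate b (mean a/b).
* **FIXED(t)** — a point mass, used mainly to pin the root in
  model-selection runs.

The cdf and quantiles of the skew families are computed by adaptive
quadrature and root finding (`integrate`/`uniroot`, tolerances 1e-10 and
1e-12); B, L and G have closed forms.

## The time prior

Calibrated nodes follow their densities; the remaining internal node ages
follow the birth–death kernel conditional on the root age, which with the
default λ = μ = 1, ρ = 0 reduces to i.i.d. Uniform(0, t~root~) order
statistics. The ancestor-older-than-descendant constraint is enforced by
rejection (−∞ log prior) with **no renormalization** — the same convention
as the reference MCMC dating software. A consequence users must check is
that the *marginal* prior at a calibrated node can differ from the density
they wrote down whenever calibrations interact; `prior_truncation_report()`
quantifies this per node, and the effect is largest for heavy-tailed
truncated-Cauchy calibrations adjacent to the root. The root must always
carry a calibration or fixed age, because the kernel conditions on it.

The general (λ, μ, ρ) kernel is implemented in closed form, including the
ρ = 0 limits, but only the uniform special case is exercised by the
contract tests.

## Clock models

Three rate priors over branches, per locus *i*:

* **SC** — one rate μ~i~ for all branches.
* **IR** — branch log-rates i.i.d. N(log μ~i~ − σ²~i~/2, σ²~i~); the
  −σ²/2 correction keeps E[r] = μ~i~. Rate variance is the same at every
  timescale.
* **AR** — geometric Brownian motion: the rate attached to a branch is the
  rate at its child node, evolving from the parent node's rate over the
  branch duration Δt as log r ~ N(log r~A~ − σ²~i~Δt/2, σ²~i~Δt), with the
  root rate equal to μ~i~. Log-rate variance grows with elapsed time:
  near-clock behaviour among close relatives, drift across deep
  divergences. A closed-form consequence (verified by simulation in the
  tests) is that sister branches correlate through their shared
  root-to-parent path: cor = 1 − t~parent~/t~root~.

Across loci the μ~i~ (and σ²~i~) follow a gamma–Dirichlet prior: the
across-locus average follows Gamma(a, b) and the proportions a symmetric
Dirichlet(α~D~). The density includes the exact Jacobian of the
(average, proportions) → rates transform. α~D~ defaults to 1, a choice this
package documents as its own (the source analyses do not state one); it is
configurable. Default hyperpriors follow the published analyses: G(2, 40)
on the mean rate for nuclear-scale data (mean 0.05 s/s/100My, 95% CI
0.00606–0.139), G(2, 8) for mixed nuclear+mitochondrial data, and G(1, 10)
on σ²; model-selection runs use G(2, 1)/G(2, 20) with σ² ~ G(1, 1).

## Likelihood

`exact_loglik()` is Felsenstein pruning under HKY (or JC) with
discrete-gamma rate mixing (mean-of-bin category rates, 4 categories by
default), over compressed site patterns, with the per-pattern kernel in
C++. `?` and gaps are fully ambiguous, so species absent from a partition
contribute nothing to it. The total factorizes over partitions, each with
its own locus rate.

`build_branch_approx()` maximizes the exact likelihood over branch lengths
and stores the value, gradient and Hessian (central finite differences,
relative step 1e-4, clamped so no probe is negative) for the quadratic
surrogate `approx_loglik()`. Two numerical choices matter:

* the expansion is built on the **unrooted** parameterization — under a
  reversible model the two root-adjacent lengths enter only through their
  sum (pulley principle), so the rooted Hessian would be singular;
* after L-BFGS-B, a damped-Newton polish sharpens the optimum so the stored
  gradient is numerically zero.

The surrogate is accurate within a couple of standard errors of the MLE and
unreliable far from it; it is therefore refused for power-posterior runs,
where small-β chains sample far from the optimum.

## MCMC

`run_mcmc()` is a Metropolis–Hastings sampler over node ages, locus rates,
σ², and (for relaxed clocks) per-branch rates, targeting
prior(ages) · prior(rates | ages) · likelihood^β. The proposal kit is the
field's standard: sliding windows with reflection for ages (bounded by
parent and child ages), log-scale multipliers for rates and variances, and
a whole-tree rescale move (ages × c, rates ÷ c) that leaves the
strict-clock likelihood invariant and decorrelates the rate–time product.
Step sizes are auto-tuned toward 20–40% acceptance during burn-in (default
burn-in: one quarter of the run; thinning keeps at most 20,000 samples —
all defaults are this package's own choices and are recorded in the trace
attributes together with the seed). Initialization draws the root age from
its calibration and builds a topologically consistent age assignment by
postorder accumulation and rescaling; a zero-probability start is retried
up to 100 times before erroring.

Summaries are posterior means with equal-tailed 95% intervals and effective
sample sizes from the initial-positive-sequence autocorrelation estimator;
`convergence_check()` compares independent-seed runs on the scale of pooled
CI widths.

## Marginal likelihoods and clock-model choice

`gauss_legendre_schedule(K)` maps K Legendre nodes onto β ∈ (0, 1);
`run_power_posterior()` samples prior · likelihood^β at each point,
warm-starting each chain from the previous β (prior → posterior direction,
a standard variance-reduction choice), and `ti_logml()` applies the
quadrature to the mean log-likelihood with a standard error from
ESS-adjusted variances. K defaults to 64; the desk-scale analyses in the
tests use K = 8–32. `compare_models()` turns log marginal likelihoods into
Bayes factors against the best model and posterior model probabilities
under a uniform model prior.

A caveat established by the simulation studies this methodology builds on,
and reproduced at this package's problem sizes: with few taxa and short
alignments the strict clock often attains the highest marginal likelihood
even when the data were generated with modest autocorrelated rate variation
(σ² ≈ 0.1), because the relaxed models' extra latent parameters cost more
in prior mass than the weak rate signal repays. The desk-scale
model-selection study in the test suite and acceptance script (4 tips, 500
sites, K = 8, 1500 iterations per β point) therefore reports how often the
generating AR model is ranked first over seeded replicates; recovering the
published preference for AR requires the genome-scale alignments, which are
outside this package's scope.

## Sequential (two-step) dating

By the product rule, a posterior computed from one data set and used as the
prior for an independent second data set yields the joint posterior. The
package operationalises this with `posterior_to_calibrations()`: skew-t
densities fitted by ML (multi-start Nelder–Mead over (ξ, log ω, α, log ν),
ν bounded in [2.1, 1e4]) to each mapped marginal posterior, attached as
calibrations for the second analysis. Two approximations are inherited from
the published procedure and documented rather than hidden: the correlation
structure of the step-1 posterior is discarded (product of marginals, with
ancestor–descendant truncation re-imposed by the joint prior), and the
marginals are replaced by fitted parametric densities. The acceptance test
quantifies the resulting discrepancy on a 4-tip instance — joint versus
two-step posterior means agree within a quarter of the pooled CI width.

## Synthetic data

`simulate_timetree()` draws a random coalescent-style topology with
internal ages as sorted uniforms under the fixed root age — exactly the
conditional-uniform kernel the default time prior assumes, so
simulate-then-infer round trips are internally consistent.
`simulate_branch_rates()` is the simulator twin of the clock-model priors,
and `simulate_alignment()` evolves sites independently down the tree
(branch length = rate × duration, optional discrete-gamma mixing and
missing-data masking). What the generator does *not* emulate: indels and
alignment error, substitution-model misspecification, non-contemporaneous
tips, selection, or a realistic fossil-preservation process — passing tests
show internal consistency of the method, not robustness to those features
of real data.

Problem sizes used in the tests and acceptance script (chosen once as
desk-scale study conditions): 4-tip trees, 500–1000 sites, strict-clock
coverage over 100 seeded replicates (3000 iterations each), thermodynamic
integration with K = 8 and 1500 iterations per β point, and sequential
dating with 12,000-iteration chains.

## Known limitations

* Topology is fixed; no tree search, no tip dating, no fossilized
  birth–death process.
* JC and HKY+Γ only; GTR and codon/amino-acid models are out of scope.
* The truncation convention (no renormalization) matches the reference
  implementation but means marginal priors must be inspected, not assumed.
* Skew-t shape and df are weakly identified near symmetry; fits are
  compared in quantile space, and the shape parameter itself should not be
  over-interpreted.
* At 4–8 taxa the relaxed-clock models are barely distinguishable from the
  strict clock by Bayes factors; this is a property of the data sizes, not
  a defect of the estimator.
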