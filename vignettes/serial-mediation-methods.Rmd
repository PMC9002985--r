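---
title: "Methods: latent-probit serial mediation with cluster bootstrap inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-probit serial mediation with cluster bootstrap inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`serimed` estimates how a three-level parental exposure E (overweight
*before puberty*, *at age 30 but not before puberty*, *never* — the
reference) affects an adult offspring's lung function through a serial
chain of two mediators: the offspring's own prepubertal overweight M₁ and
adult attained height M₂. Offspring sex moderates everything, so the model
is fitted separately in sons and daughters with no cross-group constraints
(a multi-group model); families are clusters, because several offspring can
share the one participating parent.

M₁ is binary, so it enters as a latent response: M₁* = a'x + ε₁ with
ε₁ ~ N(0, 1) and M₁ = 1{M₁* > 0}. Fixing the latent residual variance at 1
and the threshold at 0 (θ-style probit identification) makes the a's
ordinary probit coefficients. Downstream equations regress on the *latent*
M₁*, not the binary flag — height picks up `d·M₁*`, each outcome picks up
`b₁ₖ·M₁*` — which is the only convention under which the published
path-product relationships between the coefficient and effect tables hold.
Height and the outcomes are linear-Gaussian; FEV₁ and FVC are modelled
jointly with a free 2×2 residual covariance (model 1), or the ratio
100·FEV₁/FVC is a single outcome (model 2). Parental education confounds
the mediator, mediator–mediator and outcome equations; offspring age and
smoking adjust the outcomes only; covariates never interact with the
exposure.

## Estimation: exact marginal likelihood

The observed data per offspring are (M₁, M₂, Y). Conditional on ε₁
everything is linear-Gaussian and M₁ is a deterministic indicator, so the
observed-data likelihood is the integral of that conditional density over
ε₁. We evaluate this integral in closed form rather than numerically:
stacking w = (M₂, Y₁, Y₂), the model implies w ~ N(μ(x), Ω) with
Ω = λλ' + σ₂²ψψ' + blockdiag(0, Σ), where λ are the loadings of w on ε₁
and ψ on ε₂; and ε₁ | w is again Gaussian, so

log p(M₁, w) = log N(w; μ, Ω) + log Φ( t·(η + λ'Ω⁻¹(w − μ)) / s ),

with t = 2M₁ − 1 and s² = 1 − λ'Ω⁻¹λ. This is the exact limit of the
quadrature formulation. We still expose a fixed-order Gauss–Hermite
evaluation (`observed_loglik(..., method = "quadrature")`, default order
41, minimum 11) because it is the natural independent check — but we do
not optimise it: an integrand containing a deterministic threshold
indicator makes the quadrature sum piecewise-constant in the threshold
parameters (nodes cross the boundary discretely), which both slows
convergence in the order and breaks gradient-based optimisation. The
closed form is smooth, exact and cheap; tests verify the two agree and
that both agree with a brute-force Monte-Carlo integral on a small table.

Maximisation is BFGS with analytic gradients in compiled code, on data
standardised internally (an exact reparameterisation, undone on exit) so
that all parameters are O(1). Convergence requires a relative
log-likelihood change below 1e-9 and a gradient sup-norm below 1e-6 scaled
by the objective's magnitude — the unscaled criterion is unattainable in
double precision once the log-likelihood is ~10⁵ — with an iteration cap
of 500 and three jittered restarts (best likelihood wins) on failure.
Starting values are a probit fit for the mediator equation plus
least-squares fits that substitute E[M₁* | M₁, x] (the inverse-Mills
construction) for the latent mediator.

Standard errors are never computed analytically: all inference is the
cluster bootstrap below, the inference the analysis design prescribes.
The estimator is full-information maximum likelihood rather than the
WLSMV (weighted least squares mean-and-variance adjusted) machinery this
model family is often fitted with in SEM software; the structural system,
identification and estimand are unchanged, and FIML is consistent for the
same parameters.

## Natural effects

With no exposure–mediator interaction and latent-scale linearity, natural
(counterfactual) effects are exact path products per exposure contrast:
NDE = c, NIE via M₁ = a·b₁, NIE via M₂ = h·b₂, NIE via the serial chain
= a·d·b₂, total = their sum (additivity is exact, and tested to machine
precision). No numerical counterfactual integration is performed — by
design, since this reproduces the published coefficient-table → effect-table
arithmetic exactly. Reports round mL effects half-away-from-zero to
integers and probit/cm paths to two decimals; internal values are never
rounded.

## Cluster bootstrap

Parents are resampled with replacement to the original parent count within
a line, each drawn parent contributing all offspring (duplicated parents
get fresh cluster ids); sex groups re-form per resample. Each resample
refits both groups — warm-started from the full-sample estimates and
preconditioned with the full-sample BFGS curvature, which makes a refit a
few milliseconds — and recomputes every effect, structural path and
sons − daughters difference. Intervals are non-bias-corrected percentiles
(linear interpolation between order statistics, `quantile` type 7; no
convention is canonical for percentile bootstraps, so this one is fixed
and declared). Δ intervals are percentiles of the per-resample difference, never a
difference of marginal interval endpoints. Non-converged refits are
dropped and counted, with a hard error below 95% success. The shipped
pipeline default is B = 10,000; tests use a few hundred.

Significance is "the interval excludes zero" (inclusive at the boundary),
feeding the mediation typology: complementary (both direct and indirect
significant, same sign), indirect-only, direct-only, else non-mediation.

## The synthetic-cohort generator

The restricted two-generation cohort cannot ship, so the generator draws
cohorts from exactly the structural model above. Its defaults are the
study conditions: per line, the published exposure-category, low-education
and smoking prevalences, offspring-sex fraction, age ranges (uniform
18–51 paternal, 18–54 maternal; the shape is a choice, the range is
published), and the published per-group path coefficients. Coefficients
that are not publicly reported use documented physiological defaults:
education → latent overweight 0.15 probit units, education → height −1 cm,
education
→ outcomes −40 mL, age slopes −28/−25 mL/yr (sons' FEV₁/FVC) and −22/−20
(daughters'), smoking −120/−60 mL, FEV₁–FVC residual correlation 0.7.
Parents have 1/2/3 offspring with probabilities 0.70/0.25/0.05 (≈1.36
offspring per parent, the published cluster multiplicity). Intercepts and
residual scales are then *solved* so the implied group means, prevalences
and standard deviations of height, FEV₁ and FVC hit the published
descriptive values exactly under the model; an unreachable target residual
variance is an error, not a silent clamp. Post-bronchodilator values are
the pre values plus the published group mean shift plus N(0, 50 mL) noise.

The generator emulates the published marginals and path structure — it
does not emulate real-data features such as informative missingness,
reporting error in silhouettes, assortative mating, parental-height
genetics, or centre heterogeneity. Passing tests therefore demonstrate
that the estimator and inference machinery are correct *under the model's
own assumptions*, not that those assumptions hold in any real cohort.
Each generated cohort carries oracle columns (the latent M₁* and the
implied true effect decomposition) so the likelihood fit can be compared
with a latent-observed least-squares oracle.

## Unmeasured-confounder simulation

The sensitivity module deliberately simplifies to one exposure, one
mediator and one outcome (decilitre scale in this module only). One or two
confounders U ~ N(0, 0.001) act on exposure (through a probit link by
default; logit is configurable), mediator and outcome with a common strength β_U swept over
{0, 1, 3, 5, 7, 9}. Each of `n_sim` runs simulates a dataset, fits the
product-of-coefficients mediation model with and without the U's
(intervals from `n_draws` Monte-Carlo draws of the coefficient sampling
distributions), and records whether the two analyses *match*. "Match" is not a uniquely
defined notion; it is operationalised here, and stated in the output
metadata, as agreement of the significance conclusions for both the direct and the
indirect effect. Reported alongside is
the absolute difference of the average direct and indirect estimates.
Base coefficients default to the published paternal-line sons' FVC
pathway (prevalence 0.12, exposure → height −3.42 cm, height → FVC
0.61 dL/cm, direct −2.62 dL, mediator residual 6.4 cm, unit outcome
noise).

## Numerical and design choices

* Quantile convention: type-7 linear interpolation, fixed.
* Degenerate inputs: a one-class mediator in any group aborts before
  optimisation ("degenerate mediator"); a degenerate exposure skips a
  sensitivity run (error above 5% skipped); empty groups and mismatched
  effect labels are errors, not NA propagation.
* Group-specific residual covariances are estimated freely (the more
  general choice; cross-group equality is never imposed).
* Bootstrap resampling is per line; the two lines are analysed as
  independent studies throughout.
* Missing data: complete-case per line with one logged count per drop
  reason; no imputation.
* If a table carries both silhouette scores and pre-coded flags, flags win
  with a warning.
* Records with inconsistent silhouette reports across stages are not
  special-cased (no rule is documented for them); validation only.

## Problem sizes used by the test suite

Chosen so the suite exercises the asymptotic claims meaningfully: worked
examples are exact arithmetic; estimator recovery and oracle agreement use
one cohort of 50,000 parents (≈68,000 offspring) with B = 40 bootstrap
refits for standard errors; bootstrap coverage uses 200 null-model
replicates of 2,000 parents with B = 500 resamples each; the sensitivity
null check uses 200 simulation runs; interactive-scale checks use 400–2,000
parents. The per-NIE-pathway coverage (via overweight, via height, via the
serial chain; pooled over contrast × group × outcome) is required to sit in
92–98%; individual cells are additionally required never to drop below 92%.
Cells for pathways whose latent loadings are weakly identified at 2,000
parents over-cover (up to ~99.5%) — the familiar conservativeness of
percentile intervals for products of coefficients when a factor is near
zero — which is why the banded check pools within pathway class.

## Known limitations

* The latent-scale path products rely on no exposure–mediator interaction;
  interaction-allowing decompositions are out of scope.
* Percentile product-of-coefficients intervals are conservative near the
  null (see above); they are used regardless because they are the
  inference the analysis design prescribes.
* The sensitivity module's base coefficients describe one pathway at a
  time; it does not propagate the full serial system.
* Analytic (sandwich/delta) standard errors are intentionally absent.
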