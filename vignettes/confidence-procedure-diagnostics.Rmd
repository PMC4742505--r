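---
title: "Diagnosing confidence procedures: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing confidence procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coverdiag)
```

## The problem

A confidence procedure guarantees one thing: in repeated sampling, a
fraction γ of the intervals it produces contain the true parameter. Users
routinely want three further things the guarantee does not supply — that a
particular computed interval has probability γ of containing the parameter,
that its width measures the precision of the estimate, and that values
inside it are more plausible than values outside. `coverdiag` implements
two models in which all three readings fail visibly, together with the
diagnostics (conditional coverage on relevant subsets, false-value inclusion
curves, width profiles) that expose the failures.

## The uniform location model

Two observations y₁, y₂ are i.i.d. uniform on [θ−5, θ+5]; θ is the unknown
location and 5 m is a fixed half-length. Sufficient statistics are the
midpoint x̄ and the spread d = |y₁−y₂| ∈ [0, 10]. The likelihood of θ is the
indicator of x̄ ± (5 − d/2): an interval of width 10 − d, so the data are
*most* informative when the spread is large. Key distributional facts used
throughout:

* marginally, x̄ − θ is symmetric triangular on ±5, giving the 50% quantile
  5 − 5/√2 ≈ 1.4645 m and standard error √(100/24) ≈ 2.0412 m;
* conditionally on d, x̄ − θ is uniform on ±(5 − d/2);
* the spread density is f(d) = (10 − d)/50, with mean 10/3.

The five 50% procedures (trivial; sampling distribution x̄ ± (5 − 5/√2);
nonparametric x̄ ± d/2; UMP, the nonparametric interval truncated to the
likelihood set when d ≥ 5; objective Bayes x̄ ± ½(5 − d/2)) all attain 50%
coverage, which the Monte-Carlo harness confirms. The uniform-on-d fact
yields the package's exact conditional coverage,

> P(θ ∈ interval | d) = min(1, 2·h(d) / (10 − d)),

where h(d) is the procedure's half-width at spread d. This formula is not
itself an assumption: the tests gate it against rejection-sampled
Monte-Carlo estimates at several spreads before any other result relies on
it. At d = 0.5 it gives 30.8% (sampling distribution), 5.3%
(nonparametric/UMP), and exactly 50% (Bayes) — the same data, three
defensible "long-run probabilities", which is precisely the relevant-subset
critique. Integrating the formula against f(d) recovers 0.5 for every
procedure, a law-of-total-probability check the suite performs by
quadrature.

False-value inclusion probabilities are computed the same way: conditional
on d, the probability that θ + Δ falls in the interval is an
interval-overlap length divided by 10 − d, and the marginal is a
one-dimensional integral over d evaluated by adaptive quadrature (absolute
tolerance 10⁻⁹; the integrand is piecewise smooth with kinks where the
overlap saturates, well within quadrature reach). These analytic curves are
the ground truth against which the Monte-Carlo `inclusion_curve()` is
verified, and they reproduce the known ordering: the UMP curve lies below
every other at every displacement, the sampling-distribution curve below
the Bayes curve, and the nonparametric and Bayes curves cross.

### Posteriors

`posterior_grid()` multiplies any bounded, grid-evaluable prior by the
indicator likelihood and renormalizes. The default grid step is 0.001 m with
linear interpolation of the grid CDF for interval endpoints. Because the
likelihood has a sharp cutoff, grid normalization carries an O(step)
boundary-truncation error; the refinement test therefore compares normalized
densities across a 10× step change at the 10⁻³ level and endpoints at the
grid-step level, while posterior *mass* is normalized exactly (sums to 1
within 10⁻⁹). The ocean is modeled as unbounded for sampling; priors carry
their own bounded support.

### Design choices in this module

* **Intervals are closed at finite endpoints.** The model is continuous, so
  boundary events have probability zero; the choice only needs to be
  consistent, and closed containment is what `interval_contains()`
  implements everywhere.
* **Emptiness is a state, not a zero-width interval.** The trivial
  procedure's empty branch and the effect-size module's empty inversions
  stay distinguishable from genuine points.
* **The trivial procedure's point** ("directly under the rescue boat") is an
  arbitrary constant; it is a parameter with default 0. Coverage is 50%
  regardless, since a fixed point has probability zero of equaling θ —
  except in the measure-zero coincidence where the point *is* θ, which the
  test suite deliberately avoids by separating the two.
* **Non-50% levels.** The sampling-distribution and Bayes procedures extend
  naturally (triangular quantile; central posterior fraction) and are
  exposed at any γ ∈ (0,1) as a documented extension. The nonparametric and
  UMP procedures have no canonical non-50% form, and none is invented: they
  are fixed at γ = 0.5.
* **Conditioning by rejection.** Exact conditioning on a spread value has
  probability zero, so `mc_conditional_coverage()` accepts draws within
  ±0.05 of the target and refuses to report on fewer than 1000 accepted
  draws (the error names the acceptance rate). The analytic formula plays
  the role of the exact-line value.

## The ω² test-inversion interval

For a balanced one-way design with k groups of n observations (N = kn), the
effect size ω² — the population fraction of total variance attributable to
groups — indexes the noncentral F distribution of the ANOVA statistic
through λ = Nω²/(1−ω²), with exact inverse ω² = λ/(λ+N). This conversion is
validated in the tests by reproducing all of the worked design's one-sided
p values (F(2,27) = 5: upper-tailed .16 at ω² = .1 and .42 at .2;
lower-tailed .58 at .2) before anything else in the module is trusted.

The confidence interval at coefficient γ = 1 − α inverts two one-sided
noncentral-F tests of size α/2: the interval is every ω² rejected by
neither. Bound existence follows from the ordinary ANOVA p value p:

* p ≤ α/2 — both bounds exist;
* α/2 < p ≤ 1 − α/2 — the lower bound does not exist and is reported as 0,
  and the interval is flagged **suspect**: its width cannot be read as
  estimation precision;
* p > 1 − α/2 — every ω² (including 0) is rejected by the lower-tailed
  test and the interval is empty, reported as [0, 0] with the empty state
  preserved alongside the convention.

Root-finding runs on the λ scale, which is unbounded above and better
conditioned than ω² near 1: the bracket is grown by doubling until the sign
changes, then `uniroot` solves to absolute tolerance 10⁻⁸, and the solution
maps back through λ/(λ+N). Bracketing failure raises a diagnostic error,
never a silent 0.

Two reporting subtleties are worth stating because they affect comparisons
with published two-decimal values. The printed upper endpoint .36 of the
68% interval for F(2,27) = 5 is itself a rounding of 0.3565, so the
lower-tailed p value *at .36* is 0.153, not the test size .16 — the
identity p_lower(upper endpoint) = α/2 holds exactly at the unrounded
endpoint, and that is what the tests assert. Similarly the 68% upper
endpoint at F = 0.18 computes to 0.0017 with this λ parameterization
(two-decimal reports in the literature give 0.01); the tests compare at the
0.01 level rather than pretending more agreement than the arithmetic
supports.

### Likelihood, posterior and HPD

The ω² likelihood is the noncentral-F density at the observed F evaluated
along λ(ω²). The Bayesian backend multiplies it by a user-supplied prior on
ω² (default flat on [0, 0.995], 1000 grid points) and normalizes by the
trapezoid rule. This is a deliberate, documented modeling choice: a full
hierarchical treatment would place priors on the group means and error
variance and integrate them out; the F-likelihood-times-prior posterior is
the transparent grid counterpart, and the two are not equated. For that
reason no published HPD endpoints are used as numeric targets; the HPD
tests are property-based (mass attainment within 10⁻³ of the level under
10× grid refinement, mode containment, contiguity, stability of endpoints).
The HPD set {ω² : posterior ≥ c} is found by bisection on the threshold c
(mass tolerance 10⁻⁶) with linear interpolation at threshold crossings;
contiguity is checked and reported rather than assumed. The direction the
construction is meant to illustrate — when the inversion interval's width
collapses, the credible interval stays honestly wide — is asserted at
F(2,27) = 0.18, where the 68% flat-prior HPD is more than an order of
magnitude wider than the suspect [0, 0.0017] inversion interval.

### The synthetic ANOVA generator

`simulate_anova()` draws k groups of n normal observations with unit error
variance and fixed, centered, equally spaced group means scaled so the
population between-group variance fraction is exactly the target ω²; the
implied noncentrality is then exactly Nω²/(1−ω²), consistent with the
conversion above. F is computed from the between/within mean-square
decomposition and cross-checked in the tests against `stats::anova` on the
same data. The generator emulates the idealized balanced design the
inversion assumes — it does not emulate unequal group sizes, non-normal or
heteroscedastic errors, or random (rather than fixed) group effects, so
passing tests certify the construction under its own assumptions, not
robustness beyond them. Simulated checks: at ω² = 0 the mean simulated F
matches the central-F mean df₂/(df₂−2); at ω² = 0.1 (k = 3, n = 10) the
68% interval's empirical coverage over 2000 simulations is 0.68 within
three Monte-Carlo standard errors — the coverage that the set-at-zero
convention is designed to maintain.

## Monte-Carlo policy and problem sizes

Every stochastic routine takes an explicit integer seed, uses R's default
Mersenne-Twister stream locally, and restores the caller's RNG state, so
results are bit-reproducible within this implementation for a given seed
and settings (cross-implementation bit-reproducibility is not promised).
Agreement in stochastic tests always means "within 3 Monte-Carlo standard
errors", with the SE computed from the binomial formula at the realized
sample size. The suite runs coverage checks at 10⁵ replicates, conditional
checks at up to 5.3×10⁶ total draws (about 10⁵ accepted in the
conditioning bin), and the ANOVA coverage study at 2000 simulated
experiments — sizes chosen so each estimate's Monte-Carlo error is an order
of magnitude below the effects being detected while the whole suite stays
interactive.

## Known limitations

* The nonparametric/UMP procedures exist only at the 50% level, as defined.
* The ω² posterior is the F-likelihood grid posterior, not a full
  hierarchical model; HPDs under the two can differ.
* Report files embed a 32-bit FNV-1a hash of the resolved config for
  provenance, which detects accidental mismatches but is not
  collision-resistant in an adversarial sense.
* No η², partial η², RMSSE or signal-to-noise intervals; no factorial
  designs or contrasts.
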