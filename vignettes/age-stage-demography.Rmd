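---
title: "Age x stage-classified demographic analysis with agestage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age x stage-classified demographic analysis with agestage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestage)
```

## The model

`agestage` analyses populations whose vital rates depend jointly on age
and on a discrete stage (size class, developmental stage, condition,
location). The individual state is the pair (age class, stage); with
$s$ stages and $\omega$ age classes the joint state space has
$s\omega$ combinations, indexed with stages grouped within age classes:
joint index $k = (\text{age}-1)s + \text{stage}$.

The model inputs are

* $\mathbf U_j$ ($s \times s$, one per age class $j$): stage
  transitions and survival of individuals currently in age class $j$.
  Column $i$ sums to the survival probability of stage $i$ at that age;
  columns must be substochastic.
* $\mathbf F_j$ ($s \times s$): per-capita production of offspring of
  each stage by parents of each stage in age class $j$. Multiple
  offspring types are supported; types never produced simply have zero
  rows.
* $\mathbf D_i$ ($\omega \times \omega$, one per stage): age advance.
  The default has ones on the subdiagonal and a 1 in the
  $(\omega,\omega)$ corner, making the final age class open-ended.
* $\mathbf H_i$ ($\omega \times \omega$): age assignment of newborns.
  The default sends every newborn to age class 1.

The joint projection matrices are assembled with the vec-permutation
matrix $K_{s,\omega}$ (the permutation with
$K\,\mathrm{vec}X = \mathrm{vec}X^\top$):
$$\tilde U = K^\top \mathbb D K \mathbb U,\qquad
  \tilde F = K^\top \mathbb H K \mathbb F,\qquad
  \tilde A = \tilde U + \tilde F,$$
where $\mathbb U,\mathbb F$ are block diagonals over age classes and
$\mathbb D,\mathbb H$ block diagonals over stages. Reading
$\tilde U$ right-to-left: move among stages within an age class, flip
to ages-within-stages order, advance age, flip back. With the default
operators $\tilde A$ is block-Leslie: fertility blocks across the first
block row, transition blocks on the subdiagonal, $\mathbf U_\omega$ in
the corner. The test suite verifies the assembly against a directly
written block-Leslie layout on randomized models.

Assumptions: discrete time with a common projection interval;
time-invariant, density-independent rates; a closed population; the
Markov property on the joint state (everything an individual will do
depends only on its current age–stage pair).

### Cohorts as absorbing Markov chains

Treating $\tilde U$ as the transient part of an absorbing chain, the
fundamental matrix $\tilde N = (I - \tilde U)^{-1}$ gives expected
state occupancies, from which the package derives longevity moments,
the survivorship matrix, the joint distribution
$\tilde B = \tilde M \tilde N$ of age and stage at death, and life
disparity $\tilde\eta^\dagger = \tilde B^\top \tilde\eta_1$. Mixed
cohorts are handled throughout by mixing distributions $\pi$, and the
variance of any per-state outcome splits by the law of total variance
into within-stage (individual stochasticity) and between-stage
(heterogeneity) components; the split is exact and is tested as such.

### Population dynamics and sensitivity

Growth rate, stable structure and reproductive value come from the
dominant eigenpair of $\tilde A$; the net reproductive rate from the
next-generation matrix $\tilde R = \tilde F\tilde N$, whose
block-triangular structure reduces the eigenproblem to the
$s \times s$ birth-to-birth block $\mathbf R_{11}$. The cohort
generation time uses the exact identity
$\sum_x x\tilde U^x = \tilde N\tilde U\tilde N$, so no series is ever
truncated (a truncated-series version exists only as a test oracle).

Sensitivity of any output $\xi$ to any parameter vector $\theta$
factors into five terms: the output derivative with respect to
$\mathrm{vec}\,\tilde U$ and $\mathrm{vec}\,\tilde F$ (the only term
that depends on $\xi$); two constant structural Jacobians
$I\otimes K^\top\mathbb DK$ and $I\otimes K^\top\mathbb HK$; the
block-placement Jacobians $Q_i^\top\otimes P_i$; and the per-age
parameter Jacobians (the only term that depends on $\theta$). The
package ships analytic output derivatives for $\lambda$
($w^\top\otimes v^\top$, with $\langle v,w\rangle = 1$ enforced
internally — the scaling is a standard requirement even where it is
often left implicit) and for $R_0$, plus the multiplicative-survival
parameterization $\mathbf U_i = \mathbf G_i \boldsymbol\Sigma_i$,
$\sigma_i = \hat\sigma_i \circ \theta$. Every analytic derivative is
checked against central finite differences at relative tolerance
$10^{-6}$ on randomized models.

## Conventions that matter

These are the places where equally sensible packages differ, so they
are fixed here explicitly:

* **Age counts from 0.** $x$ is the number of completed projection
  steps since entering age class 1, so $\ell(0) = 1$ and the cohort
  generation time $\Gamma$ is the mean of $x$ weighted by offspring
  production: reproduction during the first interval happens at
  "age 0".
* **Longevity counts the step being lived**, so its minimum is 1: an
  individual dying in its first interval lived one step. Discrete and
  continuous life-expectancy conventions differ by about one half.
* **Death is attributed to the state occupied when the fatal
  transition was applied**: the absorbing states are indexed by the
  age–stage pair at the moment of death.
* **Life disparity is reported exactly as the discrete formula
  computes it.** A deterministic single-state death then yields
  $\eta^\dagger = 1$ where the continuous-time limit would give 0; the
  discrepancy is a floor of one time step inherent in the discrete
  counting convention. We report it unchanged rather than silently
  adjusting, and provide `continuous = TRUE` to subtract 1 where the
  continuous convention is wanted.
* **Undefined vs infinite mortality.** A hazard computed from an
  already-extinct (or structurally impossible) cohort is `NaN`; a
  cohort that dies out exactly at the next step has hazard `+Inf`. The
  two mean different things and are kept distinct.
* **Index order.** All results use stages-within-ages;
  `reorder_age_primary()` conjugates by $K$ to the ages-within-stages
  arrangement (a similarity transform, eigenvalues unchanged) for users
  who prefer age-primary blocks.

## Numerical choices

* Substochasticity of the $\mathbf U_j$ columns is checked to
  tolerance $10^{-10}$ and violations are *errors*, not warnings:
  a silent super-unity survival corrupts every downstream Markov
  result.
* The fundamental matrix is obtained by a single LU solve of
  $(I-\tilde U)N = I$, never by forming an explicit inverse per
  right-hand side; the spectral radius of $\tilde U$ is checked first
  and radii within $10^{-12}$ of 1 raise an "immortal chain" error
  (e.g. an open-ended age class with survival exactly 1).
* Survivorship is accumulated by vector–matrix products (cost linear
  in the largest age), never by explicit matrix powers.
* Eigen-selection takes the full spectrum, keeps candidates within
  $10^{-10}$ relative of the maximal modulus, and picks the one with a
  nonnegative right eigenvector; several *distinct* tied eigenvalues
  with nonnegative eigenvectors raise an ambiguity error naming them.
  Reducibility from impossible-state masking is handled by restricting
  normalization and checks to possible states.
* Variances that compute to tiny negatives ($\ge -10^{-9}$) from
  floating cancellation are clamped to 0; anything more negative is an
  internal-consistency error.
* Mixing vectors off unit sum by at most $10^{-8}$ are renormalized
  silently; larger deviations are errors.
* Kronecker-product Jacobians in the sensitivity chain are never
  materialized: the assembled product is computed through
  $\mathrm{vec}(MX) = (I\otimes M)\mathrm{vec}X$ and block extraction,
  so the cost is $O(p\,(s\omega)^2)$ for $p$ parameters. Dense
  structural matrices are available for inspection only up to
  $s\omega \le 40$.
* Matrices are stored dense; joint dimensions into the low thousands
  are desk-scale and need no sparse machinery.
* Model bundles serialize matrices with 17 significant digits, which
  round-trips doubles exactly.

## Open design points and how they were decided

* The $(\omega,\omega)$ corner of the age-advance operator defaults
  to 1 (open-ended final age class); setting it to 0 kills all
  individuals at the final age and is exposed as `final_survival`.
  Additional age-advance mortality is *accepted* (any substochastic
  $\mathbf D_i$) but never generated by the defaults, since it can
  always be folded into the $\mathbf U_j$.
* For the scalar fertility schedule $f(x) = c^\top F_x\pi(x)$, the
  default $\pi(x)$ is the cohort's own stage composition at age $x$ —
  the only choice consistent with interpreting $f(x)$ as the schedule
  experienced by an actual cohort. Any other mixture (e.g. the stable
  population's age-conditional composition) can be passed explicitly.
* Reproductive value has no canonical scaling; it is kept in the
  $\langle v,w\rangle = 1$ scaling that the sensitivity formulas
  require and can additionally be reported relative to any reference
  state. No particular reference is privileged.

## The synthetic example species

The generator emulates a poecilogonous marine invertebrate: one
species, two larval offspring types. Small (planktotrophic-like)
larvae are cheap and numerous; large (lecithotrophic-like) larvae
carry more parental investment. Four stages: small/large juveniles and
small-born/large-born adults, over $\omega = 50$ age classes.

Defaults (all rates per projection step, chosen once as a plausible
regime for such a life history and then left alone):

* survival: $\sigma_{JS} = 0.30$, $\sigma_{JL} = 0.55$ (high larval
  mortality, large advantage), $\sigma_{AS} = 0.90$,
  $\sigma_{AL} = 0.95$; age-constant, with an optional gentle logistic
  senescent decline (`senescence = TRUE`) since the shape of adult
  senescence in such species is not established;
* maturation: logistic in age, plateau 0.6 at midpoint age 6 for
  small juveniles, plateau 0.8 at midpoint age 4 for large ones
  (earlier onset, higher plateau);
* fertility: logistic ramp (midpoint age 8) to plateaus
  $(f_{SS}, f_{SL}, f_{LS}, f_{LL}) = (1.6, 0.16, 1.0, 0.5)$ — small
  offspring are produced at higher rates by both adult types, and each
  type disproportionately produces its own kind (heritability
  asymmetry). These plateaus put the dominant eigenvalue near 1, i.e.
  a near-stationary persistent population, which is the regime a field
  demographer would consider typical.

What the generator does **not** emulate: any real species' estimated
schedules (the curves are parametric stand-ins; externally estimated
or transcribed schedules are loaded with `load_schedule_table()`),
environmental stochasticity or density dependence, parameter
uncertainty, and observation error. Passing tests on the synthetic
species therefore demonstrates internal consistency of the theory and
its implementation on a realistic-shaped life history — not agreement
with any field system.

## The Monte Carlo oracle

`microsimulate()` realizes the same life cycle stochastically:
individuals draw a birth stage from a mixing distribution, then at
each step transition or die according to the columns of $\tilde U$,
with offspring accumulated as per-step expectations (or Poisson
draws). Its summaries — longevity mean and variance, death-age
histograms, lifetime offspring by type — must agree with the analytic
chain within 3 standard errors at $n = 10^5$, and the suite checks
this on the closed-form toys and on a reduced ($\omega = 20$) example
species. The simulator is step-synchronous and vectorized over
individuals under one seeded stream: results are reproducible per
`(n, seed)` pair, which is what the cross-validation needs, and the
vectorized design keeps $10^5$ individuals fast in R. (Per-individual
random substreams, which would additionally make individual $i$'s
trajectory invariant to $n$, were considered and not adopted.)

Problem sizes used by the test suite — toys with $s \le 4$,
$\omega \le 4$ for exact oracles, the species at $\omega = 50$ for the
pipeline and $\omega = 20$ for simulation cross-checks, $n = 10^5$
trajectories — keep each check well-conditioned and the whole suite
fast; they were chosen as the smallest sizes at which every property
is non-trivially exercised.

## Known limitations

* Variance of *lifetime reproduction* (as opposed to its mean) needs
  reward-augmented chain machinery that is out of scope here, as are
  higher moments of longevity beyond the second and per-stage
  occupancy-time variances.
* No estimation: the package analyses given $\mathbf U_j, \mathbf F_j$
  and makes no assumptions about how they were fitted (capture–
  recapture, event-history, IPM discretization, ...).
* Time-invariant linear dynamics only: no density dependence,
  stochastic environments, or transient-analysis extensions.
* The stable-age generation time (mean parental age of offspring
  produced at the stable structure) is not implemented; the
  growth-rate measure $T = \log R_0/\log\lambda$ and the cohort
  measure $\Gamma$ are.
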