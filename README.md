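# agestage

Age × stage-classified matrix population models in R: construction by
the vec-permutation block algorithm, absorbing-Markov-chain cohort
theory, population dynamics, and exact matrix-calculus sensitivity
analysis.

## The problem

Classical demography classifies individuals either by age (Leslie
matrices, life tables) or by a discrete stage such as size, instar, or
condition (Lefkovitch matrices). Many populations need both: vital
rates depend jointly on how old an individual is and what state it is
in, and the interaction of the two cannot be recovered from either
marginal model. `agestage` is for population ecologists and demographers
who have (or want to explore) per-age-class stage matrices and need the
full toolkit of demographic results on the joint state space.

The biological content of a model is a set of `s × s` stage
transition/survival matrices **U**ⱼ and fertility matrices **F**ⱼ, one
per age class `j = 1..ω`, plus age-advance operators **D**ᵢ and
newborn age-assignment operators **H**ᵢ. The joint projection matrices
on the `sω` age–stage combinations (stages grouped within age classes)
are assembled with the vec-permutation matrix **K**:

    Ũ = Kᵀ 𝔻 K 𝕌,    F̃ = Kᵀ ℍ K 𝔽,    Ã = Ũ + F̃

where the blackboard symbols are block diagonals of the per-age and
per-stage matrices. With the default age operators, Ã has block-Leslie
form: fertility blocks across the first block row and transition blocks
on the block subdiagonal, with an open-ended final age class.

From the assembled model the package computes:

* **Life-table functions** — joint and birth-stage survivorship
  ℓ̃(x), ℓ(x), mixed-cohort survivorship ℓ(x|π), mortality rates μ(x),
  intra-cohort selection (the changing stage composition of an aging
  cohort), and the weighted/mixed fertility schedules.
* **Longevity statistics** — the fundamental matrix
  Ñ = (I − Ũ)⁻¹, mean/variance of remaining longevity for every
  age–stage combination, and the law-of-total-variance decomposition of
  mixed-cohort variance into within-stage stochasticity and
  between-stage heterogeneity.
* **Age and stage at death** — the mortality matrix M̃, the joint
  distribution B̃ = M̃Ñ of state at death, its marginals and mixtures,
  and life disparity η̃† = B̃ᵀη̃₁ (mean years of life lost).
* **Population dynamics** — growth rate λ, stable joint structure and
  marginals, reproductive value with an ergodicity diagnostic, the
  next-generation matrix R̃ = F̃Ñ and its birth-to-birth block
  **R**₁₁ (net reproductive rate R₀ and the lifetime-reproduction
  aggregations), and generation times, including the closed-form cohort
  generation time Γ built on ΣₓxŨˣ = ÑŨÑ.
* **Sensitivity analysis** — the five-term chain rule
  dξ/dθᵀ = (dξ/dvecᵀÃ)·(I⊗KᵀDK)·Σᵢ(Qᵢᵀ⊗Pᵢ)·(dvecUᵢ/dθᵀ) + (fertility
  path), with analytic output derivatives for λ and R₀, the
  multiplicative-survival parameterization Uᵢ = GᵢΣᵢ, and a
  finite-difference validator.
* **Fixtures** — a synthetic poecilogonous example species (two larval
  offspring types with different parental investment), hand-checkable
  toy models, a schedule CSV loader, and an individual-based Monte
  Carlo simulator used as an independent check on all of the above.

## Worked example

The built-in example species has four stages — small/large juveniles
and small-born/large-born adults — over 50 age classes. Large offspring
receive more parental investment: they survive better at every age,
mature earlier, and their advantage persists through adulthood.

```r
library(agestage)

sch   <- build_example_schedules(species_config())
model <- assemble_model(sch)
model
#> Age x stage-classified model: 4 stage(s) x 50 age class(es) = 200 joint states
#> Index convention: stage_within_age

st <- stable_analysis(model)
st
#> Stable population: lambda = 1.010456
#> Stage marginal of w: 0.3904 0.2352 0.0321 0.3423

N     <- fundamental_matrix(model)
repro <- net_reproductive_rate(model, N)
round(repro$R11[1:2, 1:2], 3)
#>       [,1]  [,2]
#> [1,] 0.121 2.546
#> [2,] 0.012 1.273
```

The population grows about 1% per time step. The birth-to-birth block
of the next-generation matrix says a small-born individual produces on
average 0.121 small and 0.012 large offspring over its life, while a
large-born individual produces 2.546 and 1.273 — a large survival and
maturation advantage compounded over the life cycle.

```r
pi <- birth_mixture_from_stable(st, 4)   # stage mixture of stable-population births
round(pi, 3)
#> [1] 0.685 0.315 0.000 0.000

sl <- age_slice(longevity_stats(N), 1, 4)
round(sl$mean_by_stage, 2)               # life expectancy at birth by stage
#> [1]  1.54  5.15 10.00 20.00
variance_decomposition(sl$mean_by_stage, sl$var_by_stage, pi)
#> Variance in longevity, mixture decomposition
#>   mixture mean      2.6741
#>   within (stochasticity)   40.5733
#>   between (heterogeneity)  2.8057  (6.5%)
```

About 69% of stable-population births are small larvae. A newborn
cohort mixed in those proportions has mean longevity 2.67 steps, and
6.5% of the variance in longevity among its members is attributable to
the heterogeneity between offspring types; the rest is individual
stochasticity within types.

```r
sensitivity_survival(model, "lambda", ages = 1)
#> [1] 0.00104 0.04180 0.00000 0.00000
```

A multiplicative increase in first-age-class survival of large
juveniles raises λ forty times more than the same perturbation for
small juveniles.

A thin command-line layer over the same functions is installed at
`inst/cli/agestage.R`, with subcommands `example-species`, `build`,
`population`, `cohort`, `longevity`, `death`, `sensitivity`, and
`simulate`.

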