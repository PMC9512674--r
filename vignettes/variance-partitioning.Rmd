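---
title: "Partitioning binary-trait liability in nuclear families: models, priors and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning binary-trait liability in nuclear families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famGxE)
```

## The problem

Family studies of common disease ask how much of the variation in disease
risk is attributable to genetics, to environments shared at different
levels of family structure, to where a family lives, and — less commonly
quantified — to interactions between genes and environment. famGxE
implements a fully Bayesian variance-partition analysis for binary
phenotypes observed on nuclear families (two parents plus their children
aged 16 or older, all sharing one residence).

Disease status $y_i \in \{0,1\}$ is modelled through a logit-scale
liability $l_i$ with $y_i \sim \mathrm{Bernoulli}(\mathrm{logistic}(l_i))$.
The most general model assembles the liability as

$$
l = X\beta + f_q(q) + f_p(x) + G + F + C + S + E
  + k_{GF}\,G{\cdot}F + k_{GC}\,G{\cdot}C + k_{GS}\,G{\cdot}S
  + k_{GE}\,G{\cdot}E,
$$

where the products are taken per individual. The terms are:

* $X\beta$ — demographic fixed effects: intercept, sex (0 = female,
  1 = male) and numeric age in years. Age enters as a single numeric
  coefficient, so the estimate reads as a log-odds change per year of
  age.
* $f_q(q)$ — a cubic polynomial in each of five standardized
  environmental-quality (EQI) domain scores (air, water, land,
  sociodemographic, built). Each domain's raw variables are summarized
  by the first principal component, standardized, and sign-aligned so
  that larger scores mean worse quality.
* $f_p(x)$ — a Gaussian process over the family residence coordinate
  $x$ (latitude, longitude), with exponentiated quadratic kernel
  $k(x,x') = \sigma_P^2\exp(-\lVert x-x'\rVert^2 / 2\ell^2)$. Families
  sharing a location share the effect exactly: the process is evaluated
  at unique locations and expanded by indexing.
* $G \sim \mathcal{N}(0, \sigma_G^2\Sigma_G)$ — additive genetic
  effects, with $\Sigma_G$ the pedigree-derived numerator relationship
  matrix (parent–child and full siblings 0.5, spouses 0, unit
  diagonal), built by the recursive tabular method.
* $F, C, S \sim \mathcal{N}(0, \sigma^2_\bullet\Sigma_\bullet)$ —
  environments shared by the whole family, by the couple, and by the
  sibling group; the $\Sigma$ are 0/1 block structures with unit
  diagonal.
* $E \sim \mathcal{N}(0, \sigma_E^2 I)$ — the individually independent
  environment.
* $k_{G\bullet}\,G{\cdot}\bullet$ — gene–environment interaction random
  effects, formed generatively as per-individual products of the latent
  vectors, scaled by a free factor $k$.

Five nested models form two forward-selection traces, compared by
information criteria:

| model | spatial GP | environments | interactions |
|-------|-----------|--------------|--------------|
| LM0   | –         | E            | –            |
| LM1   | yes       | E            | –            |
| IM1   | yes       | E            | GE           |
| LM2   | yes       | F, C, S, E   | –            |
| IM2   | yes       | F, C, S, E   | GF, GC, GS, GE |

`modelSpec("IM0")` additionally names the reduced interaction model
($X\beta + f_q + G + E + k_{GE}G{\cdot}E$, no spatial term) under which
the coverage simulation study operates.

## Variance partition on the liability scale

For a set of variance scales, the per-component contributions to
$\mathrm{Var}(l)$ are $\sigma_P^2$, $\sigma_G^2$, $\sigma_F^2$,
$\sigma_C^2$, $\sigma_S^2$, $\sigma_E^2$ and, for each interaction,
$k^2\sigma_G^2\sigma_\bullet^2$. Dividing by their sum yields the
statistics $p^2, h^2, f^2, c^2, s^2, e^2, hf^2, hc^2, hs^2, he^2$; by
construction they lie in $[0,1]$ and sum to one. They are computed **per
posterior draw** and then summarized by the posterior mean and the 95%
highest-posterior-density interval — the reported intervals are
intervals of the statistics themselves, not transformed interval
endpoints. All statistics live on the logit (liability) scale; no
observed-scale transformation is applied.

A modelling note on the interaction terms: the covariance contributed by
a product term $k\,G{\cdot}E$ is $k^2\sigma_G^2\sigma_E^2\,
(\Sigma_G \odot I)$, the elementwise product of the component
structures. We implement the interaction generatively — as the product
of the two latent vectors — rather than through covariance algebra. The
generative form is what the sampler fits, it is unambiguous about what
$\odot$ acts on, and it keeps the model identified: $G$ is almost surely
not proportional to $G{\cdot}E$. The sign indeterminacy
$(G,E) \to (-G,-E)$ under a product term is absorbed by the symmetric
priors; all partition statistics depend only on $k^2$ and the
$\sigma^2$, so no sign alignment is needed.

## Priors

* **Fixed effects**: horseshoe shrinkage (global scale 1, local
  half-Cauchy(1) scales, standard normal innovations) on every
  coefficient except the intercept, which gets $\mathcal{N}(0,5)$.
  Shrinkage regularizes the 15 polynomial coefficients; exempting the
  intercept avoids shrinking the disease prevalence.
* **Variance scales** $\sigma^2$: Gamma(shape 2, rate 0.5) — a
  zero-avoiding prior with mode above zero, which keeps variance
  components away from the boundary where the likelihood alone cannot
  discriminate.
* **Interaction factors** $k$: conditionally on the variance scales,
  $k \mid \sigma_G, \sigma_\bullet \sim
  \mathcal{N}\!\left(0,\, c^2 / (\sigma_G^2\sigma_\bullet^2)\right)$
  with $c = 2$. The quantity that matters scientifically is the implied
  interaction variance $k^2\sigma_G^2\sigma_\bullet^2$; a prior placed on
  $k$ alone (say $\mathcal{N}(0,1)$) makes that implied variance scale
  with the *product* of the component variances — a priori the
  interaction would rival or exceed the main effects, and because binary
  observations carry little information separating the individually
  independent environment from its interaction with genetics, the
  posterior of $he^2$ inherits the inflation (we verified this against
  an independent Gibbs implementation of the same posterior: both
  samplers agree, so it is a property of that prior, not of the
  sampler). Scaling the conditional prior by
  $1/(\sigma_G\sigma_\bullet)$ puts the implied interaction variance on
  the scale of a single variance component: with $c^2 = 4$ its prior
  mean equals the Gamma prior mean of every other component.
* **GP length scale** $\ell$: inverse-Gamma with shape 3 and scale set
  so the prior mean equals half the maximum inter-location distance —
  mass is kept away from 0 (where the GP degenerates to iid noise) and
  away from scales beyond the data's extent, where $\ell$ is not
  identified.

All hyperparameters are overridable via `assembleModel(..., priors =)`.

## Posterior computation

The joint posterior is sampled by the No-U-Turn sampler (NUTS) with
dual-averaging step-size adaptation (target acceptance 0.9 — the
interaction models are ill-conditioned and benefit from small steps) and
diagonal mass-matrix adaptation over doubling warmup windows. Latent
effects use the non-centered parameterization: unit-normal innovations
transformed by structure factors (a sparse Cholesky factor of
$\Sigma_G$, group indicators for $F/C/S$, the Cholesky factor of the GP
kernel at unique locations). The log-posterior and its analytic gradient
— including the gradient of the GP Cholesky factor with respect to
$\ell$ — are compiled C++ (RcppArmadillo).

Defaults are 4 independent chains of 1000 warmup + 1000 kept draws.
Chains are initialized from a mean-field automatic-differentiation
variational (ADVI) approximation optimized by Adam; each chain start is
an independent draw from the fitted approximation, and a diverging
variational objective falls back to random unit-Gaussian initialization
with a warning. Kept draws are pooled by concatenation across chains.
Diagnostics: split R-hat, effective sample size (via coda), divergence
counts and tree depths. All randomness derives from the single
configured seed through R's RNG, so runs are bit-reproducible per
platform. Note that the scalar $k$ parameters mix between the two
symmetric modes $\pm k$ slowly or not at all by design; their R-hat is
not meaningful, while $k^2$ — the quantity the statistics use — mixes
well.

## Model comparison

WAIC and PSIS-LOO-CV are both reported on the deviance scale
($-2 \times$ expected log predictive density); lower is better. WAIC
uses the standard log-pointwise-predictive-density minus variance
penalty; its 95% interval is the normal approximation
$\pm 1.96\,\mathrm{SE}$ from the pointwise contributions (the interval
construction is a package choice, documented here because several
conventions exist). PSIS-LOO smooths the upper 20% of each
observation's importance ratios with a generalized-Pareto fit
(Zhang–Stephens posterior-mean estimator), truncated at the raw
maximum; observations with shape $k > 0.7$ are flagged unreliable. With
a degenerate posterior the two criteria coincide exactly, which the
test suite exploits as an oracle. `selectionTrace()` treats WAIC as the
headline criterion and PSIS-LOO as confirmatory; disagreements and
overlapping intervals are annotated, never silently resolved.

Two caveats worth knowing. With one latent effect per observation,
leave-one-out importance ratios are intrinsically heavy-tailed, so many
observations carry high Pareto-k flags — PSIS-LOO remains useful as a
confirmatory ranking but its absolute value is optimistic. WAIC shows a
milder version of the same optimism: when data are simulated without
any interaction, the interaction model's WAIC tends to edge out its
linear counterpart by an amount within roughly twice the reported WAIC
standard error; differences should therefore be read against the
criterion's standard error, never as bare numbers.

## The synthetic-cohort generator

`generateCohort()` emulates the assumed data structure, not any real
population: nuclear families of two parents (ages 35–70) and 1–3
children (ages 16–45, sexes Bernoulli(0.5)); one residence per family
drawn uniformly from a set of locations placed uniformly in a
continental-US bounding box; per location and EQI domain, three raw
Gaussian variables sharing a latent factor (cross-variable correlation
0.6), PCA-summarized exactly as real covariates would be. Phenotypes
are simulated from the liability model via `sampleLatentEffects()` and
`simulatePhenotype()` under a `generativeTruth()`.

Defaults worth noting:

* Fixed-effect truth defaults to all-zero coefficients so that
  variance-partition recovery is not confounded by fixed-effect misfit;
  nonzero settings are available.
* Children's sexes and ages are independent of all random effects —
  the models themselves assume genetic and environmental effects are
  independent, and the generator matches that assumption.

What the generator does **not** emulate: realistic geography or EQI
marginals, assortative mating, migration between locations,
ascertainment through insurance claims, or diagnostic misclassification.
Passing the validation suite therefore demonstrates that the inference
machinery recovers what it assumes — it does not validate the modelling
assumptions against real cohorts.

On half-siblings: the sibling-shared environment matrix marks all
child-role members of a family as one sibling group (a statement about
shared upbringing), while the genetic relationship matrix follows the
actual parent links; half-siblings would be genetically 0.25 but still
share the full sibling environment. The generator never produces them.

## The coverage simulation study

`runSimulationStudy()` repeats, per variance setting: simulate a cohort
under the reduced interaction model with
$(\sigma_G^2, \sigma_E^2) \in \{(1,5), (2,4), (3,3), (4,2), (5,1)\}$
and $k_{GE} = 1/3$; fit the same model; record whether the 95% HPD
intervals of $h^2$, $e^2$ and $he^2$ contain the true values

$$
h^2 = \frac{\sigma_G^2}{D},\quad e^2 = \frac{\sigma_E^2}{D},\quad
he^2 = \frac{k^2\sigma_G^2\sigma_E^2}{D},\quad
D = \sigma_G^2 + \sigma_E^2 + k^2\sigma_G^2\sigma_E^2 .
$$

The package's default study size is 200 families and 20 replicates per
set with 4×(500+500) draws; the test suite and the acceptance script
run a further-reduced configuration (100 families, 8 replicates,
4×(300+300) draws, and 80 families × 6 replicates respectively) chosen
so the whole five-set study completes in minutes on one CPU while the
binomial error of the coverage estimate remains compatible with the
nominal 0.95 level. Larger configurations are a `cohortConfig()` /
`samplerConfig()` call away. Replicates whose sampler fails are
excluded from the denominator and counted.

## Numerical choices

* Kernel form: $\exp(-d^2/2\ell^2)$, the standard exponentiated
  quadratic; distance is raw Euclidean on degree coordinates (a
  haversine option exists but is off by default). Since $\ell$ is
  inferred, kernels differing by a constant in the exponent denominator
  are equivalent up to rescaling $\ell$.
* GP jitter: $10^{-6}\sigma_P^2$ on the diagonal, configurable; keeps
  the kernel matrix numerically positive definite when families share
  locations.
* The age column is centered at the cohort mean before sampling — a
  pure reparameterization that moves the intercept to "mean age" and
  improves conditioning; reported age coefficients are unchanged.
* Structure matrices are stored dense; at the package's intended
  cohort sizes (hundreds to low thousands of individuals) sparsity is
  an optimization, not a contract. The sampler itself uses sparse
  factors.
* Draws with exactly zero total variance (possible only in
  hand-constructed draw matrices) are excluded from partition summaries
  and counted.
* PCA for EQI scores is fitted at location level, not individual
  level, so populous families do not re-weight the score of their
  county; scores are properties of places.

## Limitations

* Founders are assumed non-inbred and mutually unrelated; inbreeding
  and marker-based relationship matrices are out of scope.
* Maximum-likelihood/REML estimation is deliberately not provided; the
  package is fully Bayesian.
* The spatial term assumes smoothness on a plane; widely separated or
  non-contiguous geographies (islands) violate the assumption.
* One phenotype per run; multi-disease analyses loop externally.
* NUTS on the interaction models can emit occasional divergences at
  small sample sizes; raising `targetAccept` and the warmup length is
  the first remedy.

## A minimal session

```{r example, eval = FALSE}
truth <- generativeTruth("IM0", sigma_g_sq = 3, sigma_e_sq = 3,
                         k_ge = 1/3)
cohort <- simulateCohort(cohortConfig(nFamilies = 100), truth, seed = 1)
model <- assembleModel("IM0", cohort)
draws <- sampleModel(model, samplerConfig(seed = 1))
varianceFractions(draws)
fitReport(model, draws)
```
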