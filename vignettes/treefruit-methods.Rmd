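---
title: "Modeling tree fruit production with treefruit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tree fruit production with treefruit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treefruit)
```

## The problem

Individual trees of the same tropical species differ enormously in how much
fruit they produce, and that inequality shapes seedling recruitment,
frugivore food supply, and future forest composition. `treefruit` models
individual-level, ordinal fruit-production observations of mapped trees as
a function of three classes of predictors: tree size (diameter at breast
height, DBH, cm), soil nutrient availability interpolated to the tree's
location, and crowding by neighboring trees. Because exact fruit counts on
canopy trees are impractical, observations are ordinal categories
(1 = no fruit, 2 = 1-100, 3 = 101-1,000, 4 = more than 1,000 fruits),
recorded in several observation periods timed so that each species' peak
fruiting window is seen at least once.

## The models

Three analyses share one latent linear predictor for tree $i$ of species
$j$:

$$\eta_i = \mathbf{x}_i^\top \boldsymbol\beta_j
 + \beta_{j,\mathrm{NCI}}\,\mathrm{NCI}_i(\alpha_j, \nu_j)/s + \varepsilon_i,$$

where $\mathbf{x}_i$ holds the standardized covariates of the chosen set
(intercept; DBH; optionally the soil triple NMin, P, SBC),
$\varepsilon_i \sim \mathrm{Normal}(0, \tau)$ is an individual random
effect with precision $\tau$, and $s$ is a fixed conditioning constant
(default 100) absorbed by the crowding coefficient.

1. **Binomial** (`analysis = "binom"`): the tree's reproductive status
   (any fruit in any period) is Bernoulli with
   $\mathrm{logit}(\pi_i) = \eta_i$.
2. **All-individual ordinal** (`"amulti"`, $K = 4$): the maximum category
   $F_i$ over periods follows a cumulative-logit (proportional-odds)
   multinomial, $\mathrm{logit}(Q_{ik}) = \gamma_k - \eta_i$,
   $\pi_{ik} = Q_{ik} - Q_{i,k-1}$, with ordered cut points
   $\gamma_1 = 0 < \gamma_2 < \gamma_3$.
3. **Reproductive-only ordinal** (`"rmulti"`, $K = 3$): the same model on
   reproductive individuals only, original categories 2-4 relabeled 1-3,
   which isolates what controls *how much* fruit a reproductive tree makes
   from the very common zeros.

Species coefficients are exchangeable,
$\boldsymbol\beta_j \sim \mathrm{MVN}(\boldsymbol\mu, \Sigma)$, tying rare
species to the community-level mean. Anchoring $\gamma_1 = 0$ identifies
the intercept; species share cut points within a model.

### The neighborhood crowding index

Crowding on a focal tree is
$$\mathrm{NCI}_i = \sum_{n} \mathrm{DBH}_n^{\alpha_j}\,
 \exp(-\nu_j / d_n),$$
summed over all mapped trees of any species within 10 m (a closed ball;
neighborhoods are truncated at plot boundaries and never cross plots).
The asymmetric variant (ANCI) restricts the sum to neighbors with strictly
larger DBH than the focal tree, representing size-asymmetric competition
for light. $\alpha_j$ and $\nu_j$ are estimated within the likelihood,
species-specific for the focal tree but shared across neighbor species,
with Gamma(1, 1) priors.

Two kernels are provided. The form above, `kernel = "as_printed"`,
follows the index as published; note that $\exp(-\nu/d)$ *increases*
toward 1 with distance, the opposite of conventional crowding kernels.
`kernel = "decay"` uses $\exp(-\nu d)$, the conventional decaying form.
Both are first-class options and the published form is the default; we
deliberately do not silently "correct" the published definition, and
results can be reported under both. Distances below 0.1 m (coincident
stems from multi-stemmed mapping) are clamped to that floor so the kernel
stays finite.

A known and consequential property of this index family: the exponent
$\alpha$ is only weakly identified. Across trees, index values computed
at different $\alpha$ are correlated well above 0.9, so the likelihood is
nearly flat along a ridge that trades $\alpha$ off against the crowding
coefficient. With vague coefficient priors the posterior then drifts
toward small $\alpha$ and a large-magnitude coefficient (a
change-of-volume effect), even when data were generated at a larger
$\alpha$. The *sign* and the predictive effect of crowding are stable;
the coefficient's magnitude in isolation is not interpretable without
fixing the kernel. The package's parameter-recovery tests document this:
interval coverage of the true coefficients stays nominal (the intervals
widen along the ridge) while the point estimates of the crowding
coefficient are shrunk along it.

### Soil covariates

Sampled nutrient fields are interpolated to each tree as the
inverse-distance-weighted (power 1) average of the five nearest soil
samples in the tree's plot; a coincident sample is returned exactly. The
model covariates are potential nitrogen mineralization
(NMin = 30-day incubation change in NO3 + NH4), total extractable P, and
the sum of base cations (SBC = K + Ca + Mg), each standardized globally
(z-scores pooled across species; the per-species coefficients make this a
labeling convention, and the moments are stored for back-transformation).
Concentration units cancel under standardization. The inverse-distance
power is configurable; 1 is the default because plain distance weighting
is the simplest member of the family.

### Priors

"Vague" priors are made concrete as: $\mu \sim \mathrm{N}(0, 100^2)$
elementwise; $\Sigma \sim$ inverse-Wishart(identity, $p + 2$);
$\tau \sim \mathrm{Gamma}(0.001, 0.001)$ (precision parameterization,
matching the convention of the BUGS-family software in which such models
are usually fit); $\alpha_j, \nu_j \sim \mathrm{Gamma}(1, 1)$; free cut
points flat subject to ordering. All are configurable through
`prior_config()`, and the prior-sensitivity of `log_prior()` is part of
the test surface.

## Inference

`run_mcmc()` is a blocked adaptive random-walk Metropolis-within-Gibbs
sampler:

* individual effects: single-site random-walk proposals, vectorized and
  accepted element-wise (each $\varepsilon_i$ touches only tree $i$'s
  likelihood);
* each species' coefficient vector: a joint random-walk block;
* $(\log\alpha_j, \log\nu_j)$: a joint block per species in which the
  crowding coefficient is simultaneously rescaled to hold the species'
  mean crowding contribution fixed — a symmetric random walk in
  transformed coordinates whose Jacobian is accounted for. This move
  travels along the ridge described above and greatly improves mixing of
  the kernel parameters;
* free cut points: joint random walk with ordering rejection;
* $(\boldsymbol\mu, \Sigma, \tau)$: conjugate Gibbs draws.

Proposal scales adapt by Robbins-Monro recursion only during burn-in
(targets 0.44 for scalar updates, 0.234 for blocks), so the retained
chain is a valid time-homogeneous Markov chain. Initialization uses
independent per-species logistic fits (fallback zeros), empirical
cumulative-logit cut points, $\varepsilon = 0$, $\alpha = \nu = 1$.
Any correct MCMC scheme is acceptable here; correctness is defined
against oracles (a fine-grid numeric posterior for a one-parameter model,
conjugate closed forms, simulation-based calibration), not against any
particular sampler's trajectories.

Two protocols ship as named configurations. `mcmc_config()` defaults to a
desk-scale protocol (3 chains x 5,000 iterations, 1,000 burn-in) that the
test suite and simulation studies use; `paper_scale_config()` runs the
full-length field-data protocol (3 x 50,000 retained draws for the
binomial model; 3 x 100,000 thinned by 10 for the ordinal models, both
after 10,000 burn-in). Convergence is monitored with the Gelman-Rubin
statistic; 1.1 is the advisory threshold (the diagnostic's customary
rule-of-thumb), and `summarize_posterior()` warns above it. A fixed
burn-in plus this diagnostic stands in for "burn-in until converged":
adaptive burn-in lengths would break exact reproducibility for a given
seed.

## Model comparison and effects

`compute_dic()` reports the conditional DIC (individual random effects in
focus, matching the default of the BUGS-family software):
$\bar D$ = mean deviance over retained draws, $D(\bar\theta)$ = deviance
at the posterior mean of *every* sampled quantity (cut points averaged
and re-sorted, a choice this package documents because it is not
otherwise specified), $p_D = \bar D - D(\bar\theta)$,
$\mathrm{DIC} = \bar D + p_D$. `compute_scores()` adds proper scoring
rules of the posterior-mean predictive: Brier and logarithmic scores for
the binomial model, the ranked probability score for ordinal models —
standard proper rules for those outcome types, chosen by this package.
`compare_models()` assembles the per-analysis comparison table, flags the
DIC minimum, refuses to compare fits made on different data, and breaks
exact ties toward the fewer-parameter set (flagged as ties).

Effect strength follows the SD-based interval convention: *strong* if the
95% interval (mean +- 2 SD) excludes zero, *moderate* if the 87% interval
(mean +- 1.5 SD) excludes zero, *weak* otherwise. Quantile intervals are
reported alongside, labeled, because the two constructions differ for
skewed posteriors.

## Post-processing

* `threshold_size()`: the reproductive threshold $D_{thres}$ (DBH at
  which the probability of reproduction is 0.5) solved in closed form per
  posterior draw at reference covariates (standardized zero, individual
  effect zero — a population-median curve rather than one marginalized
  over $\varepsilon$, a documented choice). Draws with a non-positive DBH
  coefficient leave the threshold undefined; they are excluded and their
  fraction reported, in preference to sign-constraining the prior.
* `threshold_vs_dmax()`: OLS of $\ln D_{thres}$ on $\ln D_{max}$ plus the
  $R^2$ of the constrained line $D_{thres} = \tfrac12 D_{max}$.
* `seed_mass_regressions()`: simple regressions of threshold size (or of
  average category probabilities) on literature dry seed mass, with and
  without a configurable outlier-exclusion list.
* `average_category_probabilities()` and `prediction_curves()`: posterior
  summaries of category probabilities along DBH or along the crowding
  index (the index value swept directly on its raw scale).

For the reproductive-only analysis, species with fewer than 2
reproductive individuals are excluded (configurable); one reproductive
tree cannot inform a within-species fruit-quantity model.

## The synthetic forest generator

`generate_forest()` and `simulate_fruit()` emulate the study design so
that every stage is testable offline with known truth:

* five 41 m x 240 m plots (configurable); 17 species with the census
  abundances and literature seed masses of the field study; stems placed
  uniformly (optionally Thomas-clustered — the census maps real plots, so
  uniform is the simplest testable default);
* per-species lognormal DBH distributions truncated at the 5-cm census
  threshold (size distributions skewed toward small stems; canopy species
  larger: meanlog log 16 vs log 9, sdlog 0.65 vs 0.5 — round magnitudes
  chosen once as field-realistic);
* soil sampled on a meter-spaced 200-point transect down the plot center
  (composites; the three field subsamples per meter are not emulated
  separately) plus a 10-m lattice; nutrient values are a smooth low-order
  spatial trend (log-scale quadratic surface, sd 0.3) times the target
  mean, plus 10% sampling noise — only the spatial autocorrelation
  matters for exercising the interpolation, so no attempt is made to
  model soil genesis;
* fruit categories drawn from the cumulative-logit model at true
  parameters. By default (`period_model = "peak"`) each tree's *peak*
  category is drawn once from the model and observed in one randomly
  chosen period, with off-peak periods showing a category at or below the
  peak (truncated draw). This mirrors the design intent of the multiple
  observation periods — catching each species' peak fruiting at least
  once — and makes the two reductions (maximum category; any-fruit
  status) follow the fitted models exactly, which is what parameter
  recovery requires. `period_model = "iid"` draws every period
  independently instead; under that option the maximum over periods is
  stochastically larger than a single model draw, so recovering the
  generating parameters from reduced data is *not* expected.

Default generative parameters: community means (intercept -1, DBH 1.5,
NMin 0.1, P 0, SBC 0.3, crowding -1 on standardized scales),
between-species SD 0.3, cut points (0, 1.8, 3.5), individual-effect
precision 4 (SD 0.5), kernel parameters alpha = nu = 1. These encode the
study system's qualitative structure — strong positive size effects,
negative crowding, weak nutrient effects, many zeros — at magnitudes a
field ecologist would call realistic, and they are fixed study
conditions, not tuning knobs.

What the generator does **not** emulate: phenology calendars and masting
time series (periods are exchangeable), dioecy, measurement error in the
category assignments, spatial autocorrelation of the individual effects,
and real soil-DBH covariance. Passing recovery tests on these synthetic
forests therefore demonstrates that the inference machinery is correct
and well calibrated for the stated model, not that the model is adequate
for any particular real forest.

## Numerical choices and problem sizes

Category probabilities are computed from differences of logistic CDFs and
floored at 1e-300 before logging; overflowed proposals (e.g. extreme
kernel exponents) propagate NaN and are rejected. Deviance is recorded at
every retained draw. The validation experiments in the test suite use
sizes chosen to exercise the full model while staying desk-scale: 20
replicate ordinal DBH+ANCI fits of 4 species x 200 trees with 3 x 5,000
chains for parameter recovery; 10 replicates per condition for DIC model
selection (3 species x 110 trees, binomial); 20 replicates for
reproductive-threshold recovery with a known 25-cm threshold; 1,000
random configurations for the brute-force neighbor and interpolation
oracles.

## Known limitations

* The crowding-kernel exponent is weakly identified (see above); report
  crowding effects predictively (curves along the index) rather than by
  coefficient magnitude.
* With one reduced observation per tree, the individual-effect precision
  $\tau$ is informed mostly through the prior and the category mix; its
  posterior is diffuse. A direct consequence is that the *conditional* DIC
  (random effects in focus) is unstable across refits in this regime — it
  follows the chain's $\tau$ state. The package's model-selection
  validation experiments therefore compare covariate sets on fits without
  the individual-effect layer, where DIC differences reflect the
  covariates; when the random effects are retained, DIC differences
  smaller than the refit-to-refit spread should not be interpreted.
* The reproductive-only model conditions on an outcome of the binomial
  model; the two analyses are deliberately separate (that is the design's
  device for excess zeros), so their coefficients are not comparable
  across analyses.
* No edge correction: neighborhoods of trees within 10 m of a plot
  boundary are truncated, accepting attenuated crowding there in exchange
  for keeping those focal trees.
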