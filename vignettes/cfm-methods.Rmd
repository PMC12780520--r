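---
title: "Methods: classifying and modelling coexisting forms of child malnutrition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and modelling coexisting forms of child malnutrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmtools)
```

## The problem

A child under five can fail more than one anthropometric standard at once.
The conventional indicators — stunting (low height-for-age), wasting (low
weight-for-height), underweight (low weight-for-age) and overweight/obesity —
are usually tabulated separately, which hides the children in whom deficits
(or a deficit and an excess) coexist. `cfmtools` implements a nine-way,
mutually exclusive nutritional-status taxonomy built from the three z-score
indices, together with the survey machinery needed to estimate how common
each state is and which covariates are associated with the composite states.

The four composite ("coexisting forms of malnutrition", CFM) categories are
anchored on underweight and stunting:

* **CUW** — underweight and wasted (WAZ ≤ −2 and WHZ ≤ −2),
* **CUS** — underweight and stunted (WAZ ≤ −2 and HAZ ≤ −2),
* **CUWS** — underweight, stunted and wasted,
* **CSO** — stunted (HAZ ≤ −2) with overweight/obesity (WAZ ≥ +2 and/or
  WHZ ≥ +2), not underweight.

A child failing exactly one standard carries a standalone form (SFM);
a child failing none is normal. "Malnourished" is SFM or CFM.

## The z-score engine

Z-scores are computed with the LMS method: a growth reference tabulates, per
sex and indicator, the Box-Cox power $L(t)$, median $M(t)$ and coefficient of
variation $S(t)$ along an axis $t$ (age in months, or length/height in cm),
and a measurement $y$ maps to

$$ z = \frac{(y/M)^L - 1}{L\,S}, \qquad z = \frac{\log(y/M)}{S} \ \text{as } L \to 0, $$

with the log-limit taken below $|L| < 10^{-8}$; the two branches agree to
better than $10^{-6}$ SD at the switch. The inverse transform
$y = M(1 + LSz)^{1/L}$ round-trips to below $10^{-10}$ SD, which the
synthetic generator relies on.

Engine conventions, all configurable:

* **Interpolation** of $L, M, S$ is piecewise linear in $t$, independently
  per parameter; knot rows are reproduced exactly and there is no
  extrapolation — an axis value outside the table gives a missing component,
  never a guess. Tables keyed in days are converted to months at load
  (1 month = 30.4375 days) since survey age is stored in months.
* **Restricted adjustment** applies to the weight-based indices (WAZ, WHZ)
  only: a z-score beyond ±3 is linearized on the measurement scale using the
  local width of the 2-to-3 SD band, e.g.
  $z = 3 + (y - \mathrm{SD3}^+)/(\mathrm{SD3}^+ - \mathrm{SD2}^+)$ above +3.
  It is the identity on $[-3, 3]$ and continuous at the join; HAZ is never
  adjusted. Because the adjustment is monotone and fixes ±2, it never moves a
  child across a classification threshold.
* **Position correction**: WHZ uses the length axis below 24 months and the
  height axis from 24 months. When the measurement position is known and
  mismatches the age convention, 0.7 cm is added to a standing measurement
  below 24 months and subtracted from a recumbent one at or above 24 months,
  before any length/height lookup. Unknown position assumes the
  age-appropriate convention.

Reference tables are pluggable CSV inputs (`t,L,M,S` plus metadata); the test
suite runs entirely on a synthetic fixture (below) and never requires the
real standards files.

## Plausibility screening

Before classification, biologically implausible triples are excluded:
a record is retained iff $|HAZ| \le 6$, $|WHZ| \le 5$ and $-6 \le WAZ \le +5$.
The bounds are inclusive — exclusion is strictly beyond — and a missing
component imposes no constraint. Exclusions are recorded as per-record
dispositions (`excluded_outlier`), so the attrition of any run is auditable
rather than assumed.

## The classifier and its edge cases

Four predicates are evaluated on a complete triple: stunted (HAZ ≤ −2),
wasted (WHZ ≤ −2), underweight (WAZ ≤ −2), and excess (WHZ ≥ +2 or
WAZ ≥ +2). The printed descriptions of "normal" as −1.99 to +1.99 are read
as a rounded rendering of the open interval (−2, +2): a z of exactly −2.0
is abnormal, −1.999 is not. Categories resolve in priority order CUWS →
CUS → CUW → CSO → standalone → normal.

Two predicate combinations fall outside the underweight-anchored taxonomy
and required a documented decision rather than inferred intent:

* **Stunted and wasted but not underweight.** Not a CFM type under the
  definitions used here. Such children are assigned the standalone category
  by fixed precedence (stunting over wasting), counted in SFM, and flagged
  `stunted_wasted_not_underweight` so users can tabulate them.
* **Underweight combined with an excess predicate** (possible only via
  WHZ ≥ +2): a biologically contradictory pattern. It resolves by deficit
  precedence (CUS if also stunted, else standalone underweight) and is
  flagged `underweight_with_overfeeding_pattern`.

Any other multi-predicate residual is flagged `multiple_standalone`. Flagged
records still receive exactly one category, so the nine categories always
partition the retained records; the test suite proves exhaustiveness and
exclusivity against an independent hand-written predicate lookup table over
a dense grid of z triples.

## Survey-weighted estimation

Prevalence is the Horvitz–Thompson ratio
$100 \cdot \sum w_i \mathbb{1}[c_i] / \sum w_i$. Published tables of this
kind print 95% confidence intervals without stating their construction, and
the printed widths are not recoverable from the printed n and p alone; the
interval here is therefore a methodological choice, not a reproduction: a
Wilson score interval evaluated at the Kish effective sample size
$n_\mathrm{eff} = (\sum w)^2 / \sum w^2$, with a Wald option. Cluster and
stratum labels are carried through; full linearized design-based variance is
out of scope.

Survey weights are only relatively scaled within one survey, so pooling
across countries needs a rule. The default, *sample-size pooling*, rescales
each country's weights to sum to its unweighted n, so each country
contributes its sample size to regional and global estimates — consistent
with pooled-denominator reporting. *Population pooling* accepts user-supplied
country shares instead. Under sample-size pooling the estimates are invariant
to rescaling any single country's weights, which the tests assert.

`validate_report()` checks the two additivity identities
(malnourished = SFM + CFM; CFM = CUW + CUS + CUWS + CSO) on any report,
internally generated (tolerance $10^{-9}$) or transcribed from a published
table (tolerance 0.15 percentage points for rounding).

## Determinant models

The inferential chain mirrors common practice in this literature:

1. **Screening** by Pearson chi-square on each covariate × outcome table
   (`stats::chisq.test` without continuity correction), pass at p ≤ 0.05.
2. **Multinomial logistic regression** fitted by our own Newton–Raphson on
   the stacked score, with step-halving whenever a step would decrease the
   log-likelihood. Convergence when the maximum absolute score is below
   $10^{-8}$ or the relative log-likelihood change is below $10^{-10}$, cap
   100 iterations. A two-level outcome reduces exactly to binary logistic
   regression (verified against `glm`, and against `nnet::multinom` for
   three levels). Quasi-complete separation — any coefficient beyond 15 in
   absolute value — triggers a flagged ridge refit (penalty $10^{-6}$) with
   a warning. Wald CIs: $\exp(\beta \pm 1.96\,\mathrm{se})$.
3. **Backward elimination** removes whole covariate blocks (all dummy levels
   jointly, across all outcome equations) by likelihood-ratio test,
   worst-first, until every remaining block has p ≤ α = 0.05. Block-wise
   removal matches the notion of removing a *covariate*, not a level.
4. **Collinearity**: VIF per dummy column via least-squares $R^2$ on the
   remaining columns; exact collinearity is reported as a flagged `Inf`,
   not an error. The conventional "below 2" reading is a diagnostic, not an
   enforcement.

Two standard models are bundled (`cfm_models()`): a four-level multinomial
{underweight (ref), CUW, CUS, CUWS} on the children in those categories, and
a binary {stunting (ref), CSO} on the stunted-anchored categories. Which
records form each risk set is not fixed by convention, so this subpopulation
construction is a documented default, configurable by filtering before
`backward_eliminate()`. Models are unweighted by default (weighting the
likelihood is an option), and covariate missingness is handled complete-case
per model with dropped counts recorded.

## The synthetic-data generator

Restricted-access survey microdata cannot ship with a package, so every
stage is exercised on generated data with known ground truth.

**Latent model.** Two latent components — the height-for-age and
weight-for-height axes — are bivariate normal with configurable means,
SDs and correlation; country membership and categorical covariates add
fixed mean shifts. WAZ is coupled to both components. On the z-score output
pathway the coupling is stochastic
($\mathrm{waz} = 0.55\,\mathrm{haz} + 0.55\,\mathrm{whz} + \varepsilon$,
$\sigma_\varepsilon = 0.4$). On the raw-measurement pathway no independent
noise is possible: given age, the generated weight and height determine all
three indices, so the toy references are constructed log-linear (L = 0,
constant S, log-linear medians), which makes the engine-implied coupling
exactly $\mathrm{waz} = \mathrm{whz} + k\,\mathrm{haz}$ with
$k = d_1 S_h / (c_1 S_w) \approx 0.55$ fixed by the table slopes. The stored
truth category of every record is recomputed by the package's own forward
engine from the emitted record, so the end-to-end identity (pipeline
classification equals stored truth) holds exactly, not approximately.

**Defaults.** Mean HAZ −0.9 (SD 1.25), mean WHZ −0.35 (SD 1.05), correlation
0.05; six countries spanning the six global regions with shifts ordered so
South/Southeast Asia fares worst and Latin America/Central Asia best; five
covariates (child sex and age band, maternal education, wealth quintile,
residence) with mild planted effects; i.i.d. gamma(4, 0.25) sampling
weights; 25 clusters per country. These were chosen once as a plausible
pooled under-five population and are not tuned to any published figure.

**What it does not emulate.** Real z-score distributions are skewed and
heavy-tailed; real weights correlate with design; real clusters carry
intra-class correlation (labels are provided, but draws are independent);
and the latent-normal model with a positive HAZ–WHZ correlation
under-produces the stunted-with-overweight state (CSO realizes well below
typical published prevalences, so the bundled CSO model often has little to
work with at small n). Passing tests therefore demonstrate correctness of
the machinery, not calibration to any real population.

**Oracle.** `expected_category_probabilities()` integrates the trivariate
normal over the 27 boxes that the ±2 cutpoints induce: deterministic 2D
Gauss–Legendre quadrature over the (HAZ, WHZ) marginal with the closed-form
conditional normal CDF in the WAZ direction (32 nodes per dimension;
truncation at 8.5 SD; the rank-2 measurement-pathway covariance is handled
by the conditional degenerating to an indicator). A plain Monte-Carlo method
(eigendecomposition sampler, ≥ $10^6$ draws, reported SE) serves as the
independent cross-check; the two agree within Monte-Carlo error in the test
suite. Scenario-level expectations are the mixture of the oracle over all
distinct mean-shift cells. `planted_effect_calibration()` inverts the oracle
by bisection (tolerance $10^{-6}$ in log-OR) to find the latent shift whose
induced category odds ratio equals a target, enabling parameter-recovery
tests with exact planted truth.

```{r oracle-example}
cfg <- default_scenario(n_per_country = 200, covariate_effects = FALSE,
                        seed = 42)
k <- attr(generate_reference_fixture(42), "consistency")$k
round(expected_population_prevalence(cfg, k = k), 4)
```

## Numerical choices and test problem sizes

* Classifier validation uses the full grid $z \in \{-6, -5.75, \dots, +5\}^3$
  (91,125 triples) against an independent predicate-table oracle.
* The end-to-end check runs 12,000 children (2,000 per country, seed 17):
  large enough that every category's realized prevalence has a standard
  error well under half a percentage point, small enough to re-run freely.
* Planted-OR recovery uses n = 50,000 across five seeds; backward-elimination
  error rates use 200 simulations of n = 5,000. These sizes give binomial
  noise comfortably inside the asserted bands.
* Ties and degenerate inputs: exact-boundary z-scores classify on the
  abnormal side; empty groups, zero total weight, degenerate contingency
  tables and singular designs raise named errors; missing anthropometry is a
  disposition, never an exception.

## Known limitations

* No Taylor-linearized or replicate-weight variance estimation; CIs treat
  the Kish effective n as if from independent draws.
* No severity grading (moderate vs severe) and no split of overweight vs
  obese.
* The DHS dialect implements the variable/sentinel conventions on CSV
  exports only; proprietary containers are out of scope.
* The measurement pathway's exact linear WAZ coupling is a property of the
  synthetic fixture geometry, not of real growth standards; with real
  reference tables the three indices decouple as in real data.
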