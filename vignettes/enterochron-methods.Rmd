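---
title: "Models and methods behind enterochron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind enterochron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

enterochron analyzes longitudinal gut-microbiome and antimicrobial-resistance
(AMR) data from cohorts sampled on a fixed age grid. This vignette explains
the models, their assumptions, the tunable parameters and the numerical
choices, and what the synthetic cohort generator does and does not emulate.

## The study design the package encodes

The motivating design follows 18 female pigs in two cohorts (6 and 12
animals) from weaning to first parity, sampling feces at nine ages — 3, 6,
10, 12 and 22 weeks while growing, 32 weeks at first estrus / artificial
insemination, 49 weeks one week before farrowing, 50 weeks on the day of
parturition and 53 weeks at weaning of the first litter. All 162 samples
enter the culture-based AMR panel; a balanced subset of 8 pigs (4 per
cohort, 72 samples) is profiled by sequencing and qPCR. `study_age_grid()`
and `stage_for_age()` encode the grid and the age-to-stage mapping;
`read_metadata()` enforces them unless `strict_ages = FALSE`, so the rest of
the package works on any longitudinal design.

## Enterotyping with Dirichlet-multinomial mixtures

Community types ("enterotypes") are components of a Dirichlet-multinomial
mixture over **raw** genus counts — the DM likelihood models the counting
process itself, so normalized values are never the input here (the
normalization question simply does not arise for a count model; this is
stated prominently because it differs from every other stage, which consumes
CSS-normalized values).

For a count vector $x$ with total $n$ and concentrations $\alpha$
($A = \sum_j \alpha_j$):

$$\log \mathrm{DM}(x \mid \alpha) = \log\Gamma(A) - \log\Gamma(n + A) +
\log\Gamma(n+1) + \sum_j \left[\log\Gamma(x_j + \alpha_j) -
\log\Gamma(\alpha_j) - \log\Gamma(x_j + 1)\right].$$

`fit_dmm()` runs EM: exact E-step responsibilities through log-sum-exp, and
an M-step that sets the weights to mean responsibilities and maximizes each
component's responsibility-weighted DM log-likelihood over
$\log \alpha_k$ with L-BFGS-B (bounds $\pm 10$ on the log scale, analytic
gradient, warm-started with a capped inner iteration count — a generalized
EM step, so the recorded log-likelihood trace is non-decreasing, which the
tests assert on every fit). Initialization is k-means on proportion
profiles; the default of 3 seeded restarts is enough at this scale because
the k-means seeds land in the same basin, and the restart count is exposed
for harder problems. Convergence is a relative log-likelihood change below
`tol = 1e-6` (default `max_iter = 200`). Components whose weight falls
below 1e-6 are pruned with a warning and the effective K reported.

### Choosing K: the Laplace evidence, and why it carries a prior

`laplace_score()` approximates the negative log model evidence at the fitted
mode with a Gaussian (Laplace) approximation, using the *analytic* Hessian
of the negative log-likelihood in the unconstrained parameterization
(logit weights, log concentrations; $d = (K-1) + K \times S$ parameters).
The Hessian is assembled from responsibilities — per-component curvature
terms plus the outer-product information correction — and is verified
against central finite differences in the test suite.

A subtlety matters in practice: with ~100 taxa, most concentration
parameters belong to rare taxa the data barely inform. Under an implicitly
uniform prior those near-flat directions make the evidence integral
improper, and the raw formula *rewards* extra components instead of
penalizing them. The score therefore computes the evidence under a diffuse
normal prior with standard deviation `prior_sd = 10` on each unconstrained
parameter:

$$\text{score} = -\log L + \tfrac{\|\hat\theta\|^2}{2\,\sigma_0^2} +
\tfrac{d}{2}\log \sigma_0^2 + \tfrac12 \log\det(H + I/\sigma_0^2).$$

A flat direction then contributes nothing (its prior and posterior widths
cancel), while a well-identified direction is penalized by half its log
curvature — the behavior the evidence is supposed to have. This mirrors what
the established DMM implementations achieve through their regularizing
priors. If the regularized Hessian still fails a Cholesky factorization,
negative curvature is floored at zero with a warning. `select_k()` fits each
K in `k_range` (default 1..7), reports the full score profile, and breaks
ties toward the smaller K.

`assign_enterotypes()` gives posterior probabilities (log-sum-exp) and MAP
labels; `enterotype_trajectories()` summarizes per-pig age-ordered label
sequences, per-age enterotype proportions and consecutive-age transition
counts. Because mixture labels are arbitrary, all comparisons against a
reference labeling go through `label_match_accuracy()`, which maximizes
agreement over component permutations.

## The microbiome maturation score

The score formalizes "how far along the adult trajectory is this sample"
without any regression on age:

1. **First appearance** (`first_appearance_ranks()`): per pig, a genus
   appears at the earliest age where its within-sample relative abundance
   exceeds `ra_threshold` (default 0.005, i.e. 0.5%). Genera are ranked
   within the pig by that age, ties receiving midranks. The threshold is
   applied per sample and is scale-free, so the score is invariant to
   sequencing-depth rescaling (property-tested).
2. **Concordance** (`kendalls_w()`): Kendall's W with the standard tie
   correction on the complete-case submatrix (genera ranked by every pig),
   with a permutation p-value that permutes each pig's ranks independently —
   the null of no between-pig concordance. Exhaustive enumeration of all
   within-pig permutations is available for tiny instances and is what the
   exactness tests use.
3. **Consensus order** (`consensus_order()`): genera sorted by their median
   rank across pigs (missing entries ignored), ties broken alphabetically so
   the order is reproducible.
4. **Score** (`maturation_scores()`): the mean consensus rank of the genera
   present in the sample (presence weighted 0/1 — the literal reading of
   presence/absence weighting; an abundance-weighted variant exists behind
   `abundance_weighted = TRUE` but is never the default).

Genera missing for a pig are excluded pairwise (complete-case per genus for
medians, complete-case submatrix for W); the alternative of assigning
max-rank-plus-one is deliberately not taken because it would let a single
low-coverage pig distort the consensus. The consensus is a single cross-pig
order (one score axis), not a per-pig order — the per-pig alternative would
make scores incomparable across pigs.

## Community metrics

- **CSS normalization** (`css_normalize()`): a sample's scaling factor is
  the sum of its counts at or below its own quantile-`q` nonzero count
  (default `q = 0.5`, type-7 quantile), and values are rescaled by
  `scale_constant = 1000`. The fixed median quantile is used rather than an
  adaptive quantile search: it is reproducible, and the adaptive rule's
  data-dependent quantile adds nothing at these sample sizes. Both knobs are
  arguments.
- **Alpha diversity** (`alpha_diversity()`): richness and Shannon diversity
  with the natural log; an all-zero sample gets richness 0 and Shannon 0 by
  documented convention.
- **Bray–Curtis** (`bray_curtis()`): $\sum_i |a_i - b_i| / \sum_i (a_i+b_i)$
  via `vegan::vegdist`; two all-zero samples are an error (the dissimilarity
  is undefined, not 0 or 1).
- **Beta-dispersion** (`beta_dispersion()`): distance to the group centroid
  in the principal-coordinates embedding with the standard
  negative-eigenvalue correction, via `vegan::betadisper` (group centroids,
  not spatial medians). Singleton groups get dispersion 0.
- **Shared features** (`shared_features()`): presence is a nonzero count in
  at least `min_samples` samples of the group (default 1, exposed because
  prevalence-filtered presence is a defensible alternative); counts are
  reported for every nonempty presence combination plus the all-group
  intersection.

## PERMANOVA with strata

`permanova()` implements the distance-based ANOVA directly: Gower-center
$G = -\tfrac12 J D^2 J$, then sequential (Type-I) sums of squares through
projection matrices of the growing design — term order matters and follows
the model statement (age, then cohort). The pseudo-F per term uses the
residual mean square; p-values come from permuting sample labels, **within
levels of the `strata` variable** when given, which is how repeated sampling
of the same pig is respected: pigs are not exchangeable, but a pig's
time points are under the null. Monte-Carlo p-values use the add-one
correction $(1 + \#\{F^\pi \ge F\})/(1 + B)$ so p is never zero; with
`complete = TRUE` the (restricted) permutation group is enumerated and the
p-value is the exact proportion, identity included. A degenerate input with
all-equal distances returns $R^2 = 0$, $p = 1$ rather than 0/0.
`pairwise_permanova()` applies the same machinery to every pair of group
levels with BH adjustment across pairs. vegan's `adonis2` is used in the
test suite as an independent cross-check of the statistics, never as the
implementation.

## Random-intercept mixed models

`fit_random_intercept_lmm()` fits $y = X\beta + b_{g} + e$,
$b_g \sim N(0, \sigma_b^2)$, $e \sim N(0, \sigma_e^2)$, by profiling the
variance ratio $\lambda = \sigma_b^2/\sigma_e^2$: for fixed $\lambda$ the
compound-symmetry structure gives closed-form per-group inverses
($V_g^{-1} = I - \tfrac{\lambda}{1+\lambda n_g} J$), so the REML criterion
is a smooth 1-D function minimized with `optimize` over
$\log\lambda \in [-15, 15]$. An optimum at the lower edge is refitted at
exactly $\lambda = 0$ and flagged `boundary`. Fixed effects are the GLS
estimates at the optimum with Wald tests against the normal reference —
appropriate at these sample sizes and verified against lme4 to six decimals
in the tests (lme4 is the cross-check, not the engine; the closed-form
route also honours the degenerate contract that singleton groups reduce
exactly to OLS). Alpha-diversity models additionally include the raw read
count as a fixed covariate, because sequencing depth differs systematically
by age. Post-hoc age contrasts are Wald contrasts with BH adjustment; a
studentized-range (Tukey) reference for mixed models is out of scope and
this substitution is documented here deliberately.

`differential_abundance_scan()` runs that model per genus on
$\log(\text{CSS value} + \text{pseudo})$ with fixed effects age (continuous,
weeks) and cohort and a pig random intercept. The pseudo count is half the
genus's smallest nonzero normalized value — the single largest interpretive
choice in this module, chosen because the pipeline feeds CSS-normalized
values (log of zero must be avoided without flattening low-abundance
genera). Genera below 0.01% mean relative abundance are filtered; trends
are classified by the age-coefficient sign at `p < 0.05` and BH `q < 0.25`
(both exposed, since stricter thresholds like q < 0.01 are natural for
final reporting).

## AMR trends: penalized splines with continuous-time AR(1)

`fit_penalized_spline_ar1()` models log10 CFU/g against age as a cubic
B-spline on an **equally spaced** knot grid (default `n_knots = 9` over the
observed range) with a second-order difference penalty and a linear,
centered cohort term. Equal spacing is chosen over age-quantile placement
because the difference penalty's null space is then exactly the polynomials
of degree `penalty_order - 1`: heavy smoothing shrinks the fit onto a
straight line, a contract the tests exercise directly (`lambda = 1e12`
reproduces the GLS line). The smoothing parameter is selected by GCV on the
whitened problem over a wide log-spaced grid; with only nine distinct ages
the effective degrees of freedom saturate near the number of distinct ages.

Within-pig errors follow a stationary continuous-time AR(1),
$\mathrm{corr}(e_s, e_t) = \phi^{|s-t|}$ in weeks, appropriate for the
irregular age spacing. Estimation iterates penalized fit → profile-ML
estimate of $\phi$ from within-pig lagged residual innovations → GLS refit
on the per-pig Cholesky-whitened problem, until $\phi$ moves less than
1e-4 (max 20 passes; $\phi$ estimates outside $(-0.999, 0.999)$ are clipped
with a warning; a residual variance of zero fixes $\phi = 0$). The
coefficient covariance is $\hat\sigma^2 (X'X + \lambda P)^{-1}$ from the
penalized GLS normal equations.

`derivative_band()` evaluates the analytic first derivative of the basis and
its pointwise variance; bands are **pointwise** at the requested level, not
simultaneous — so under a flat truth, isolated grid points will exceed the
band at roughly the nominal rate, and narrow spurious windows are possible.
`significance_windows()` returns the maximal intervals where the lower bound
is positive (increasing) or the upper bound negative (decreasing), with
endpoints linearly interpolated at the bound's zero crossing. No
extrapolation outside the fitted age range is permitted.

Zero-growth plates are left-censored at the detection limit and excluded
from the trend fit by default (recorded as missing log10 CFU); substituting
half the detection limit is a config alternative in the generator, but
inventing $-\infty$ values is not. Drug/bacterium combinations with no
resistant growth anywhere (fluoroquinolones for both indicators; quinolones
for coliforms) are excluded from the modeled set. qPCR outcomes — absolute
and 16S-standardized log10 copies (`standardize_gene_copies()`) — are
modeled with the random-intercept LMM using age as categorical contrasts
(`qpcr_age_models()`); the smooth-trend machinery is reserved for the
plate-count outcomes.

## The synthetic cohort generator

`cohort_config()` fixes the study conditions; the generators are first-class
tested code, not fixtures. What it emulates:

- the 18-pig / two-cohort / nine-age design with the 8-pig (4+4) profiled
  subset: 162 metadata records, 72 sequenced samples;
- a four-component enterotype trajectory E1 (weeks 3–6) → E2 (10–12) → E3
  (22) → E4 (32 on), with 2 of the 8 profiled pigs reverting to E3 at weeks
  49–53 and 6 retaining E4. Profiles are anchored by named dominant genera
  (Rikenellaceae-RC9/Prevotella/UCG-002; Megasphaera/Streptococcus;
  Streptococcus/Clostridium/Treponema; Treponema/Clostridium) with the
  remaining mass decaying geometrically over filler taxa, rotated per
  component so profiles are mutually well separated. Anchor weights are free
  configuration with these documented defaults — dominance ordering is what
  is known, exact proportions are not;
- age-increasing alpha diversity induced purely through a monotone total
  Dirichlet concentration (30 at week 3 rising to 95 from week 49), which
  isolates the diversity effect from composition shifts;
- per-age log-normal library sizes with a lower week-3 mean (meanlog
  log 50,000 at week 3 versus log 150,000 later), loosely calibrated to an
  overall average of ~150 K reads with a depressed earliest age — these are
  plausibility defaults, not estimates;
- fungal counts: 291 taxa in two phylum groups with the first dominant, one
  DM component with total concentration 2.5 (hence low diversity and large
  inter-pig variance), and a 4-fold concentration bump in five Candida-like
  taxa at the parturition age;
- AMR plate counts: per (bacterium, drug) piecewise-linear mean log10 CFU/g
  curves on the age grid — high at week 3, declining to ~week 10,
  class-specific rises between weeks 12 and 32, smaller late-gestation
  changes — plus a stationary continuous-time AR(1) pig process
  ($\phi = 0.85$/week, sd 0.5) and white noise (sd 0.2), censored below a
  detection limit of 2 log10 CFU/g;
- qPCR: absolute log10 copies/g curves anchored at week-3 means of 7.10 for
  tet(A) and 5.35 for bla-CTX-M, declining through week 10 and partially
  rebounding; a near-flat 16S curve set so the standardized week-3 tet(A)
  mean is −3.6; pig random intercepts (sd 0.25) and noise (sd 0.2). With
  both set to zero the week-3 means are exact.

What it does **not** emulate — and therefore what passing tests do not show
about real data: compositional zero-inflation beyond what the DM induces,
taxonomic misassignment, primer or extraction batch effects, diet and
housing covariates, chimeras or depth-dependent contamination, and any
genotype–phenotype linkage between AMR genes and taxa. Recovery results on
the generator certify the estimators, not the biology.

All generator randomness derives from `config$seed` through per-stage
sub-seeds (a stage-name hash), so each `generate_*` function is
independently reproducible; the same scheme drives `run_pipeline()`, whose
stages can be rerun in isolation. Outputs are TSV plus a JSON manifest.

## Problem sizes used in the shipped checks

The test suite exercises the estimators at the study's own scale — 72
samples by 100 taxa for enterotyping (selection over K = 1..7 across ten
seeded cohorts), 162 plate-count observations per drug class — and scales
the harder recovery checks to 60–100 pigs where the quantity of interest
(AR(1) $\phi$, change windows) needs more series than eight pigs provide.
Null-calibration checks (PERMANOVA and LMM type-I error) use 500 simulated
datasets at 12 samples and 30 pigs respectively. These sizes are the
package's own validation choices: large enough for the stated tolerances,
small enough to run everywhere.

## Known limitations

- Enterotype inference treats samples as exchangeable given the component:
  the mixture ignores the repeated-measures structure, exactly as the
  standard DMM enterotyping workflow does; the longitudinal structure is
  recovered downstream in the trajectory summaries.
- The Laplace evidence is a mode-based approximation; with very small
  sample counts per component it can be unstable, which is why empty
  components are pruned and the score regularized.
- Derivative bands are pointwise; families of windows across many drug
  classes carry the corresponding multiplicity.
- The maturation score depends on the 0.5% presence threshold; genera
  hovering at the threshold can flip presence between adjacent ages.
- `fit_random_intercept_lmm()` supports exactly one random intercept; no
  crossed or nested random effects, no zero-inflated or log-ratio DA models.
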