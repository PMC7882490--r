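---
title: "Methods: heaping-aware analysis of bounded belief surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heaping-aware analysis of bounded belief surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskbeliefs)
```

## The problem

During an epidemic, people act on their beliefs about three quantities: how
deadly the disease is (the infection fatality ratio, IFR), how likely they
are to catch it, and how much of it there will be in the population
(prevalence). Surveys elicit these on bounded 0--100 scales. Three
methodological problems follow, and this package addresses each:

1. **Response heaping at 50.** On a 0--100 scale, "50" often means "no
   idea" rather than a numeric judgment of one half. A mass of such
   fifty-fifty answers biases item means toward 50.
2. **Benchmarking.** Calling a belief optimistic or pessimistic requires an
   objective reference: IFR and prevalence computed from recorded deaths,
   diagnosed cases and population counts, stratified the same way as the
   respondents.
3. **Bounded outcomes with survey weights.** Regressions of 0--100 items
   on covariates need a mean model that respects the bounds and the
   post-stratification weights, and effects reported on the probability
   scale.

## The heaping ("50-blip") procedure

For an item vector $x_1, \dots, x_n \in [0,100]$, responses are rescaled to
$(0,1)$ by $x/100$ and boundary-shrunk with the Smithson--Verkuilen
transform $x' = (x(n-1) + 0.5)/n$, so exact 0s and 100s stay in the sample
at finite likelihood. A beta law $\mathrm{Beta}(\alpha, \beta)$ is fitted by
maximum likelihood (`fit_beta()`, BFGS on $(\log\alpha, \log\beta)$ from a
method-of-moments start; a pure moments fit is available via
`method = "moments"`). The excess-50 statistic (`excess_fifty()`) is

$$\text{excess} = 100\left[\hat F_n(45 \le x \le 55) -
  \left(I(u;\hat\alpha,\hat\beta) - I(\ell;\hat\alpha,\hat\beta)\right)\right],$$

the observed share of responses in the closed 45--55 window minus the
window mass the fitted beta predicts, with $I$ the regularized incomplete
beta function.

Numerical choices worth stating:

* **Continuity correction.** Responses are integers, so recorded values
  45..55 correspond to latent values in $[44.5, 55.5)$. The expected mass
  therefore uses $\ell = 0.445$, $u = 0.555$ by default. Without the
  correction the expected mass under-covers the category by about one
  point for items with typical spread, and a heap-free item would show a
  spurious excess of roughly $+0.9$ points; with it, simulated heap-free
  items center at an excess of 0. The uncorrected window
  ($\ell = 0.45, u = 0.55$) remains available via `continuity = FALSE`.
* **The 50s stay in the fit** by default: the statistic models the full
  observed distribution, and the heap is part of it. This costs a small
  downward bias in recovered excess when the heap is large (about
  $-0.7$ points at a 15% heap in the recovery simulations) because the
  contaminated fit inflates the expected window mass; `include_fifty =
  FALSE` refits without the 50s for sensitivity analysis.
* **Estimand.** Under the generator, the true excess is
  $100\,\pi_{50}(1 - m)$ with $\pi_{50}$ the heap mass and $m$ the beta
  mass of the (rounding-corrected) window — not $100\,\pi_{50}$, because a
  heaped respondent who would have answered inside the window anyway adds
  no excess. `true_excess_fifty()` computes it; recovery tests measure
  bias against it.

The impact of the heap on location is reported by
`heaping_adjusted_means()`: the item mean as a proportion, the mean
excluding exact 50s, and the p-value of an OLS regression of demeaned
responses on the indicator $1\{x = 50\}$ — algebraically the
pooled-variance two-sample t test of the 50-group against the rest (the
suite asserts the identity numerically). The per-item report
(`heaping_table()`) is computed unweighted: heaping is a property of the
raw response distribution, not of the weighted population estimate.

## Objective benchmarks

From a stratified count table (deaths, diagnosed, population),
`compute_rates()` returns $\mathrm{IFR} = 100\,d/c$ and prevalence
$100\,c/N$. Strata with no diagnosed cases carry an explicit undefined
marker, never a silent zero. Contrasts against a reference stratum use
true odds ratios on the proportion scale
(`odds_ratio_table()`); at the observed magnitudes (prevalence well under
1 per 100) the odds ratio and the rate ratio are numerically
indistinguishable, so nothing downstream depends on that choice.
Aggregation (`aggregate_strata()`, e.g. 13 regions into 3 incidence tiers)
sums counts and recomputes rates from the pooled counts; averaging
per-stratum rates would weight small strata incorrectly, and a property
test forbids it.

## Calibration comparisons

`paired_test()` is the classical paired Student t on within-respondent
differences after listwise deletion, with exact one- or two-sided
p-values; degenerate inputs (constant differences) return $t = 0, p = 1$
rather than NaN. `classify_pairs()` counts higher/equal/lower pairs with
an equality tolerance defaulting to 0 — on integer items, "similar" most
plausibly means exact equality. `proportional_slope()` is no-intercept
OLS, $b = \sum xy / \sum x^2$ with
$SE = \sqrt{\sum(y - bx)^2/(n-1)}\,/\sqrt{\sum x^2}$.
`stratified_gap()` subtracts benchmark prevalence (per 100) from the mean
0--100 belief per stratum; positive gaps mean over-stated risk. Paired
tests are unweighted by default, matching plain survey reporting of such
tests; the gap function exposes a weighting toggle.

## Comparative optimism

The index is $(q_4 - q_2 + 100)/200$: the unique affine map of the
difference between expected prevalence and own risk onto $[0,1]$ with 0.5
at equality. By linearity, the per-wave index mean equals
$(100 - \overline{q_2 - q_4})/200$ exactly, and the paired t on
$q_2 - q_4$ is the same test as the t of the index against 0.5. The wave
contrast comes from a weighted quasibinomial logit GLM of the index on a
wave indicator — the same machinery as the main regressions — with the
indicator's robust p-value reported. Covariates beyond the wave indicator
are deliberately omitted from this contrast; the question is whether the
population gap moved, not its composition.

## Weighted quasibinomial regression and marginal effects

`fit_quasibinomial()` models $E[y] = \mathrm{logit}^{-1}(X\beta)$ with
variance $\phi\,\mu(1-\mu)$, fitted by iteratively reweighted least
squares to `epsilon = 1e-10` (at most 100 iterations), post-stratification
weights multiplying the working weights. Quasi-likelihood needs no integer
support, so continuous slider proportions — including exact 0s and 1s,
guarded by a $10^{-10}$ floor on $\mu(1-\mu)$ in the variance — are valid
outcomes. Dispersion is the Pearson statistic over residual degrees of
freedom. The default covariance is the design-robust sandwich
$B^{-1} M B^{-1}$ with $B = X^\top \mathrm{diag}(w\,\mu(1-\mu))\,X$ and
$M = \sum_i w_i^2 (y_i - \mu_i)^2 x_i x_i^\top$; a model-based option
exists. Separation and non-convergence are flagged, never silent.

`average_marginal_effects()` reports, for each non-reference factor level,
the weighted mean over records of the fitted-probability contrast against
the reference level with all other covariates at observed values, and for
numeric terms the mean derivative (central difference, step $10^{-6}$).
Standard errors use the delta method with a numerically differentiated
Jacobian (central differences, step $10^{-6}$ on each coefficient).
Reference levels follow the first-listed category of each codebook
variable, fixing sign conventions. The suite cross-checks the fit against
an independently coded IRLS loop (to $10^{-15}$ in practice), the robust
covariance against an established sandwich implementation, the
single-binary-covariate AME against its closed form, and the delta-method
SEs against a 200-resample bootstrap (agreeing within 5% on the fixture,
tested at 20%).

## What the generator emulates — and what it does not

`generate_survey()` produces two waves matching the study conditions:
1005/1004 respondents; demographics drawn independently from the published
margins; items drawn as $100 \cdot \mathrm{Beta}(a, b)$ rounded to
integers, with $\mathrm{logit}$-scale covariate effects (gender, age band,
incidence tier) on the beta mean; a point mass $\pi_{50}$ of exact 50s
(replacement mixture, defaults set from the published excess percentages:
0.12 for own risk, 0.15 for others' risk, 0.02 for prevalence, 0 for
IFR); per-item MCAR missingness at the published per-item rates; wave
shifts applied to the beta mean on the native scale (+11.5 points own
risk, −11.1 expected prevalence), so the configured shift equals the
generated shift in means by construction; and post-stratification weights
on gender × age cells, normalized to mean 1. Beta means and precisions are
moment-matched to the published wave-1 means and SDs. Incidence-tier
population shares (0.34/0.39/0.27) are approximate metropolitan population
shares of the three region groups, which the source tables do not print.

Deliberate simplifications, hence limits on what passing tests show about
real data: missingness is MCAR, not informative; items are correlated only
through shared demographic predictors (no residual copula); heaping is a
replacement mixture at 50 only, though the configuration accepts any
anchor; demographics are drawn independently from margins rather than a
joint census table; and the stratum count generator uses a plain binomial
cascade (diagnosed ~ population, deaths ~ diagnosed). Real heapers may
also round to 0, 100 or multiples of 10, and real nonresponse is unlikely
to be MCAR.

## Problem sizes and reproducibility

Recovery simulations use 100 generator seeds of $n = 1000$ responses per
heap mass ($\pi_{50} \in \{0, 0.05, 0.15\}$), the bootstrap comparison 200
resamples of $n = 300$, and the optimism recovery 1000 respondents per
wave — sizes at which Monte-Carlo error is a fraction of the tolerances
being asserted. All randomness flows from explicit integer seeds;
`run_pipeline()` derives a named substream per stage so toggling stages
does not perturb the others, and two runs with the same configuration are
byte-identical. The `analysis/` scripts run the full workflow on the
simulated study and write every table under `results/`;
`scripts/acceptance.R` recomputes the headline quantities from scratch for
any seed.

## Known limitations

* With a large heap, the default fit-including-50s under-recovers the
  excess by up to about 1 point; the exclusion flag trades that for a
  different (bulk-shape) bias.
* The beta MLE assumes a unimodal-or-U bulk; strongly bimodal response
  distributions would make the expected window mass unreliable.
* Odds-ratio contrasts require a reference rate strictly inside (0, 100).
* The regression machinery reproduces the published estimation pipeline,
  not the published coefficients: those require the original deposited
  dataset, which the codebook mechanism is designed to absorb.
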