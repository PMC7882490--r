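# riskbeliefs

Heaping-aware analysis of bounded belief-elicitation surveys, built for
repeated cross-sectional surveys that ask people to quantify epidemic risks
on 0–100 scales: the infection fatality ratio (IFR) of a disease, one's own
risk of catching it, the risk others perceive, and its expected population
prevalence. The package is aimed at survey methodologists and
epidemiologists who need to (a) detect and adjust for "fifty-fifty"
response heaping, (b) benchmark stated beliefs against recorded
case/death/population counts, and (c) model bounded, weighted outcomes —
and at analysts who want a fully synthetic, parameter-recoverable testbed
for that entire chain.

## The core statistics

**Excess-50 ("50-blip") detection.** On a 0–100 scale, "50" frequently
encodes epistemic uncertainty rather than the number one half. For each
item × wave, a beta law is fitted by maximum likelihood to the responses
(rescaled to (0,1) and boundary-shrunk by x′ = (x(n−1)+0.5)/n), and the
heap is measured as

    excess% = 100 · [ observed share of responses in [45, 55]
                      − ( I(0.555; α̂, β̂) − I(0.445; α̂, β̂) ) ]

with I the regularized incomplete beta function (the half-unit offsets are
the continuity correction for integer responses). Means with and without
the 50s, and the p-value of regressing demeaned responses on the indicator
1{x = 50}, quantify the heap's impact on location.

**Objective benchmarks.** From stratified counts, IFR = 100·deaths/diagnosed
and prevalence = 100·diagnosed/population, with odds-ratio contrasts
against a reference stratum and pooled-count aggregation (regions →
incidence tiers).

**Comparative optimism.** index = (q4 − q2 + 100)/200 ∈ [0, 1], where q2 is
own risk and q4 expected prevalence; 0.5 means neutrality, above 0.5
comparative optimism. Per-wave paired t tests and a quasibinomial GLM wave
contrast track its dynamics.

**Survey-weighted quasibinomial GLM.** E[y] = logit⁻¹(Xβ) with variance
φ·μ(1−μ), post-stratification weights in the working weights, Pearson
dispersion, design-robust (sandwich) covariance, and average marginal
effects with delta-method standard errors on the probability scale.

A synthetic generator (`generate_survey()`, `generate_stratum_counts()`)
emulates the full data structure — demographic margins, beta-distributed
items with covariate effects, a configurable heap mass π₅₀, per-item
missingness, wave shifts, post-stratification weights — with the generating
truth attached, so every estimator is tested by parameter recovery.

## Worked example

```r
library(riskbeliefs)

# two-wave survey at the study conditions (n = 1005 / 1004)
sim <- generate_survey(generator_config(seed = 20260901))
survey <- sim$table

heaping_table(survey)[, c("item", "wave", "excess_pct",
                          "mean_proportion", "mean_without_50s")]
#>    item           wave excess_pct mean_proportion mean_without_50s
#>  1 q1_ifr             1      0.303           0.156            0.154
#>  3 q2_own_risk        1      9.50            0.338            0.318
#>  5 q3_others_risk     1     11.7             0.486            0.484
#>  7 q4_prevalence      1      3.56            0.433            0.430
#>  ...

optimism_dynamics(survey)
#> Comparative optimism by wave (q2 - q4, 0-100 points):
#>  wave n_pairs mean_q2_minus_q4      p_value index_mean
#>     1     505        -10.64554 1.167164e-11  0.5532277
#>     2     503         13.32604 4.819322e-17  0.4333698
#> Wave contrast (GLM on index): AME = -0.1201, p = 1.46e-27
```

Reading the output: the IFR item (generated without a heap) shows ~0 excess
50s while own-risk (generated with π₅₀ = 0.12) shows ~9.5% excess, and
dropping its 50s moves the wave-1 mean from 0.338 to 0.318 — the heap pulls
the mean toward 0.5. The optimism index starts above 0.5 (respondents rate
their own risk 10.6 points below expected prevalence: comparative optimism)
and falls below 0.5 in wave 2 (+13.3 points: comparative pessimism), driven
by the generated +11.5/−11.1-point wave shifts; the GLM wave contrast is
strongly significant.

The `analysis/` directory runs the whole workflow as numbered scripts
(simulate → descriptives → benchmarks → heaping → calibration → optimism →
regression), each printing what it finds and writing its tables under
`results/`. The same chain is callable as one function, `run_pipeline()`.

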