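---
title: "Measuring socioeconomic inequality in the costs of seeking care"
author: "equicost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring socioeconomic inequality in the costs of seeking care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equicost)
```

## The problem

Patients pay for primary care twice over: directly, through transport fares
and point-of-use medical charges, and indirectly, through the minutes spent
travelling, waiting and in consultation. In low-income settings these
burdens are not spread evenly — the poorest often walk long distances to
free public facilities and wait longest, while wealthier patients pay more
in money but less in time. `equicost` quantifies that distribution from
patient exit-interview data: one row per patient, with travel mode, three
time components (minutes), two cost components (local currency), facility
and service descriptors, residence, and a battery of household asset
indicators.

## The wealth index

Household living standards are proxied by an asset-based wealth index:
each indicator is standardised to zero mean and unit variance and the
patient's score is the projection onto the first principal component of the
standardised indicator matrix. PCA is run on the correlation scale, the
standard choice when binary and ordinal items are mixed; categorical items
must be one-hot expanded by the caller, since the item list is survey
configuration rather than code. Eigenvectors are sign-ambiguous, so the
score is oriented to correlate positively with the row-sum of standardised
indicators: higher score = wealthier. Constant indicators carry no
information and are dropped with a warning.

From the scores, `fractional_ranks()` places each patient in (0, 1) as the
cumulative population share up to the midpoint of their position —
\((i - 0.5)/n\) for the \(i\)-th poorest with unit weights and no ties.
Tied scores receive the midpoint rank of their tie block (equivalently, the
average of the ranks the tied positions would occupy). This choice, on
which the source data are silent, preserves the weighted mean rank of
exactly 0.5 — the identity the concentration index relies on — and means
ties can never straddle a quintile boundary, because quintiles are cut on
the rank itself: quintile \(= \min(\lfloor 5R \rfloor + 1,\, 5)\), with 1
the poorest fifth.

## The inequality measures

Three complementary measures are computed per outcome:

* **Equity gap** — the absolute difference in group means (poorest minus
  least-poor quintile, or rural minus urban), tested with a Welch
  two-sample t-test. Welch rather than pooled-variance is used because the
  zero-inflated cost outcomes have wildly different group variances.
* **Equity ratio** — the quotient of the same means; a zero denominator
  yields an explicit undefined value rather than infinity.
* **Concentration index** —
  \(CI = \frac{2}{\mu}\,\mathrm{cov}(y_i, R_i)\), twice the covariance
  between outcome and fractional wealth rank over the outcome mean.
  Negative values concentrate the burden among the poor. The covariance
  uses the population convention (divisor = total weight), which makes the
  unit-weight identity \(CI = 2\sum y_i R_i /(n\mu) - 1\) exact; the
  sample-covariance variant differs by \((n-1)/n\) and is not used.

Inference for the CI comes from the *convenient regression*: OLS of
\(z_i = 2\,\mathrm{var}(R)\,y_i/\mu\) on \(R_i\) has slope exactly equal to
the CI (the \(n/(n-1)\) factors cancel between numerator and denominator),
and its heteroskedasticity-robust (HC1) standard error gives a two-sided
normal test of CI = 0. This doubles as a second, independent implementation
of the point estimate, which the test suite exploits. Constant outcomes
have no sampling variability and are reported as se = 0, p = 1. The robust
SE was validated against a 2000-resample pairs bootstrap at n = 500
(agreement within 15%). Which SE the original analysis used is not
recorded, so starred significance levels are not promised to replicate
exactly.

Significance stars follow the conventional strict thresholds: `***` below
1%, `**` below 5%, `*` below 10%; a p-value exactly at a threshold gets the
weaker star.

Binary outcomes (probability of paying, travel-mode shares) run through the
same machinery as plain indices. No Wagstaff or Erreygers bounded-outcome
normalisation is applied — the attainable range of a plain CI on a binary
variable shrinks with its mean, which should be kept in mind when comparing
indices across outcomes.

## The cost pipeline

Travel time and transport cost are stored as one-way values at ingest;
`apply_convention()` doubles exactly those two fields for round-trip
reporting and refuses to double twice. Waiting, consultation and medical
cost never change with the convention. Currency is converted at the
survey-period rate (1600 TZS per USD, configurable) at full precision;
rounding (2 decimals for USD, 1 for minutes, 1 decimal percent for shares)
happens only in reporting.

Each outcome is analysed on its own complete-case subset — per-variable
item nonresponse is simply dropped, with the per-cell n recomputed after
every restriction and never cached. No imputation and no outlier trimming
are applied: the source tables imply per-row n's consistent with plain
complete-case analysis, and no trimming rule is documented, so none is
invented. Share decompositions treat time (minutes) and direct costs (USD)
as separate families, since the study could not value time in money.

Mode-specific rows filter on travel mode before summarising; "for all"
rows pool modes. For mode-specific transport cost both the all-users and
the payers-only variants are emitted, labelled, because the source tables
are ambiguous about which conditioning was used. The public-facility
robustness restriction (`restrict_public_only`) reruns everything on the
public subset; the ownership stratifier is then degenerate and skipped.

## The synthetic survey

`generate_survey()` emulates the study conditions so the pipeline can be
validated end-to-end without the deposited data: 1407 patients in 150
facilities (at most 10 per facility), 82% public facilities, 82.8% rural
residents, 42 binary asset indicators loading on a standard-normal latent
wealth \(w\), a rank-dependent multinomial logit giving ~71% foot travel
with a pro-rich motorised share, and payment probabilities of 21.3%
(transport, non-foot travellers only — walking is free) and 17.8%
(medical, with a mild pro-rich logistic slope of 0.95 on the rank).

The core design choice is that every continuous outcome has mean linear in
the true fractional rank, \(E[y\,|\,R] = a + bR\), because that form has a
closed-form large-sample concentration index

\[ CI_\infty = \frac{b}{6a + 3b}, \]

obtained from \(CI = 2b\,\mathrm{var}(R)/\mu\) with
\(\mathrm{var}(R) \to 1/12\) and \(\mu = a + b/2\). The generator therefore
supplies a quantitative oracle the field data cannot: the pipeline's
estimated CI must land within ±0.02 of \(b/(6a+3b)\) at n = 10,000, and
the poorest-minus-least-poor gap under true ranks equals \(-0.8\,b\).
Defaults are tuned to the headline magnitudes of the target survey
(travel a = 40, b = −20 minutes, so mean 30 and \(CI_\infty = -1/9 \approx
-0.111\); waiting a = 54.5, b = −15.6; consultation flat at 12.9), so the
generated tables are visually comparable to the published ones — but no
claim of distributional fidelity is made.

Noise families are gamma for times and lognormal for payment amounts,
reflecting the right-skew of self-reported durations and expenditures; the
zero medians of the cost outcomes arise from the payment (zero-inflation)
layer, not the continuous family. Item nonresponse is missing completely
at random at the per-outcome rates observed in the target survey (18.8%
for travel time down to 0.6% for medical cost). Mode-choice intercepts
(−3.844 for car, −2.017 for motorbike/bicycle, with rank slopes 3 and 1.5)
and the rural and medical-payment logit intercepts were calibrated once,
by numerical integration, to hit the configured population shares.

What the generator does *not* emulate: facility-level clustering of
unobservables, informal payments, care-seeking selection (only attenders
are observed), any direct residence or facility effect on outcomes (rural
and facility gradients arise solely through their correlation with
wealth), and rounding of self-reported minutes. Passing tests on synthetic
data therefore demonstrate the estimators are correct, not that real
exit-interview data satisfy the generating assumptions.

## Numerical and degenerate-input choices

* Ranks are recomputed within each outcome's complete-case subset (scores
  are computed once on the full sample), so the mean-rank-0.5 identity
  holds in every estimation sample.
* An all-zero outcome has an undefined index and raises an error; a
  constant positive outcome has CI = 0 with p = 1.
* `equity_gap` on two constant, equal groups returns p = 1 rather than a
  t-test failure.
* Quintile extremes with fewer than 2 observations per cell report the gap
  without a p-value.
* All simulation randomness flows from a single mandatory seed; identical
  seeds give byte-identical surveys and analysis tables.

## Problem sizes used in validation

The test suite validates estimator identities on 1000 random samples of
n = 5–500, parameter recovery on 20 surveys of n = 10,000 (CI within
±0.02 of the closed form), wealth-index recovery at n = 2000 with 20
indicators (rank correlation > 0.8), and the bootstrap SE comparison at
n = 500 with 2000 resamples. These sizes give Monte-Carlo error well below
each asserted tolerance.

## Known limitations

The index is descriptive: no need-standardisation, no decomposition into
contributing factors, no dominance testing, and no survey weights (the
target analysis is unweighted; the rank and CI code accept weights, the
inference path assumes unit weights). Catastrophic-expenditure and
impoverishment measures and monetary valuation of time are out of scope.
Replication against the deposited field data requires obtaining the
deposit separately and mapping its variable dictionary onto the canonical
schema via a key-value schema file; `replicate_study()` then reports the
headline figures.
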