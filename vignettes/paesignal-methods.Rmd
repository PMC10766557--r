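---
title: "Methods: three-stage pandemic adverse-event screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-stage pandemic adverse-event screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paesignal)
```

`paesignal` screens spontaneous adverse-event (AE) report streams for events
whose reporting changed with the onset of a public-health emergency. This
vignette is the package's account of the model: what each stage assumes, the
tunable parameters and their defaults, what the synthetic generator does and
does not emulate, the numerical choices, and the limitations a user should
know about.

## The data model

Each report is a tuple: a drug set, an AE set, patient age (years), sex
(1 = male, 2 = female), weight (kg), reporter qualification (1 physician,
2 pharmacist, 3 other professional, 4 lawyer, 5 consumer), a six-flag
severity vector (death, life-threatening, hospitalization, disability,
congenital anomaly, other) and the submission date, carried both as a
calendar date and as days since the calibration date 2000-01-01. Unknown
values are explicit `NA` sentinels and propagate: a cohort filter excludes
unknowns only for the attribute it filters on, so a sex-filtered cohort
drops unknown-sex reports while an unfiltered one keeps them.

Cases may be submitted repeatedly; `deduplicate_reports()` keeps the latest
submission per case number. Because "latest" does not disambiguate equal
dates, ties break by the larger version number and then by input order
(later row wins); the output is sorted by case id so results never depend on
input order.

The analysis window is 11 March – 30 September, compared across years
2013–2020. Window membership is decided by month–day comparison inside each
year, which treats leap years uniformly and is inclusive at both endpoints.

## Stage 1: disproportionality

For each AE the 2×2 table (rows: pandemic-window year 2020 / comparator
2019; columns: AE present / absent) yields the reporting odds ratio β with
the Wald 95% CI on the log scale (`z = 1.96`) and a two-tailed Fisher exact
p, Bonferroni-corrected over the family of AEs actually tested. Enriched
means adjusted p < α and lower CI bound > 1; purified means adjusted
p < α and upper CI bound < 1. Defaults: α = 0.05.

Choices the estimator forces:

* **Zero cells.** The Fisher test handles zeros exactly, so p-values use raw
  counts. The odds ratio and CI are undefined on zero cells; the
  Haldane–Anscombe correction (+0.5 on all four cells, flagged in the
  output) is the standard remedy in disproportionality analysis.
* **Eligibility.** An AE enters testing only with ≥ `n_min` (default 3)
  reports across the two years. Untestable singletons would inflate the
  Bonferroni family without any power to reject.
* **Family size.** The family is the set of AEs tested in the current
  screen, not the full vocabulary: correction is applied per analysis.
* **Tail rule.** The two-sided Fisher p sums all point hypergeometric
  masses not exceeding the observed one, with the customary 1e-7 relative
  slack so exact ties are not broken by floating-point representation.
  The denominator of β counts all cohort reports in the year, not only
  AE-bearing ones.
* **Exclusions.** Terms that name the pandemic pathogen itself (e.g.
  "covid-19") are tested and reported but flagged excluded: their
  association with the pandemic period is definitional, not a drug-safety
  signal.

## Stage 2: trajectory deviation (PAEAI)

A year-over-year change may simply continue an AE's own trend. The yearly
proportion trajectory `v_2013..v_2020` is modelled per AE by an AR(2) with
intercept, `v_k = c + φ₁ v_{k−1} + φ₂ v_{k−2}`, fitted by conditional least
squares on the five equations k = 2015..2019. With five usable equations and
three parameters this is the only well-posed simple estimator, and it is
deterministic; Yule–Walker or ML estimation is neither stable nor necessary
at this length. The intercept is included because proportions are not
mean-zero (it can be disabled). Predictions are one-step-ahead from
*observed* lags, so the 2020 prediction uses the observed 2018–2019 values.
Residuals `e_k = v′_k − v_k` are standardized by `√((1/6) Σ_{2015..2020} e²)`
— their squares then sum to 6 — and

`PAEAI = log₁₀( |r_2020| / ((1/5) Σ_{2015..2019} |r_k|) )`.

The standardization constant cancels in the ratio, so the index equals
`log₁₀(|e_2020| / mean |e_hist|)`. The logarithm base is configurable;
base 10 is the default because the index is read as orders of magnitude
(any base preserves the sign, which is all the screen uses).

Numerical edges:

* A rank-deficient design (constant or collinear history) falls back to the
  intercept-only mean predictor and is flagged degenerate.
* `|e_2020| = 0` (exactly on trend) maps to `−Inf`; this is checked first,
  so a perfect fit everywhere still reads "on trend". A zero historical mean
  residual with a nonzero 2020 residual maps to `+Inf`. Both are flagged.
* R² is computed over the five fitted (training) points, not the 2020
  prediction, and is `NA` for a constant history.
* Predictions are not clamped to [0, 1]; residuals are used as-is.

**Known limitation — positive bias.** In-sample residuals of a 3-parameter
fit on 5 equations are shrunk, while the 2020 residual is out-of-sample, so
under pure noise `|e_2020|` exceeds the historical mean more often than not
and PAEAI is positive in roughly 60–90% of null replicates (simulation at
5,000 reports/year). PAEAI is therefore a *deviation filter* that orders and
separates shocked trajectories from on-trend ones — a genuinely on-trend
grower scores far below a shocked AE of the same size — not a calibrated
test; family-wise error control in the pipeline comes from Stages 1 and 3.

## Stage 3: drug interference

Two failure modes remain after Stage 2: the AE co-occurs with drugs without
being associated with any, or it is associated with a drug whose pair
reporting did not actually change with the pandemic. For each surviving AE,
every drug co-occurring with it in the 2020 window is a candidate.

**Matching.** For a drug, all exposed 2020 reports form the test group; each
test report (processed in ascending case-id order) receives the `ratio`
(default 10) unexposed reports with the highest cosine similarity between
characteristic vectors, without replacement, so `|C| = ratio·|T|` when the
pool suffices (flagged `short_match` otherwise). Ties break by (similarity,
case id), making the matching fully deterministic. The characteristic
vector is `[age, sex, weight, qualification, b₁..b₆, t]`; sex and
qualification enter as their integer codes (a one-hot alternative would
change distances but not the contract; the integer coding mirrors the
vector's definition). Each component is z-scored over the cohort before the
cosine — age (years), weight (kg) and t (days) live on wildly different
scales and the day count would otherwise dominate the similarity. Missing
age/weight are imputed with the cohort median and missing sex/qualification
with a dedicated 0 level, with an imputation mask retained. Matching is
without replacement because re-used controls would appear multiple times in
the γ table and artificially sharpen it.

**γ and δ.** γ is the drug–AE odds ratio computed *within* the matched set
(a cohort-wide variant is available behind a flag for sensitivity
analysis); δ is the pair-versus-pandemic odds ratio over the full 2019 and
2020 cohorts — its 2019 cells cannot come from any matched 2020 set. Both
use the same CI, Fisher and zero-cell machinery as Stage 1; the Bonferroni
family for γ is all pairs tested in the γ stage, for δ all pairs entering
the δ stage. A pair is significant when the adjusted p < α and the CI
excludes 1 (either side). An AE is finally retained when at least one drug
passes both screens.

## Demographic stratification

The same three stages run independently per cohort: overall, female, male,
young, adult, elderly by default. Elderly is age > 65 (integer ages, so
min = 66); the young/adult boundary is not fixed by the study convention,
so the package default (young < 20, adult 20–65) is a repository choice
recorded in the run metadata and configurable. Summary tools follow the
conventions of the field: female proportions are computed among sex-known
reports with a seeded bootstrap SD (resampling reports with replacement,
B = 1000 by default); the gender gap is `#female − #male` (negative =
less frequent in women), optionally normalized by same-sex cohort totals
per million; per-million rates divide enriched-AE counts by cohort report
counts — a proxy for population size, since patient-level denominators do
not exist in spontaneous-report data; SOC rollups send unmapped terms to an
"unclassified" bucket. Network export emits one edge per attributed pair
with γ/δ statistics and a confounder flag when the AE appears as the drug's
indication in a user-supplied table.

AE and drug identifiers are opaque strings throughout: MedDRA and ATC are
license-restricted vocabularies, so normalisation is delegated to
user-supplied two-column mapping files and unmapped terms are kept verbatim
and reported.

## The synthetic generator

`generate_reports()` emulates the structural features the pipeline depends
on: per-report drug and AE sets, demographics with heavy missingness,
reporter qualification, severity flags, window-restricted dates, duplicate
case submissions, and three ground-truth mechanisms — per-AE linear yearly
trends, a multiplicative 2020 pandemic effect, and drug–AE couplings
expressed as odds multipliers on P(AE | drug), optionally with an extra
pandemic-interaction multiplier. Draws are independent Bernoulli per drug
and per AE except where a planted association couples them; this is the
simplest structure that makes γ and δ identifiable. With all effects at 1
and no associations, the data satisfy the null of every downstream test.

Defaults are chosen to mirror a FAERS-like stream: 20,000 reports/year;
60 catalog AEs with baselines 0.005–0.095 (about three AEs per report, so
genuinely event-free reports — which receive a filler id — are rare at
~5%; a large filler share would otherwise absorb complementary signal and
surface as a spurious "purified" event whenever real effects are planted);
sex 55.8% female / 34.2% male / 10% unknown (a 62/38 split among known);
age missing 15%, weight missing 40%; qualification shares 16.0 / 7.6 /
14.8 / 3.1 / 55.1 / 3.4% across physicians, pharmacists, other
professionals, lawyers, consumers, unknown; plausible severity-flag rates
(hospitalization 30%, death 5%). Dates are uniform inside each year's
window (out-of-window dates and duplicate fractions are configurable and
default to 0). What it does **not** emulate: reporting-delay dynamics,
indication/therapy fields, country mixtures, term misspellings, and the
long-tailed real AE vocabulary — so passing tests demonstrate correctness
of the statistical machinery under the generative assumptions, not
robustness to real-world coding noise.

## Problem sizes used in validation

The test-suite simulations are sized for a desk-scale machine: Type-I
control uses 200 null replicates at 2,000 reports/year; planted-signal
recovery uses one stream at 20,000 reports/year with five (drug, AE)
signals (3× pandemic effect, odds-4 association); oracle equivalence checks
the Fisher implementation against exhaustive enumeration on every 2×2 table
with both row margins ≤ 30. These sizes give the screening stages hundreds
of expected pandemic-window reports per planted AE, which is the regime the
method is designed for; much smaller streams leave Stage 3 underpowered
(the δ test in particular), and results there should be read as
conservative.

## Known limitations

* PAEAI's positive bias under the null (above): Stage 2 filters but does
  not control error rates.
* The Wald CI and the Fisher p can disagree near the boundary (discrete vs
  asymptotic); classification requires both, which is conservative.
* Matched-set γ depends on the candidate-pool quality; with
  `short_match = TRUE` the 1:10 contract is broken and γ should be read
  with caution.
* Unknown-country or multi-country reports are excluded whenever a country
  filter is set; this is a package choice, not a study-derived rule.
* The per-million normalisation treats report counts as a population proxy;
  true exposure denominators do not exist in spontaneous-report data.
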