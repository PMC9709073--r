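---
title: "Disproportionality signal detection on spontaneous-report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous-report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-report databases such as FAERS collect voluntary reports of
suspected adverse drug events. They have no denominator — nobody knows how
many patients took a drug without an event — so safety signals are sought
through *disproportionality*: is an event reported for the drug of interest
more often, relative to all its reports, than for every other drug? The unit
of analysis is the 2×2 table of deduplicated reports,

|                    | event reported | event not reported |
|--------------------|---------------:|-------------------:|
| target drug (PS)   | a              | b                  |
| all other drugs    | c              | d                  |

with `N = a + b + c + d`. `faersignal` implements the full path from the
raw quarterly ASCII tables to flagged signals: parsing, case-version
deduplication, primary-suspect cohort construction, contingency tables at
the MedDRA preferred-term (PT) and system-organ-class (SOC) levels, four
estimators with significance criteria, label-based expectedness
classification, a consumer-report sensitivity variant, and time-to-onset
summaries.

## Ingestion and deduplication

Quarterly FAERS files re-publish earlier versions of the same case, so
statistics on raw rows double-count. `deduplicate()` keeps, per `caseid`,
the row with the latest FDA receipt date, breaking ties by the larger
numeric `primaryid` (FDA version numbers increase). The rule is
deterministic and idempotent; since the public archive does not document a
canonical tie-break, this one is a package choice and is stated here rather
than inferred from any source.

Dates in FAERS arrive at full, year-month, or year precision.
`parse_date()` keeps partial dates (they still support receipt-year
tabulation) but only calendar-valid 8-digit dates get day-resolution
arithmetic; month 13 or day 32 is treated as absent rather than guessed.

## Cohort definition

A report belongs to the target cohort when at least one of its drug rows
has role code PS (primary suspect) *and* its normalized drug name or
active-ingredient string contains a target name (generic or trade) as a
word-boundary substring — so salt forms like `NIRAPARIB TOSYLATE
MONOHYDRATE` match, while accidental superstrings do not. All other
deduplicated reports form the background. Concomitant or
secondary-suspect mentions of the target never create cohort membership.

The sensitivity variant `exclude_consumers()` removes reports with
reporter-occupation code CN from target and background alike, since
consumer-heavy corpora (three quarters of an oncology cohort can be
consumer-reported) may dilute or distort professional reporting patterns.

## The four estimators

All four compare observed joint reporting with its expectation under
independence, `E = (a+b)(a+c)/N`:

* **ROR** `= ad/bc`, with the log-scale Wald interval
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`. Signal: `a ≥ 3` and lower
  bound `> 1` (strict).
* **PRR** `= [a/(a+b)]/[c/(c+d)]`, with the Pearson chi-squared of the
  table (no continuity correction). Signal: `a ≥ 3`, `PRR ≥ 2`,
  `χ² ≥ 4`. On reconstructed published tables the uncorrected statistic
  tracks the printed chi-squared; the Yates correction moves away from it.
* **IC** `= log2(a/E)` (BCPNN information component). The default lower
  bound is the delta-method one,
  `IC − 1.96·√(1/a − 1/(a+b) − 1/(a+c) + 1/N)/ln 2`, which for a rare term
  approaches `IC − 1.96·√(1/a)/ln 2` and reproduces the interval widths of
  published niraparib tables to two decimals. A closed-form Bayesian
  variant (`variant = "gamma"`, Gamma(a+½, E+½) posterior) is available
  behind the same interface. Signal: `IC025 > 0`.
* **EBGM** (MGPS family). `mode = "simplified"` is the raw relative
  reporting ratio `a/E` (identically `2^IC`) with a one-sided lower bound
  `exp(ln EBGM − z·√(1/a+1/b+1/c+1/d))`; `z = 1.645` is the default
  (one-sided 95%), `z = 1.96` matches some published tables and is
  configurable. `mode = "shrinkage"` is the DuMouchel gamma-Poisson
  shrinker: a two-component gamma mixture prior on the relative reporting
  rate, fitted by maximum likelihood on the marginal negative-binomial
  counts across the whole table collection, with `EBGM = exp E[ln λ | a]`
  and `EBGM05` the posterior 5th percentile. Shrinkage needs the
  collection to identify its five hyperparameters; the fit refuses below
  50 tables. Signal: `EBGM05 > 2`.

The minimum-count rule `a ≥ 3` applies to ROR and PRR only; IC and EBGM
carry their own shrinkage/width penalties for small counts. "All-four"
signals are the conjunction. Expectedness is case-insensitive exact-term
matching of the PT against a user-supplied label list: PTs are controlled
vocabulary, so substring matching would create false "expected" labels.

Tables with a zero cell return `NA` (an undefined-signal marker) by
default; the Haldane–Anscombe +0.5 correction is available but off, since
the `a ≥ 3` rule dominates at PT level. No multiple-testing correction is
applied: the classical criteria are used as published, and the suite's
null-calibration test measures their actual false-flag rate instead.

## The reconstruction oracle

Published disproportionality tables print `(a, n, ROR, CI)` per term but
not the comparator cells. Those two unknowns satisfy two printed
relations — the Wald half-width and the odds ratio — giving the closed
form used by `reconstruct_comparator()`:

```
r = (ln(hi/lo) / (2·1.96))² − 1/a − 1/b      # = 1/c + 1/d
d = (1 + b·ROR/a) / r,   c = a·d / (b·ROR)
```

Forward-computing PRR on the recovered cells reproduces the published PRR
column to two decimals for every row checked — a joint validation of the
ROR, CI and PRR formulas *and* of the counting convention: reconstruction
is numerically consistent with `a+b` equal to the deduplicated report
count (11,701 in the published niraparib table) and inconsistent with the
event-row count, which is why `build_tables()` counts reports, not event
rows. Because the printed inputs are rounded to two decimals, recovered
cells are positive reals; when the rounded interval is narrower than the
`1/a + 1/b` floor (it happens for very large `a`), the system is
infeasible and the function says so explicitly rather than returning a
spurious table. Published IC/EBGM columns are not always internally
consistent at two decimals (some rows print an IC that disagrees with the
log2 of their own EBGM), so forward IC is only held to ±0.03 bits on
coherent rows and EBGM to 2% — they are invariants, not calibration
targets.

## Time to onset

Onset is `event_dt − min(start_dt)` over the THER rows linked to the
matched PS drug sequence, using the earliest *full-precision* start (first
exposure). Partial or missing dates and event-before-start input errors
are excluded, each report tallied under exactly one reason. Summaries use
linear-interpolation quartiles (R type 7 — the convention must be fixed
for reproducibility and is not dictated by any source) and 30-day bins
right-closed at each multiple of 30 (`0–30`, `31–60`, …, `>360`), matching
the "first month / second month / … / after one year" reading.

## The synthetic corpus generator

`simulate_corpus()` emits the six FAERS tables with known ground truth.
Its model is deliberately the implicit null of 2×2 disproportionality:

* each drug enters a report independently with its marginal probability;
  the target takes role PS when present;
* each PT is an independent Bernoulli with probability
  `base_rate(PT) × RR(PS drug, PT)`, capped at 1; a report drawing no PT
  gets one backfilled (spontaneous reports always carry at least one
  event). Default base rates sum to ≈3.1 — about three events per report,
  of the order seen in real oncology corpora — so empty draws are rare
  (≈4%) and the backfill leaves marginals within Monte-Carlo error of the
  configured rates;
* demographics default to the published oncology mix: 78.5% female, 77.4%
  consumer-reported, 87% US, most ages missing or over 50;
* onset is exponential with median 18 days, observed at full precision
  for 37% of reports; 1% of dated reports are injected event-before-start
  errors;
* a configurable fraction of cases (default 5%) is also emitted as a
  stale earlier version with a distinct `primaryid`, exercising
  deduplication end to end;
* one seeded RNG stream drives every draw, so a config is byte-reproducible.

What the generator does **not** emulate: PT–PT correlation (real
haematology terms co-report), drug-name misspellings, free-text
narratives, reporting trends over time, or the heavy-tailed events-per-
report distribution of real FAERS. Passing tests therefore demonstrate
correctness of the counting and estimation machinery under the
independence model, not robustness to real-world coding noise.

## Problem sizes and numerical choices

The test suite runs the estimator oracle on 1,000 random tables, null
calibration on a 100,000-report corpus, and RR = 10 recovery on 100
seeded 4,000-report replicates — sizes at which binomial error puts the
planted signal's weakest criterion (`EBGM05 > 2`) comfortably past its
threshold while a desk machine finishes in seconds. The GPS prior fit
uses Nelder–Mead on log/logit-transformed hyperparameters from the
classical starting point (α₁=0.2, β₁=0.1, α₂=2, β₂=4, w=⅓); the EBGM05
quantile is solved by bisection on the posterior mixture CDF. Statistics
in report CSVs are rounded to two decimals (publication convention);
full-precision companions are written alongside because two-decimal
output is not reproducible input.

## Limitations

Disproportionality measures reporting, not risk: no causality, no
incidence, and confounding by indication is untouched (a cancer drug
"signals" disease progression). The package deliberately stops at ranked,
flagged tables. MedDRA itself is licensed and not shipped; PT→SOC mapping
is user-supplied, with a small demo mapping bundled for the synthetic
vocabulary only. Legacy (pre-2012) AERS layouts and the XML dialect are
out of scope.
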