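---
title: "Disproportionality signal detection for spontaneous adverse-event reports"
author: "faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
voluntarily submitted suspicions that a drug caused an adverse event. They
have no denominator (no count of exposed, event-free patients), substantial
duplication (the same clinical case resubmitted as amended versions), and
heavy missingness in demographics and dates. Pharmacovigilance practice
nevertheless extracts *signals* from them by disproportionality analysis:
for a drug cohort and one event term, the fourfold table

|               | event | no event |
|---------------|-------|----------|
| target drug   | a     | b        |
| other drugs   | c     | d        |

compares how often the event is *reported* under the target drug against
the background of all other reports. `faersignal` implements the full desk
pipeline around that idea for bevacizumab-in-glioma-style analyses:
ingestion of the seven-table quarterly ASCII dialect, case deduplication,
primary-suspect + indication cohort extraction, PT- and SOC-level tables,
three estimators with multi-method classification, FDR control, stratified
subgroup analysis with heterogeneity testing, time-to-onset binning, and a
synthetic report generator with known ground truth.

## Estimators

Three classical statistics are computed per table by `disprop()`:

* **Reporting odds ratio.** ROR $= ad/bc$ with a Wald interval on the log
  scale, $\mathrm{SE}(\ln \mathrm{ROR}) = \sqrt{1/a + 1/b + 1/c + 1/d}$.
  Signal criterion: CI lower bound $> 1$.
* **Proportional reporting ratio.** PRR
  $= \frac{a/(a+b)}{c/(c+d)}$ with the uncorrected 1-df chi-square
  $\chi^2 = \frac{(ad-bc)^2 N}{(a+b)(c+d)(a+c)(b+d)}$, $N = a+b+c+d$.
  Signal criterion: PRR $\ge 2$ and $\chi^2 \ge 4$ (inclusive; a strict
  variant is configurable). No Yates correction is applied — the continuity
  correction would systematically deflate the statistic relative to the
  standard Evans thresholds.
* **Bayesian confidence propagation (BCPNN).** The information component
  IC $= \log_2 \frac{a/(a+b)}{(a+c)/N}$ measures the observed-to-expected
  reporting ratio in bits. Signal criterion: the lower credibility bound
  IC025 $> 0$.

A term positive under all three is a **core signal**. Terms with fewer than
`min_count` (default 3) cohort reports of the event are never flagged, and
zero-cell tables are not evaluable unless the Haldane–Anscombe +0.5
correction is explicitly enabled (off by default: it perturbs all other
estimates and is unnecessary when the tabulated terms all have non-zero
cells).

### The IC025 variance: two modes

Methods tables in the applied literature often print the shorthand
$\mathrm{IC025} = \mathrm{IC} - 1.96\sqrt{1/(a+b) + 1/(c+d)}$, yet the
values actually published alongside it are usually produced by the classic
Bayesian-propagation posterior. The two disagree materially (for a strong
signal with $a = 234$ the shorthand gives $\approx 1.41$ where the
posterior gives $1.20$). `bcpnn_priors()` therefore exposes both:

* `bate1998` (default): the three-term posterior variance of the classic
  formulation with Dirichlet/Beta priors
  $\alpha_1 = \alpha_2 = \beta_1 = \beta_2 = \gamma_{11} = 1$ (so the
  marginal priors are $\alpha = \beta = 2$ and the joint cell prior
  $\gamma$ is tied to the margins), with
  $\mathrm{IC025} = \mathrm{IC} - 2\,\mathrm{SD}$. This reproduces the
  bundled published reference values for all 30 terms to two decimals.
* `table3`: the shorthand formula verbatim, for formula-faithful output.

The IC point estimate is the maximum-likelihood value in both modes.

### Multiplicity

The chi-square p-values of all terms of one analysis run (the overall
analysis, or one stratum) form one Benjamini–Hochberg family
(`bh_adjust()`, a validating wrapper over the standard step-up procedure).
The chi-square p-value is the natural common currency across terms; the
per-method flag thresholds are left untouched by the adjustment, and the
q-value is exported alongside so users can filter core signals at
`q < 0.05` as the stratified analyses do.

## Deduplication and cohort extraction

FAERS distributes amended case versions. `faers_dedup()` keeps, per
CASEID, the version with the latest FDA receipt date, breaking ties by the
highest PRIMARYID; records with unparseable FDA_DT are quarantined with a
reason rather than silently dropped. The rule is deterministic, order
invariant and idempotent. Across quarters, a PRIMARYID republished in a
later quarter replaces the earlier record before deduplication
(`combine_quarters()`).

The counting unit throughout is the deduplicated *report*, not the
patient: the cohort margin $a+b$ is the report count, which is what the
published reference tables fix term to term. The comparator universe is,
by default, **indication-restricted**: other-suspect-drug reports sharing
the target indication. This matches the reference set's total
$N = 66{,}528$, which is far below a full-database background, and is the
epidemiologically cleaner contrast (it controls for the indication);
`background = "full"` is available. A report enters the cohort when at
least one drug entry simultaneously matches the standardized target name,
the primary-suspect role, and the indication set attached to that same
drug entry.

Drug names are standardized by exact match on trimmed, upper-cased
synonyms; there is no fuzzy matching, because licensed drug dictionaries
are out of scope and silent fuzzy merges are a known source of cohort
contamination. The glioma indication list shipped as
`default_glioma_indication_pts()` is a placeholder (the licensed MedDRA
list has 28 diagnostic categories) and is user-overridable everywhere.

### Categorization rules

Ages are converted to years (`YR`, `DEC` = 10 y, `MON`, `WK`, `DY`) and
binned `<18, 18–44, 45–64, ≥65`; values below 0 or above 120 years are
outliers stored as missing. Weights above 400 kg are likewise outliers;
the weight boundary assigns 80 kg to the `≥80` group, resolving the
open interval in the printed group labels in favour of the label actually
used in the published cohort table. Reporter codes `MD/PH/RN/OT` group to
healthcare professionals and `CN/LW/SALES` to consumer-related reporters.
Every variable is total: anything missing or unrecognized is `NS`, so
categorization never drops a report. Partial dates (`YYYYMM`, `YYYY`)
count for reporting-year tabulation but are missing for day-resolution
arithmetic.

## Stratified analysis and heterogeneity

`stratify_and_detect()` re-runs the fit inside sex, age-group,
reporter-group or weight-group strata, always against the same-stratum
comparator (sex-matched comparators for sex strata, and so on — the
natural choice given that the heterogeneity test conditions on stratum).
The published exclusion rule for unstable subgroups — fewer than 30
reports — is applied at the term level by default (`a < 30` within the
stratum excludes the term from signal listing, inclusively retaining 30),
or optionally to whole strata. The `NS` stratum is tabulated descriptively
and never enters signal listing or heterogeneity testing.

A "p-interaction" is not produced by the Cochran–Mantel–Haenszel test
itself, which tests the *common* odds ratio against 1. The package
therefore reports both: the MH common OR with its CMH p-value
(`stats::mantelhaen.test`), and the Breslow–Day statistic with Tarone's
correction on $K-1$ degrees of freedom as the homogeneity p-value
(`breslow_day_test()`, implemented in the package since base R has no
Breslow–Day). Heterogeneity is declared at $p < 0.05$. Pooling stratum
tables reproduces the overall cells exactly, and the MH common OR always
lies between the extreme stratum ORs — both are enforced by tests.

## Time to onset

Onset is the calendar-day difference between the event date and the
earliest therapy start date of the target drug entries in the report.
Bins follow the published display: 0–30, 31–60, 61–90, 91–180, 181–360,
≥360 days. The two last printed labels overlap at 360; the package
resolves day 360 into 181–360 and starts the open bin at 361, keeping the
printed label. Negative intervals — data-entry artifacts — are excluded
from the distribution (not clamped to zero) and counted separately.

## The synthetic generator

`synthetic_faers()` emits a complete seven-table quarter with known ground
truth, so every pipeline stage is testable without any download. Its
defaults are fixed to the study conditions the pipeline is meant for:
missing sex 19.6%, age 33.7%, weight 50.3%, onset dates 73.2%, reporter
1.8%; the known-stratum mixes follow the published cohort composition
(F/M 0.403/0.597; age `<18/18–44/45–64/≥65` = 0.047/0.206/0.560/0.187);
onset intervals are log-normal with meanlog 3.75 and sdlog 1.30 (mean
about 97 days, heavily right-skewed); the default injected odds ratios sit
at the published signal strengths for the vascular/renal terms. Where the
study does not pin a value (duplicate rate 10%, country mix, comparator
drugs), a realistic choice was fixed once.

Two design points matter for validity:

* **Signals are injected on the per-report odds scale**
  ($p' = \mathrm{OR}\cdot o/(1+\mathrm{OR}\cdot o)$ with $o = p/(1-p)$),
  so the injected value *is* the reporting odds ratio the pipeline
  estimates — parameter-recovery tests have an exact estimand. Stratum
  effect modifiers multiply the same odds.
* **One seeded stream, sub-streamed per generation phase**, so adding a
  field to one table cannot reshuffle draws elsewhere; a fixed seed gives
  byte-identical output.

Reports that draw no catalog event receive a neutral filler reaction term
outside the analysis catalog, keeping the FAERS invariant that every
report has at least one reaction row without perturbing any analyzed
term's estimand. Duplicate case versions share the CASEID with a lower
PRIMARYID and an earlier (or, for a third of duplicates, tied) receipt
date, exercising both halves of the deduplication rule.

What the generator does *not* emulate: drug co-reporting networks,
narrative text, country-level reporting dynamics, secular trends in
reporting rates, and within-report correlation between event terms
(events are conditionally independent given cohort and stratum). Passing
tests therefore demonstrate that the statistical machinery is correct
under the stated sampling model — not that real FAERS extracts meet that
model.

## Numerical choices

* Cells are coerced to double before the chi-square (the cross-product
  overflows 32-bit integers at realistic sizes).
* Published-table comparisons round half away from zero to 2 decimals
  (`round_half_up()`), matching how such tables are printed; IC and IC025
  carry a ±0.01 tolerance for the rounding cascade of intermediate
  quantities.
* Breslow–Day expected cells solve the standard quadratic at the MH common
  OR, with the root selected inside the admissible hypergeometric range;
  the Tarone term is clipped at zero.
* Dedup ties are broken on the numeric value of PRIMARYID (with a
  lexicographic fallback for non-numeric identifiers).

## Validation design and problem sizes

The test suite validates against three independent anchors, at sizes
chosen to keep the default run a few minutes on one CPU:

* the bundled published reference set (30 terms): every statistic
  re-derived from raw cells to 2 decimals;
* brute-force oracles: contingency, stratified, onset and Venn tallies on
  a seeded 40,000-report universe recounted from raw (report, term) pairs;
* calibration: 95% CI coverage of an injected OR of 5.0 over 100
  replicate 50,000/50,000-report universes; realized Benjamini–Hochberg
  FDR over 300 simulated 100-term universes with 5% true signals;
  Breslow–Day–Tarone type-I error over 500 two-stratum replicates under a
  common OR of 2.

The FDR calibration universes use baseline reporting probabilities of
0.005–0.03 at margins of 20,000/60,000 so that every null term has dense
cells: the 1-df chi-square tail is accurate there, and the realized FDR
lands at the theoretical $\frac{m_0}{m}\alpha = 0.0475$. With very sparse
cells (expected counts of a few dozen) the asymptotic tail is slightly
liberal exactly at BH's adaptive threshold and the realized FDR drifts to
the nominal boundary — a property of the chi-square approximation, not of
the step-up procedure, and the reason sparse designs should prefer the
BCPNN bound.

## Known limitations

* No fuzzy drug-name matching and no bundled MedDRA: mappings are exact
  and user-supplied.
* Disproportionality measures reporting associations, not incidence or
  causation; the package deliberately offers no absolute-risk output.
* The sensitivity re-analysis (`sensitivity_refit()`) takes a
  user-supplied indication subset to exclude; no default subset ships
  because "atypical" indication definitions are analysis-specific.
* HLT/HLGT/LLT tabulation levels, EBGM/MGPS and sequence-symmetry
  analysis are out of scope.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_target_reports = 2000, n_comparator_reports = 8000,
                        seed = 42)
tabs <- synthetic_faers(cfg)
kept <- faers_dedup(tabs)$kept
cases <- build_case_reports(tabs, kept = kept)
cohorts <- build_cohort(cases, "BEVACIZUMAB")
fit <- disprop(contingency_tables(cohorts$cohort, cohorts$comparator))
summary(fit)
stratify_and_detect(cohorts$cohort, cohorts$comparator, "sex")
onset_distribution(cohorts$cohort)
```
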