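---
title: "Methods: incidence and disproportionality analysis of spontaneous vaccine adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incidence and disproportionality analysis of spontaneous vaccine adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otosignal)
```

## The data and the counting unit

Passive vaccine-safety surveillance collects spontaneous reports: anyone —
patients, clinicians, manufacturers — can file one, each carrying
demographics, the vaccines received, and symptoms coded as MedDRA
preferred terms (PTs). The public export splits this into three delimited
files keyed by a report id (demographics; vaccine records; symptom rows,
several per report). `read_vaers_reports()` merges them into one row per
report with a deduplicated PT set.

The counting unit throughout is the **report**, not the person. The
source data cannot link multiple reports from one person, so neither do
we; a person who files twice is counted twice. This matches the
granularity of the data and is the standard convention for spontaneous
reporting systems.

Dose-series assignment follows the collection design of the source:
vaccine type `COVID19` marks a report against the completed-primary-series
population (CPS), `COVID19-2` against the updated-bivalent-booster
population (UBB). A report carrying both is assigned UBB — the booster
record supersedes — and a report mixing the index vaccine with an
unrelated vaccine is kept as an index report, since the adverse event was
reported in connection with the index exposure.

## Preferred-term grouping

Clinically related PTs (e.g. `Tinnitus`, `Tinnitus aggravated`) are pooled
into named adverse-event groups via an editable YAML mapping; the shipped
default declares 19 otolaryngologic groups, each seeded with the PTs its
label names plus close lexical variants. Users studying a specific corpus
should replace the seed lists with their fully curated PT inventory — the
mapping format, not the seed list, is the contract.

Two counting rules are deliberate:

* **Per-report, per-group deduplication.** A report with three
  tinnitus-family PTs adds 1, not 3, to the tinnitus group. Counting PT
  occurrences would inflate groups rich in synonyms.
* **Multi-group contribution.** A report contributes to *every* group it
  maps to. Group shares are computed against the count of reports with at
  least one mapped group (the `ANY` pseudo-group), so shares need not sum
  to 100% across groups; in practice multi-group reports are rare enough
  that they nearly do.

A duplicate PT across two groups is a configuration error (each PT has
exactly one home); PTs absent from the mapping are dropped by default, or
fatal under the `ERROR` policy for strict curation runs.

## Incidence rates

For each (group × stratum) cell,

$$\mathrm{IR} = \frac{\text{reports}}{\text{vaccinated persons}} \times 10^5,$$

a crude cumulative rate per 100,000 vaccinated persons — no person-time,
no age standardization, because the published denominators are simple
population counts by dose series and stratum. Denominators come from an
external table keyed by (series, axis, level). Two quirks of the published
denominators are encoded deliberately:

* Manufacturer-level populations are published only for the
  at-least-one-dose (ALOD) series, so manufacturer-stratified tables pair
  series-scoped counts with ALOD denominators — the conventional
  substitution when primary-series breakdowns are unavailable.
* The bivalent booster was never authorized for the viral-vector
  manufacturer, so UBB manufacturer tables cover the two mRNA brands only;
  the package restricts manufacturer levels to those present in the
  denominator table.
* Axis levels and series totals are published independently and need not
  sum exactly; a level sum exceeding the total is tolerated with a
  warning rather than rejected.

Age bands are fixed at 0–17, 18–49, 50–64, 65+, half-open on integer
years ([0,18), [18,50), [50,65), [65,∞)). Reports with an unknown value on
a stratification axis are excluded from that axis's level rows but remain
in totals, so level sums equal totals exactly only when missingness is
zero — the generator's default, which is what the sum-invariant tests
exercise.

All computation is at full double precision; display rounding (rates to 3
decimals, shares to 2, the IEEE round-half-even of R's `round()`) happens
only in `write_result_table()`, and p-values below 0.001 print as
`<0.001`.

## Association tests

Differences in event proportions across strata are tested on r × 2
event/non-event tables built from event counts and stratum population
sizes. The selection rule is the conventional small-expected-cell
criterion: Fisher's exact test when the table is 2 × 2 and any expected
cell is below 5, Pearson's chi-squared (no continuity correction,
two-tailed) otherwise; larger tables with sparse cells keep chi-squared
with a warning. Degenerate tables (no events anywhere) yield `NA` rather
than an error so sparse groups print blank. The two-sided Fisher p-value
follows the probability-ordering convention — the sum of hypergeometric
probabilities of all tables with the observed margins no more probable
than the observed one — enumerated directly over the support, with a
`1 + 10⁻⁷` relative slack on the comparison to absorb floating-point ties.
Population denominators are ~10⁸, far beyond 32-bit integer range, so all
table arithmetic is done in doubles (exact for integers to 2⁵³).

No multiplicity correction is applied across the ~19 × 3 tests; this
mirrors common practice for descriptive surveillance tables and is a
known limitation, not an oversight.

## Proportional reporting ratio

For a group with $m$ index-vaccine reports among $n$ total index-vaccine
reports, and $M$ reports of the group among $N$ reports database-wide,

$$\mathrm{PRR} = \frac{m/n}{(M-m)/(N-n)},$$

the index reporting proportion over the background proportion. $N$ and
$M$ span the whole database (index + background), so the background uses
$M-m$ and $N-n$. The totals $n$ and $N$ count **all** adverse-event
reports, not only those mapping to a study group: the denominator of a
reporting proportion is the corpus, and under the generator this makes
the estimand exactly the ratio of per-report group probabilities.

The interval is the standard log-normal (delta-method) one,

$$\exp\!\left(\ln \mathrm{PRR} \pm z_{1-\alpha/2}
  \sqrt{\tfrac1m - \tfrac1n + \tfrac1{M-m} - \tfrac1{N-n}}\right),$$

chosen because it is the field-standard interval for this statistic and
consistent with published interval widths for counts of this order. A
group with $m = 0$ reports a PRR of 0 with an undefined interval; a
zero background cell is an error unless the optional add-0.5 continuity
correction is enabled. The signal rule is the bare threshold
$\mathrm{PRR} \ge 2$ (configurable); the classical auxiliary criteria
($m \ge 3$ and χ² ≥ 4) are available behind `classical_criteria = TRUE`
but off by default, matching how the bare threshold is commonly applied
to vaccine AEFI screens. As the worked example in the README shows, the
bare rule is noisy at single-digit $m$ — that is a property of the rule,
faithfully reproduced.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the observed structure of the real
otolaryngologic corpus: per-group reporting probabilities proportional to
the published group shares (dizziness/vertigo dominating at two-thirds of
reports), a 30/70 male/female mix, an age mix concentrated in 50+, a
51/40/9 manufacturer split, a 96/4 primary-series/booster split, the
published CDC denominator populations, and background probabilities set
so the implied index/background ratios reproduce the published
disproportionality profile (tinnitus ≈ 2.3, anosmia ≈ 3.2, acid
reflux ≈ 2.6 elevated; ear infections, rhinitis, allergies deflated).
Groups are drawn independently per report — no co-occurrence structure,
because none is published. Missingness defaults to 0 so count invariants
hold exactly; tests of UNKNOWN handling set it explicitly. Each included
group emits 1–`pt_per_group` synonym PTs to exercise deduplication, and
unmapped reports get a filler PT so they still look like adverse-event
reports (and count toward $n$).

Passing tests on these corpora therefore demonstrates statistical
correctness of the machinery — not robustness to the pathologies of real
spontaneous data: reporting waves driven by media attention, duplicate
filings, free-text-only symptoms, or time-varying denominators. None of
those are modelled, and the stimulated-reporting dynamics of a mass
vaccination campaign are explicitly out of scope.

## Validation problem sizes

The test suite validates: exact reproduction of every published
incidence-rate and share cell retyped in the replay fixture; PRR point
estimates against hand arithmetic and against brute-force recounts on raw
report lists; recovery of planted reporting-rate ratios of 2 (ten corpora
of 50,000 index + 100,000 background reports, mean within three Monte
Carlo standard errors) and 3 (ten corpora of 20,000 + 40,000, each
flagged); 93.7–94.8% empirical coverage of the nominal 95% interval over
1,000 replicates at expected $m \approx 60$; a null false-signal rate of
0/100 group-screens at expected counts ≥ 100; chi-squared type-I
calibration within 5% ± 1.5% over 1,000 null tables; and agreement of the
Fisher p-value with an independent `choose()`-based enumeration over all
635,375 distinct 2 × 2 tables with $N \le 60$ (maximum deviation at
floating-point noise, ~10⁻¹⁵). These sizes were chosen to bound Monte
Carlo error well below the tolerances being asserted.

## Known limitations

* Crude rates only; no person-time, no standardization, no causality.
* The report-level counting unit overcounts persons who file repeatedly.
* The shipped PT seed lists are starting points, not a curated inventory.
* The bare PRR ≥ 2 rule has a high false-signal rate at small counts;
  use `classical_criteria = TRUE` or a minimum-count filter for
  screening work.
* One published booster-series cell is internally inconsistent in the
  source tables (its sum disagrees with its own sex split); the replay
  fixture stores it as printed and no conclusion rests on it.
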