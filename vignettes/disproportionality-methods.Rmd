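---
title: "Disproportionality methods for spontaneous-report signal detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods for spontaneous-report signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersdpa)
```

## The analysis

Spontaneous-report databases such as FAERS collect suspected adverse drug
events without denominators: there is no exposure population, only
reports. Disproportionality analysis works around this by asking whether a
particular drug–event pair is reported *more often than expected* given how
often the drug and the event are reported overall. For a target drug and a
target event (a MedDRA preferred term, PT, or its system organ class,
SOC), the corpus of event reports is collapsed into a 2×2 table:

|              | target event | other events | total   |
|--------------|--------------|--------------|---------|
| target drug  | a            | b            | a + b   |
| other drugs  | c            | d            | c + d   |
| total        | a + c        | b + d        | N       |

`faersdpa` implements the full path from raw FAERS-style quarterly files to
screened signal tables: parsing and linkage by `primaryid`, case
deduplication, drug-name normalisation, primary-suspect selection, PT→SOC
rollup, contingency construction, the four disproportionality statistics,
and descriptive summaries. A synthetic-report generator with known ground
truth makes every stage testable without the multi-gigabyte public
extracts.

## The four statistics

With `s = sqrt(1/a + 1/b + 1/c + 1/d)`:

* **ROR** (reporting odds ratio): `ROR = ad/(bc)`, with the Woolf interval
  `exp(log ROR ± 1.96 s)`. Screen: lower 95% bound > 1 and `a ≥ 3`.
* **PRR** (proportional reporting ratio):
  `PRR = [a/(a+b)] / [c/(c+d)]`, with the Pearson chi-square
  `χ² = (ad − bc)² N / [(a+b)(c+d)(a+c)(b+d)]` (no continuity
  correction). Screen: `PRR ≥ 2`, `χ² ≥ 4`, `a ≥ 3`.
* **IC** (BCPNN information component):
  `IC = log2[aN / ((a+c)(a+b))]`, the log2 observed-to-expected reporting
  ratio. Screen: `IC025 > 0`.
* **EBGM**: `EBGM = aN / ((a+c)(a+b))`. Screen: `EBGM05 > 2`.

Two structural facts follow directly from these definitions and are
asserted in the test suite: `IC = log2(EBGM)` exactly (the BCPNN and MGPS
point estimates here are log-equivalents), and scaling all four cells
leaves every point estimate unchanged while shrinking every interval.

The EBGM implemented here is the *unshrunk* relative reporting ratio, not
DuMouchel's gamma–Poisson mixture posterior. That is a deliberate scope
decision: the published avelumab signal tables this package cross-checks
against are numerically consistent with the unshrunk form (their EBGM
equals their PRR to two decimals throughout, and their IC equals
log2(EBGM)), so a shrinkage estimator would reproduce none of them. The
same applies to the IC: the full Bayesian BCPNN posterior with Dirichlet
priors shrinks small-count ICs towards zero by several tenths of a bit and
is demonstrably *not* what those tables contain.

## Interval conventions

Published signal tables rarely state their variance conventions, so they
were fixed here by a fitting exercise against a 30-row PT table and a
22-row SOC table from a published avelumab analysis, reconstructed cell by
cell (next section):

* **ROR and PRR intervals**: log-scale intervals with the shared
  `s` above. The delta-method PRR variance
  (`1/a − 1/(a+b) + 1/c − 1/(c+d)`) does not reproduce the published PRR
  bounds; the ROR-form `s` does, to within ~1% even for the largest
  ratios.
* **IC025**: `IC − 1.96·s_ic/ln 2` with
  `s_ic = sqrt(1/(a+1) + 1/b + 1/c + 1/d)`. The `1/(a+1)` term is what the
  published tables actually follow: it reproduces all 52 printed IC025
  values to ±0.019, while the plain `1/a` form drifts to −0.042 for PTs
  with a ≤ 13 reports. The plain form remains available via
  `ic_variance = "plain"`.
* **EBGM05**: the one-sided 5th percentile `EBGM·exp(−1.645 s)`. The
  two-sided multiplier 1.96 does not reproduce any of the printed EBGM05
  values; 1.645 reproduces all of them within printed precision.

## Reconstruction from printed tables

`reconstruct_from_printed()` inverts the PRR definition. Given the printed
report count `a` and PRR, the drug's total event margin, and the corpus
size N, the remaining cells are determined:

```{r}
m <- avelumab_margins()
t <- reconstruct_from_printed(a = 35, prr_printed = 4.95,
                              drug_margin = m$drug_margin,
                              n_total = m$n_total)
t
signal_scores(t)[, c("ror", "ror_lo95", "ror_hi95", "chi2", "ic", "ic025",
                     "ebgm", "ebgm05")]
```

The drug margin used for the avelumab cross-checks is 3,845 — the sum of
the 22 SOC report counts — rather than the 3,978 deduplicated cases: the
analysis counts *event rows* (one case × one distinct term), and 3,845 is
the only event-level margin derivable from the printed numbers. It also
reproduces the printed chi-square values, which the case count does not.

Agreement with the printed values is limited by their own rounding.
`c` is rounded to an integer (cells are counts); since the printed PRR
carries two decimals, the induced error in `c` is below 0.03% and the PRR
round-trips well within 0.5%. Point estimates printed near magnitude 50–90
at two decimals carry rounding noise above a flat 0.02, so the
reconstruction suite checks max(0.02 absolute, 0.2% relative). The
chi-square for near-null SOCs (PRR ≈ 1) is quadratically sensitive to the
printed PRR's rounding — `χ² ∝ (PRR−1)²` near independence — so SOC-level
chi-squares are checked at 10% relative while PT-level ones (all far from
independence) hold within 0.3%.

## Counting conventions

* **Deduplication**: one report per unique case ID, keeping the latest
  receipt date; ties go to the highest `primaryid`, since FAERS assigns
  later sequence numbers to later versions. The operation is idempotent
  and order-invariant.
* **Counting unit**: event rows (case × distinct term) for PT and SOC
  contingency tables; cases for demographic summaries. A PT repeated
  within one report counts once. At SOC level, a case contributes one row
  per distinct SOC after rollup.
* **Comparator**: all non-target-drug event rows in the corpus, with no
  indication matching or stratification.
* **Minimum-report filter**: PTs with fewer than 3 target-drug reports are
  excluded from the PT-level signal table (configurable).
* **Ages** convert to years via decade×10, month÷12, week÷52, day÷365.25;
  values above 122 years are treated as recording errors and set missing.
* **Partial dates** (`YYYYMM`, `YYYY`) floor to the period start so they
  still order correctly for deduplication, but are flagged imprecise and
  excluded from time-to-onset (they fall in the "unknown" band, as do
  negative onsets).
* **Routes** collapse to three categories: anything mentioning "drip" is
  an intravenous drip, other intravenous variants are intravenous,
  everything else (including missing) is other.
* **Percentages** in descriptive summaries use each factor's own
  denominator (factors differ in missingness and outcomes can repeat per
  case), rounded half-up to two decimals — the convention the published
  demographic tables follow, verified exactly against all 43 printed
  percentages.

## Degenerate inputs

A table with `a = 0` or an empty `b` or `c` cell has no finite log-scale
interval. The default reports such rows as *undefined* rather than
silently correcting them; `zero_cell = "haldane"` applies the classical
+0.5 to all cells for users who want estimates everywhere. Screening rules
treat undefined statistics as failed. `reconstruct_from_printed()` refuses
inputs whose implied comparator cell falls below one report.

## The synthetic generator

`generate_reports()` emits the five-table quarterly file set with known
ground truth. It emulates the features the pipeline must survive:
case-linked multi-table structure keyed by `primaryid`/`caseid`; duplicate
case versions (same case, later receipt date, a perturbed field);
configurable background PT distribution with planted relative risks for
the target drug's cases (weights multiplied by RR and renormalised);
demographic marginals matching the published avelumab report mix (63.6%
male, 70.4% physician reporters, 44.8% intravenous, and so on); 23%
missing age and 31% missing event dates; at least one reaction per report
(`1 + Poisson(mean − 1)`); brand-name spellings on a share of target
entries to exercise synonym normalisation. Identical configurations
produce byte-identical files.

It deliberately does **not** model reporting-delay dynamics, secular
trends, country-specific reporting cultures, drug–drug interaction
signals, or correlated PT co-occurrence (syndromes). Passing tests
therefore demonstrate that the statistics, filters, linkage and
deduplication behave correctly under controlled conditions — not that the
pipeline's operating characteristics transfer to the messiness of real
FAERS data.

Test problem sizes are chosen so the planted effects are measured where
the estimators are stable: null-calibration runs use 200 PTs with about 20
expected reports each across 20 seeds (the observed false-positive
fraction under the four-rule screen is essentially zero, against a 5%
bound), and planted-signal recovery uses corpora where the planted PT's
expected count is at least 30, where a fivefold relative risk lands in an
EBGM window of [3.5, 6.5]. The window is wide because the planted RR
renormalises the event distribution (diluting the realised ratio slightly
below RR) and the comparator includes sampling noise.

## Known limitations

* Shrinkage-based estimators (gamma–Poisson MGPS, full BCPNN posterior)
  are out of scope, as is multiple-comparison control across terms —
  screened tables are hypothesis-generating, not confirmatory.
* Drug-name normalisation is a synonym-table lookup, not a general
  normaliser; unmatched names pass through upper-cased and are reported.
* The shipped PT→SOC dictionary is a small synthetic stand-in assembled
  for the cross-check fixtures; real analyses should supply a licensed
  MedDRA extract as a two-column TSV.
* Record linkage beyond the case ID (probabilistic duplicate detection)
  is not attempted.
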