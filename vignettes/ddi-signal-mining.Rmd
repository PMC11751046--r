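---
title: "Two-detector DDI signal mining: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-detector DDI signal mining: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsddi)
```

## The problem and the model

Spontaneous ADR reporting systems are passive: each report names one or more
suspect drugs, one or more adverse events, demographics, and a reporter-assessed
causality grade. There is no denominator of exposed patients, so neither
incidence nor relative risk is estimable; what is estimable is
*disproportionality* — whether a drug pair and an AE co-occur in reports more
often than the single-drug and background reporting patterns predict.

`srsddi` screens candidate triples (drug1, drug2, AE) with two detectors and
flags only their intersection:

1. **Association rules.** With `T` reports in the analysis set,
   support = n111/T, confidence = support/support(pair),
   lift = confidence/support(AE), and
   conviction = (1 − support(AE))/(1 − confidence). A rule passes at
   lift > 1 and conviction > 1 (both strict) with n111 ≥ 3 (inclusive), and
   must then survive redundancy pruning (below).
2. **Ω shrinkage measure.** Ω = log₂((n111+0.5)/(E111+0.5)) with lower bound
   Ω₀.₀₂₅ = Ω − φ(0.975)/(ln 2·√n111), signalling when Ω₀.₀₂₅ > 0 (strict).
   φ(0.975) is frozen at 1.959964 for bit-reproducibility rather than
   recomputed per run.

Both detectors are computed from the *same* 4×2 contingency table per triple,
so they always agree on n111. The intersection is the package's conservatism
mechanism; no multiple-testing adjustment is applied (none is conventional in
this screening setting, and the Ω lower bound already penalizes small counts).

### Counting unit

Contingency cells partition *reports*: a report contributes to exactly one
exposure row (by which of the two focal drugs its drug set contains) and one
AE column (target AE present or not, by exact standardized-term equality — no
hierarchy roll-up, since no licensed terminology ships with the package).
Reports listing three or more drugs contribute to every one of their pairs'
"both" rows; no attribution apportioning is attempted, which matches standard
SRS practice. `T` in the support denominator is the report count of the
analysis set, consistent with the table's grand total. Drug–AE *combinations*
(one AE occurrence × one report) are used only in `descriptive_summary()`,
where frequency tables are conventionally reported on that scale. A
combination-level counting alternative for inference was considered and not
implemented; the report-level unit is the one the contingency table is
defined on.

### The E111 model

The expected both-drug target-AE count under "no interaction" is not uniquely
defined by the screening tradition; the package implements two models:

- `noren_excess` (default): with observed AE risks f101, f011, f001 in the
  only-drug1, only-drug2 and neither rows, solve
  1/(1−g111) = 1/(1−f101) + 1/(1−f011) − 1/(1−f001) and set
  E111 = n11+·g111. This is the excess-risk model used with the shrinkage
  measure in DDI surveillance: each drug's own risk elevation is absorbed
  into the expectation, so a *pair* must exceed the combined single-drug
  excesses to score. g111 is clamped into [0, 1]; a saturated single-drug
  risk (f = 1) yields E111 = n11+; any empty stratum margin falls back to the
  independence value.
- `independence`: E111 = n11+·(n++1/n+++), the overall marginal AE rate.

The excess-risk model is the more conservative for interaction detection
whenever single-drug risks exceed background (a tested property). Tests
validate the closed-form inversion against numerically solving the defining
equation with `uniroot`.

### Redundancy pruning

Published screens report signal counts "after removing redundant rules"
without defining redundancy. The package adopts the standard
confidence-improvement criterion: a pair rule (d1, d2) → AE is redundant if
either single-drug rule d → AE achieves confidence ≥ the pair rule's
confidence. Every removal is annotated with the dominating drug, so the
effect of the choice is auditable in the `rules` output. With restricted
source data there is no way to validate this definition against a published
signal count; it is a documented design choice, not a reproduction.

### Stratification

Five strata: overall, male, female, age < 60, age ≥ 60 (age 60 in the upper
group, matching the convention "aged 60 and above"). Unknown sex is excluded
from the sex strata only; missing age from the age strata only — both remain
in the overall analysis. Candidate sets and tables are recomputed within
each stratum rather than subset from the overall candidates: this is
self-consistent (a stratum-only signal can reach n111 ≥ 3 inside its stratum
while being diluted overall) and is the choice the heterogeneous-effect test
exercises.

## Filtering and standardization

`apply_filters()` applies year window → disease cohort → causality →
missingness, in that fixed order, attributing each exclusion to the first
criterion it violates; the log is therefore deterministic and sums with the
retained count to the input count. Causality grades follow the five-level
reporter scale {certain, probable, possible, unlikely, pending}; screening
conventionally keeps the first three. One grade per report row is assumed
(whether source systems ever attach per-drug grades is unknowable from
published material; the assumption is recorded here). The qualifying-disease
list for a cohort is user-supplied — deployments differ and no authoritative
list ships. Term standardization lowercases, trims and collapses internal
whitespace before dictionary lookup, robust to hand-entered names;
dictionaries are plain tables because licensed vocabularies (MedDRA, product
registries) cannot be distributed.

## The synthetic generator: what it emulates, what it does not

`generate_reports()` draws, per report: independent Bernoulli drug exposures
(with optional co-prescription odds boosts conditional on the first drug of
a boosted pair), then per-AE Bernoulli draws at baseline × single-drug
multipliers × λ (for an injected pair effect when both drugs are present),
capped at 1. Reports with no drug or no AE are redrawn, because a
spontaneous report by definition names a suspect drug and an event.

This zero-truncation has a visible statistical consequence: empirical
frequencies exceed the configured probabilities by ≈ 1/P(at least one).
`ground_truth()` therefore computes the *exact conditional* expected value of
every contingency cell of each injected triple from the config alone
(integrating over the focal pair's exposure rows), and all generator tests
compare against those closed forms, at a 3-standard-deviation tolerance. The
closed form is exact when boosts and risk effects involve only the focal
pair; configurations outside that regime are flagged `approximate`.

Default catalogs give a heavy-tailed drug mix (one dominant drug near 9%
pre-conditioning), rare serious AEs (baselines 0.002–0.005) under frequent
non-specific ones, a ~53/47 female/male split with a small unknown fraction,
a normal(65, 15) age model truncated to 18–100 (≈ 2/3 of reports at 60+),
and a causality mix dominated by "possible". These are fixed, field-plausible
choices — not fits to any particular database.

Not modeled: reporting biases (stimulated reporting, masking, duplicate
reports), drug–drug correlations beyond pairwise boosts, within-report AE
dependence, or secular trends. A green recovery test therefore establishes
that the pipeline detects multiplicative pair-specific risk elevation in an
idealized SRS; it says nothing about robustness to those biases.

## Numerical choices and degenerate inputs

- Degenerate rule denominators return sentinels, never exceptions: no pair
  exposure → `NA` confidence; AE absent from the set → `NA` lift (guarded;
  impossible for enumerated candidates); confidence = 1 → conviction `Inf`,
  which passes any finite threshold.
- Ω at n111 = 0 is defined (shrinkage gives Ω = 0 when E111 = 0 too) but the
  lower bound is not; `omega_lower_bound()` returns `NA` with a logged note,
  and such triples never signal.
- Threshold comparisons are exactly as conventional: strict for lift and
  conviction, inclusive for n111.
- Candidate ordering is fixed (n111 descending, then lexicographic) and all
  outputs carry deterministic sort orders, so identical inputs give
  byte-identical outputs.
- The generator uses a mandatory seed, restores the caller's RNG state, and
  replicate r of a recovery experiment uses seed base_seed + r, making every
  replicate individually reproducible.

## Known limitations

- Exact-term AE matching understates signals spread across synonymous or
  hierarchically related terms; a real deployment should standardize to a
  proper terminology first.
- The redundancy criterion and the E111 model are both field-standard but
  not uniquely determined by published screening descriptions; both are
  switchable/auditable rather than claimed as reproductions.
- Rule metrics are frequencies, not estimates with uncertainty; only the Ω
  detector carries an interval. The intersection criterion inherits the
  rule detector's lack of error control at very small n111 (mitigated by
  n111 ≥ 3 and the Ω bound).
- Signals are reporting associations, not causal or incidence statements.
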