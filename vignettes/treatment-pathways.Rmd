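---
title: "Mining PAD treatment pathways: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining PAD treatment pathways: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padflow)
```

## The model

`padflow` treats a patient's clinical history as a dated event log over a
fixed vocabulary: six treatment categories for peripheral artery disease
(antiplatelet, lipid-lowering, smoking cessation, exercise therapy,
endovascular revascularization, revascularization surgery) plus a
distinguished amputation outcome event. The analysis object is the
patient's *treatment pathway*: the ordered tuple of **distinct**
treatment categories, each taken at its first occurrence, truncated at
the first amputation. This is a deliberately coarse summary — it ignores
dose, duration, repetition and inter-event timing — in exchange for
pathways that are directly countable, comparable across cohorts, and
drawable as flows.

Three statistics sit on top of the extracted sequences:

* **cohort-normalized rates** — a pathway's patient count divided by the
  size of its outcome cohort, on a percent scale. Dividing by cohort
  size (rather than the pooled total) is what makes a 77-patient
  amputation cohort visually and numerically comparable to a
  5504-patient non-amputation cohort;
* **odds ratios** — per pathway, the 2×2 cross-tabulation of exact
  pathway membership against outcome, `OR = ad/bc`, and the implied
  amputation probability `p = OR/(1+OR)`. The conversion is the unique
  monotone map with `p(1) = 0.5` consistent with reading the odds ratio
  as the odds of amputation given the pathway;
* **Sankey flow graphs** — stage-indexed nodes (the same treatment at
  stage 1 and stage 2 is two nodes), outcome-colored links, each
  sequence contributing one unit of raw flow along its chain and into
  its terminal outcome node.

### Assumptions

* Event dates have day resolution, and a treatment dated *on* the first
  amputation date cannot be shown to precede it, so it is excluded
  ("strictly before"). Multiple amputation events may exist; only the
  first truncates.
* Non-amputation patients contribute their entire record: there is no
  censoring date for them, and introducing one would require an index
  date the data model does not carry.
* One patient yields at most one sequence, so "total number of
  sequences" in a cohort equals the number of included patients. All
  denominators in the package use this equality.
* Pathways are ordered tuples. The dominance and odds analyses both use
  *exact full-sequence* membership — a patient whose sequence is
  antiplatelet → lipid-lowering → surgery is **not** a member of the
  antiplatelet → lipid-lowering pathway. Containment or prefix semantics
  are defensible alternatives; exact matching was chosen because it
  keeps the pathway table a partition (counts per cohort sum to the
  cohort size) and keeps rates and odds ratios mutually consistent.
  Published per-pathway odds ratios computed under an unknown membership
  convention are therefore not reproduction targets of this package;
  the odds→probability conversion is.

## Determinism and numerical choices

* **Tie-breaks.** Same-date ties between different treatments are broken
  by the canonical category order (`treatment_codes()`). Extraction is
  therefore a pure function of the event *set* — shuffling input rows
  never changes a sequence.
* **Rounding.** Rates and probabilities round half away from zero (R's
  `round()` is half-to-even). A `1e-9` epsilon absorbs binary
  representation error in quantities like `100·k/n` before rounding;
  with percentage numerators below 10^6 this cannot flip a correctly
  computed value.
* **Zero cells.** Any zero cell in a 2×2 table triggers the
  Haldane–Anscombe correction (0.5 added to all four cells), and the
  result is flagged `corrected`. Pathways unique to one cohort are
  common at these sample sizes, so the flag matters for interpretation.
  An all-zero table is an error, not a number. No confidence intervals
  are computed by default; a Woolf (log-normal) interval is available
  via `conf_level`.
* **Node normalization direction.** A Sankey node's *outgoing* links are
  rescaled to sum to 1. Requiring incoming and outgoing normalized
  flows to both sum to 1 at every node simultaneously is not generally
  satisfiable; the package honors the balance claim exactly for
  outgoing flows and through raw-count flow conservation (in = out at
  every internal node) for incoming ones. Raw counts and
  cohort-normalized values are preserved on every link so no
  information is lost by the rescaling.
* **Degenerate inputs.** Empty event logs produce empty cohorts and an
  all-zero report; empty strata produce zero rows and no graph; a
  zero-size outcome cohort with nonzero pathway rows is an error.

## The synthetic generator

Real PAD extracts are not redistributable, so the package ships a
generator that emulates their *structure*: per-patient ordered treatment
events, an optional amputation event, duplicate treatment events,
post-outcome events, and a person table with demographics and
comorbidity flags. A `synthetic_spec()` declares pathway allocations —
blocks of patients with an intended extracted sequence — and the
generator guarantees, by construction, that extraction over its output
recovers the allocation table exactly:

* inter-event gaps are `1 + Poisson(gap_days − 1)` days (default mean
  gap 30 days), so dates strictly increase within a patient and
  ordering is never tie-dependent in generated data (tie handling is
  exercised separately with hand-built logs);
* duplicate noise re-emits an already-present category no earlier than
  its first occurrence and strictly before any amputation;
* post-outcome noise (any category) is dated after the amputation and
  only exists for amputation patients — a non-amputation patient has no
  outcome date, and a new late category would change their sequence,
  which the noise-invariance contract forbids;
* defaults `p_duplicate_event = 0.25`, `p_post_outcome_event = 0.25`,
  `max_extra_events = 3` keep noisy logs roughly 20–40% larger than
  clean ones, a plausible level of repeat prescribing and post-outcome
  care without dominating the signal.

Confounder attributes are independent Bernoulli draws at configurable
prevalences (defaults reflect a typical elderly PAD population: e.g.
hypertension 0.65, hyperlipidemia 0.75, age ~ Normal(69, 11) truncated
to 18–100) unless an allocation pins them explicitly — that is how the
stratified fixtures place exact patient counts inside a stratum. Because
flags are sampled independently, the generator does **not** emulate the
correlation structure of real comorbidities (diabetes and coronary
artery disease co-occur, in reality), nor disease progression, seasonal
patterns, coding errors, or informative missingness. Passing tests on
synthetic cohorts therefore demonstrates the *pipeline's* correctness —
counting, normalization, invariances — not clinical validity on any real
population.

### Published worked-example fixtures

`paper_fixture()` reconstructs cohorts from published cohort sizes and
printed percentage rates by integer back-solving: the count `k` is the
integer with `round(100·k/N, digits)` equal to the printed rate, scanned
over `0..N` at the printed precision. When several `k` qualify (common
for 1-decimal rates in a cohort of thousands) the smallest is used and a
warning raised; when none does, the printed rate is inconsistent with
the stated cohort size and the fixture refuses to guess. Every
back-solved allocation carries its provenance (printed rate, precision,
cohort size, solved count) in the spec's `"provenance"` attribute.
Filler patients padding a cohort to its published size use pathways
disjoint from the documented ones, so documented rates are unaffected.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `gap_days` | generator | 30 days | typical outpatient follow-up spacing; only affects dates, never counts |
| `p_duplicate_event`, `p_post_outcome_event` | generator | 0.25 | moderate, realistic noise; any value in [0,1] must leave sequences unchanged |
| `max_extra_events` | generator | 3 | caps each noise type per patient |
| `top_k` | dominance tables | all rows | published tables hand-pick a subset; no selection rule beyond dominance is stated, so the cut is a parameter |
| `conf_level` | odds table | off | the core analysis reports no intervals; Woolf CIs are opt-in |
| age thresholds | strata | 50, 65, 80 | the published cuts; arbitrary values accepted |
| colors | Sankey | `#FF8C00` / `#01796F` | "deep amber" and "pine green" families; hex configurable |

Age is a static attribute of the person table; no age-at-index
computation is attempted because the data model carries no index date.
Race and gender filters are case-insensitive exact matches against the
analyzed vocabularies ({white, black, asian}, {male, female}); other
values fall outside every stratum, and stratum sizes are consequently
*not* forced to partition the cohort (real race strata rarely do, due to
other/unknown categories).

## Problem sizes

The test suite and the acceptance script work at the scale of the
published cohorts: amputation cohorts of 77 and 176, non-amputation
cohorts up to 5504, full mixed cohorts of ~5600 patients; property
checks (noise invariance, permutation stability, brute-force recount
oracles) use 10–20-patient cohorts where an exhaustive independent
recount is feasible. A full generate → extract → tabulate run at the
5600-patient scale takes on the order of a second.

## Known limitations

* The category vocabulary is fixed at six treatments; mapping from raw
  source codes is the caller's responsibility, as the defining code
  lists are data-source specific.
* Stratification is the only confounder handling — no matching,
  weighting or regression adjustment.
* The Sankey renderer (`plot()` method) is a simple static view for
  inspection; the JSON export is the canonical figure artifact.
* Odds ratios at these amputation counts are noisy, frequently
  correction-flagged, and carry no inferential dressing by default;
  treat them as descriptive.
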