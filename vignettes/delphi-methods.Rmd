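---
title: "Quantifying expert consensus: the methods behind randelphi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying expert consensus: the methods behind randelphi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randelphi)
```

## The problem

A RAND-modified Delphi study develops a questionnaire (or a set of
recommendations) by alternating individual expert rating rounds with a
moderated consensus meeting. Each expert rates every candidate item for
relevance on a 9-point Likert scale — 1 "not relevant" to 9 "highly
relevant", with an explicit "not evaluable" escape — and additionally ranks
the questions of each questionnaire part in a top-3 or top-5 prioritization
list. Predefined quantitative rules then triage items into *selected*
(green), *up for discussion* (orange), and *not selected* (red) before the
panel meets.

`randelphi` implements the quantitative machinery of that process end to
end: data ingestion and validation, per-item statistics, the triage rules,
personalized feedback reports, auditable decision ledgers that carry one
questionnaire version into the next, and a seeded synthetic-panel generator
that makes every stage testable without access to real panel data. The
package models a study in which a 14-member primary-care expert panel rated
a 34-question, 57-item instrument for evaluating automated audit & feedback
systems, and its bundled fixtures replay that study's item arithmetic.

## Per-item statistics

Three statistics summarize each item, computed over evaluable (numeric)
ratings only:

* **Median Likert score.** The sample median of the panelists' scores; for
  an even count, the mean of the two middle order statistics, so
  half-integer medians occur. An item with no evaluable ratings is flagged
  `UNSCORABLE` and excluded from classification — it is never silently
  scored as zero.

* **Tertile fractions.** The 9-point scale splits into equal tertiles
  (1–3 lowest, 4–6 middle, 7–9 highest); the three fractions of evaluable
  scores sum to one. The consensus rule below is phrased in terms of
  "scores in the highest tertile"; since a single item has only one median,
  we read this as the distribution of the *individual panelists'* scores
  for the item — the only per-item reading under which a percentage is
  computable. Equal thirds of the scale is the standard RAND/UCLA
  convention; the rule source does not define the bounds.

* **Prioritization ("top") percentage.** In a part with ranking depth
  *k* ∈ {3, 5}, the question ranked *r*-th by a panelist earns
  *k − r + 1* points; unranked questions earn 0. The top percentage is

  $$\mathrm{top\%} \;=\; 100 \times
    \frac{\sum_{\text{panelists}} \text{points}}{n_{\text{panel}} \times k}.$$

  The denominator counts the full active panel, including panelists who
  omitted the question — with 14 panelists, ten first places and four
  omissions give $100 \times 50/70 = 71.4\%$. The panel size is an explicit
  parameter, never inferred from the ratings file, because a panelist may
  drop out between rounds without their round-1 ratings disappearing.
  Top-3 lists score 3/2/1 by the same *k − r + 1* rule. Ratings are
  collected per item but rankings per question, so each sub-item inherits
  its parent question's top percentage; the triage rules consume both
  statistics per item, and inheritance is the only consistent way to
  combine them.

## Triage rules

Preselection and consensus are assessed independently, then combined.
All cut-offs live in a `delphi_thresholds()` object; the defaults are the
study's published criteria.

**Preselection** (median × top percentage):

| median | top percentage | outcome |
|---|---|---|
| ≥ 7 | ≥ 20% | Selection |
| ≥ 7 | (0%, 20%) | Discussion |
| < 7 | ≥ 20% | Discussion |
| otherwise | | No selection |

The middle band is read as the *open* interval (0, 20): a qualifying median
with a top percentage of exactly zero falls to "No selection". That is the
only reading under which the four rows partition the plane with no gaps or
overlaps, and the property tests assert exactly that partition.

**Consensus** (tertile agreement): at least 70% of scores in the highest
tertile → Consensus; else at least 30% in the highest *and* 30% in the
lowest tertile (a polarized panel) → Discussion; otherwise → No consensus.

**Combination.** The published three-color triage does not print its
combination table, so the package implements the strictest total rule
consistent with it: an item is SELECTED only when preselection says
Selection *and* consensus says Consensus; NOT_SELECTED only when both
rules return their bottom category; every other combination is
UP_FOR_DISCUSSION. The rule is a pure function exposed as `classify_item()`
so an alternative policy can be swapped in; the published triage counts
cannot arbitrate between candidate rules because the raw ratings were
never published.

## Decision ledgers and the round arithmetic

The consensus meeting overrides the automatic triage: items are reworded
and promoted, previously selected items dropped, new questions added. Those
decisions are therefore first-class *input data* — a YAML ledger of
`{target, action, rationale}` — not something inferred from verdicts.
`apply_ledger()` supports `KEEP`, `DROP`, `PROMOTE` (only valid for items
the triage did not select), `ADD` (a new question payload), and `MODIFY`
(rewording only; never affects counts). Defaults: with verdicts supplied,
unmentioned selected items are kept and unmentioned orange/red items are
dropped; without verdicts everything defaults to kept, so an empty ledger
is the identity. A question whose items all disappear is removed.

Every application reports a change summary satisfying the conservation
identities `items_out = kept + promoted + added` and
`items_in = kept + promoted + dropped`, and `audit_trail()` re-checks them
while replaying a whole chain of versions.

The bundled fixtures replay the modeled study's chain: 57 items triaged
34/16/7, then a consensus ledger keeping 31 of the 34 selected items,
promoting ten discussion items and two not-selected items, and adding one
new question — 44 items over 31 questions — then a final-evaluation ledger
dropping one question: 43 items over 30 questions. Because the raw panel
data are unpublished, the round-1 verdict fixture and parts of the initial
item structure are synthetic reconstructions (marked `_synthetic` in their
filenames): every item id the study names as promoted or dropped is
honored, and the free choices (which unnamed item was the third
selected-then-dropped one, which question had which sub-items) were made
once so that every published count is satisfied simultaneously. The study's
abstract and results disagree on the final item count (42 vs 43); the
fixtures follow the results chain (43) and this discrepancy is documented
rather than silently resolved.

## Feedback reports

Between the rating round and the meeting, each expert receives a personal
markdown report: per item, the full panel's score distribution (a 1–9
histogram line plus the count of "not evaluable" answers), the median and
top percentage, the recipient's own score and comment, other panelists'
comments anonymized, and the provisional color. Rendering is deterministic
— identical inputs give byte-identical files — and other panelists'
identities never appear anywhere in the document; the anonymized comment
order is a seeded shuffle keyed on the item id so it is stable across
recipients and runs.

## The synthetic panel generator

`generate_panel()` draws a complete questionnaire round with the
statistical structure the triage rules assume. Each question carries a
latent *profile*:

| profile | score mass | latent relevance | intended fate |
|---|---|---|---|
| `consensus_high` | ≥ 0.90 on 7–9 | 0.90 | selected |
| `polarized` | ≥ 0.30 on 1–3 and on 7–9 | 0.50 | up for discussion |
| `middling` | centred on 4–6 | 0.30 | mostly not selected |
| `irrelevant` | ≥ 0.70 on 1–6, concentrated low | 0.05 | not selected |

Ratings are drawn independently per (panelist, item) from the profile's
score distribution, with a small probability (`ne_rate`, default 0.02) of
an explicit "not evaluable" answer. Rankings use Plackett–Luce-style
sequential sampling without replacement, with weights proportional to
latent relevance times a lognormal panelist-specific perturbation
(log-sd 0.4) — the simplest model that produces coherent top-k lists in
which genuinely relevant questions are stochastically ranked higher. The
default configuration mirrors the modeled study's scale: 14 panelists,
34 questions, 57 items, five parts with depths 5/3/5/5/5, one panelist
dropping out after round 1, and a profile mix (0.60 / 0.20 / 0.12 / 0.08)
chosen so the expected triage proportions resemble the study's 34/16/7
split. These defaults were fixed once, from the study's reported
conditions, before any recovery rates were measured.

What the generator deliberately does *not* model: rater-severity effects
(ratings are conditionally independent given the profile, because the
triage rules consume only marginal per-item distributions), qualitative
comments, and opinion shift between rounds. Passing recovery tests
therefore show that the rules recover the intended classes under the
assumed independence structure — not that they are robust to correlated
raters or to panels whose behaviour drifts.

`recovery_experiment()` runs generate → score → triage repeatedly and
tabulates true profile against triage status. In the test suite, 20
replicates of the default-scale panel confirm that consensus-high items at
maximal relevance are selected in well over 90% of item-replicates and
irrelevant items never are; the suite uses 5-replicate tables for the
softer class-dominance checks to keep the default run fast. The
distributional sanity check draws roughly 10,000 ratings (60 panelists ×
57 items × 3 replicates) per profile and requires a chi-square
goodness-of-fit p-value above 0.01.

## Numerical and degenerate-input choices

* Validation is total and typed: malformed rows, out-of-range scores,
  duplicate (panelist, item) pairs, over-long or duplicated ranking lists,
  unknown ids, and promotion of an already-selected item each raise a
  classed error (`randelphi_parse_error`, `randelphi_validation_error`,
  `randelphi_domain_error`, `randelphi_io_error`); nothing is skipped
  silently.
* "Not evaluable" (`NE` in the CSV) and missing (empty cell or absent row)
  are distinct states, preserved exactly through I/O; both are excluded
  from medians and tertile denominators and never count as low scores.
* Threshold comparisons are inclusive (`≥`) exactly where the rule table
  says "≥"; the single open interval is the (0, 20%) discussion band
  discussed above.
* Results CSVs store numerics to nine significant digits, so a write/read
  cycle is stable to at least six decimal places.
* All randomness flows from one integer seed per generated object;
  replicate *r* of an experiment uses `seed + r − 1`.

## Problem sizes

The default test-suite configurations are the study-scale panel (14 × 57)
for exactness checks, 20 seeded replicates for the recovery acceptance
check, and ~10,000 draws for the distributional check; the full suite runs
in well under two minutes on a single CPU.
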