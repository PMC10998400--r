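# randelphi

Quantitative machinery for RAND-modified Delphi studies — the consensus
method that develops and content-validates a questionnaire (or a set of
clinical recommendations) by alternating individual expert rating rounds
with a moderated consensus meeting.

The package targets analysts running such a panel: it ingests and
validates panelist ratings and rankings, computes the per-item statistics
the selection rules consume, applies the triage, renders each expert's
personal feedback report, and replays the meeting's decisions as auditable
ledgers that carry one questionnaire version into the next. A seeded
synthetic-panel generator makes the whole pipeline testable without real
panel data. The bundled fixtures model a study in which a 14-member
primary-care expert panel validated a questionnaire for evaluating
automated audit & feedback (A&F) systems.

## The statistics at the core

Each expert rates every item on a 9-point Likert relevance scale (with an
explicit "not evaluable" option) and ranks each questionnaire part's
questions in a top-3 or top-5. Per item, over the evaluable scores only:

- **median** Likert score (half-integers possible with an even panel);
- **tertile fractions** — shares of scores in 1–3 / 4–6 / 7–9;
- **prioritization (top) percentage** — a question ranked *r*-th in a
  top-*k* earns *k − r + 1* points, unranked earns 0, and

  top% = 100 × Σ points / (n_panel × k),

  so ten first places and four omissions in a 14-member top-5 give
  100 × 50/70 = **71.4%**.

Preselection (median ≥ 7 and top% ≥ 20 → Selection; one of the two → 
Discussion; otherwise No selection) and consensus (≥ 70% of scores in the
highest tertile → Consensus; ≥ 30% in both extreme tertiles → Discussion;
else No consensus) combine into the green / orange / red triage:
SELECTED only when both rules return their top category, NOT_SELECTED only
when both return their bottom one, UP_FOR_DISCUSSION otherwise.

## Worked example

Simulate a study-scale panel (14 experts, 34 questions, 57 items), score
it, and triage:

```r
library(randelphi)

sim    <- generate_panel(panel_config(seed = 42))
scores <- score_round(sim$ratings, sim$rankings, sim$questionnaire,
                      panel_size = 14)
tri    <- triage_round(scores)
tri$summary
#>          SELECTED UP_FOR_DISCUSSION      NOT_SELECTED
#>                28                23                 6

head(scores[, c("item_id", "n_evaluable", "median", "frac_high", "top_pct")], 5)
#>   item_id n_evaluable median frac_high top_pct
#> 1 1                11    5       0.182    7.14
#> 2 2                13    2       0.154   17.1
#> 3 3                13    8       0.846   34.3
#> 4 4                14    4.5     0.214    7.14
#> 5 5                13    4       0.385   30
```

Item 3, say, has a median of 8 (≥ 7) and a top percentage of 34.3%
(≥ 20%), and 84.6% of its scores sit in the highest tertile — both rules
endorse it, so it is SELECTED (green). Item 2 fails both and is red.

Replaying the bundled study chain — the round-1 triage of 57 items into
34 selected / 16 for discussion / 7 rejected, then the consensus meeting's
ledger (keep 31 of the 34, promote 10 + 2, add one question), then the
final evaluation (drop one question):

```r
v1   <- read_questionnaire(study_fixture("initial_questionnaire_synthetic.yaml"))
verd <- tibble::as_tibble(read.csv(study_fixture("round1_verdicts_synthetic.csv"),
                                   colClasses = "character"))
res  <- apply_ledger(v1, read_ledger(study_fixture("ledger_consensus_synthetic.yaml")), verd)
res$summary
#>   stage           items_in  kept dropped promoted added modified items_out questions_in questions_out
#>   consensus_round       57    31      14       12     1        0        44           34            31

res2 <- apply_ledger(res$version, read_ledger(study_fixture("ledger_final_synthetic.yaml")))
n_items(res2$version); n_questions(res2$version)
#> 43 items / 30 questions
```

Feedback reports (`build_report()` + `render_markdown()`) and the
file-oriented pipeline commands (`cmd_simulate()`, `cmd_score()`,
`cmd_feedback()`, `cmd_apply()`, `cmd_audit()`; also scriptable via
`inst/cli/delphi.R`) round out the workflow. See the vignette
`vignettes/delphi-methods.Rmd` for the model, its assumptions, and every
design choice.

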