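#' Bundled study-chain fixtures
#'
#' The package ships the file set needed to replay the published item
#' arithmetic of the study it models (57 items in 34 questions, triaged
#' 34/16/7, then 44 items / 31 questions after the consensus meeting, then
#' 43 items / 30 questions after the final evaluation):
#'
#' * `initial_questionnaire_synthetic.yaml` — the 34-question, 57-item
#'   draft structure. The sub-question layout is a synthetic reconstruction:
#'   the raw instrument's internal structure is only partly published, so
#'   the item ids named in the study's results are honored and the rest is
#'   constructed to satisfy every published count.
#' * `round1_verdicts_synthetic.csv` — per-item triage statuses consistent
#'   with the published 34/16/7 split and with every item the study names as
#'   promoted or dropped. Synthetic for the same reason: the raw panel
#'   ratings were never published.
#' * `ledger_consensus_synthetic.yaml` — the consensus-meeting decisions:
#'   31 of the 34 selected items kept, ten discussion items and two
#'   not-selected items promoted, one new payment-system question added.
#' * `ledger_final_synthetic.yaml` — the final evaluation: one question
#'   dropped at the researchers' request.
#' * `final_questionnaire.yaml` — the published final instrument
#'   (30 questions, 43 items).
#' * `thresholds.yaml` — the default selection thresholds.
#'
#' @param name Fixture file name; with no argument, lists the available
#'   fixtures.
#' @return The full path to the installed fixture file.
#' @export
#' @examples
#' study_fixture()
#' qv <- read_questionnaire(study_fixture("initial_questionnaire_synthetic.yaml"))
#' n_items(qv)
study_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "randelphi")
  if (is.null(name)) {
    return(list.files(dir))
  }
  path <- file.path(dir, name)
  if (!file.exists(path)) abort_io(paste0("no bundled fixture named '", name, "'"))
  path
}
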