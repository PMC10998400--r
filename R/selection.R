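#' Selection and consensus thresholds
#'
#' The cut-offs the triage rules use, defaulting to the study's criteria:
#' preselection needs a median Likert score of at least `median_cut` (7) and
#' a top percentage of at least `top_cut` (20%); consensus needs at least
#' `consensus_high` (70%) of scores in the highest tertile; discussion needs
#' at least `discussion_high` (30%) in the highest and `discussion_low` (30%)
#' in the lowest tertile. All thresholds live here so sensitivity analyses
#' need no code change.
#'
#' @param median_cut Median cut-off on the 1..9 scale.
#' @param top_cut Prioritization percentage cut-off, in (0, 100\].
#' @param consensus_high Fraction of scores in the highest tertile required
#'   for consensus.
#' @param discussion_high,discussion_low Highest/lowest-tertile fractions
#'   that together mark a polarized (discussion) item.
#' @return A `delphi_thresholds` object.
#' @export
#' @examples
#' delphi_thresholds() # study defaults
delphi_thresholds <- function(median_cut = 7, top_cut = 20,
                              consensus_high = 0.70,
                              discussion_high = 0.30, discussion_low = 0.30) {
  if (median_cut < 1 || median_cut > 9) abort_domain("median_cut must be in [1, 9]")
  if (top_cut <= 0 || top_cut > 100) abort_domain("top_cut must be in (0, 100]")
  if (consensus_high <= 0 || consensus_high > 1) abort_domain("consensus_high must be in (0, 1]")
  if (discussion_high < 0 || discussion_high > 1 ||
      discussion_low < 0 || discussion_low > 1) {
    abort_domain("discussion fractions must be in [0, 1]")
  }
  structure(
    list(
      median_cut = median_cut, top_cut = top_cut,
      consensus_high = consensus_high,
      discussion_high = discussion_high, discussion_low = discussion_low
    ),
    class = "delphi_thresholds"
  )
}

#' Read thresholds from an optional YAML file
#'
#' Keys `median_cut`, `top_cut`, `consensus_high`, `discussion_high`,
#' `discussion_low`; absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A [delphi_thresholds()] object.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  doc <- yaml::read_yaml(path)
  defaults <- delphi_thresholds()
  delphi_thresholds(
    median_cut = doc$median_cut %||% defaults$median_cut,
    top_cut = doc$top_cut %||% defaults$top_cut,
    consensus_high = doc$consensus_high %||% defaults$consensus_high,
    discussion_high = doc$discussion_high %||% defaults$discussion_high,
    discussion_low = doc$discussion_low %||% defaults$discussion_low
  )
}

#' Preselection rule: median x top percentage
#'
#' Four rows partition the (median, top percentage) plane:
#' median >= cut and top >= top_cut is SELECTION; median >= cut with top
#' strictly between 0 and top_cut is DISCUSSION; median < cut with top >=
#' top_cut is DISCUSSION; anything else (including a qualifying median with
#' a zero top percentage) is NO_SELECTION. The "between 1-20%" band is read
#' as the open interval (0, top_cut) — the only reading under which the four
#' rows neither overlap nor leave gaps.
#'
#' @param median Median Likert score, in \[1, 9\]. Vectorized.
#' @param top_pct Prioritization percentage, in \[0, 100\]. Vectorized.
#' @param thresholds A [delphi_thresholds()] object.
#' @return Character vector: `"SELECTION"`, `"DISCUSSION"`, or
#'   `"NO_SELECTION"`.
#' @export
#' @examples
#' preselect(8, 25) # SELECTION
#' preselect(8, 10) # DISCUSSION
#' preselect(7, 0) # NO_SELECTION
preselect <- function(median, top_pct, thresholds = delphi_thresholds()) {
  if (any(median < 1 | median > 9)) abort_domain("median must be in [1, 9]")
  if (any(top_pct < 0 | top_pct > 100)) abort_domain("top_pct must be in [0, 100]")
  med_ok <- median >= thresholds$median_cut
  top_ok <- top_pct >= thresholds$top_cut
  top_partial <- top_pct > 0 & top_pct < thresholds$top_cut
  ifelse(
    med_ok & top_ok, "SELECTION",
    ifelse(med_ok & top_partial, "DISCUSSION",
      ifelse(!med_ok & top_ok, "DISCUSSION", "NO_SELECTION")
    )
  )
}

#' Consensus rule: tertile agreement
#'
#' CONSENSUS when at least `consensus_high` of the evaluable scores sit in
#' the highest tertile (7-9); DISCUSSION when opinion is polarized, with at
#' least `discussion_high` in the highest and `discussion_low` in the lowest
#' tertile; NO_CONSENSUS otherwise.
#'
#' @param frac_high,frac_low Fractions of scores in the highest and lowest
#'   tertiles, each in \[0, 1\], jointly at most 1. Vectorized.
#' @inheritParams preselect
#' @return Character vector: `"CONSENSUS"`, `"DISCUSSION"`, or
#'   `"NO_CONSENSUS"`.
#' @export
#' @examples
#' consensus_outcome(1, 0) # CONSENSUS
#' consensus_outcome(0.5, 0.4) # DISCUSSION
#' consensus_outcome(0.5, 0.1) # NO_CONSENSUS
consensus_outcome <- function(frac_high, frac_low, thresholds = delphi_thresholds()) {
  if (any(frac_high < 0 | frac_high > 1 | frac_low < 0 | frac_low > 1)) {
    abort_domain("tertile fractions must be in [0, 1]")
  }
  if (any(frac_high + frac_low > 1 + 1e-9)) {
    abort_domain("frac_high + frac_low cannot exceed 1")
  }
  ifelse(
    frac_high >= thresholds$consensus_high, "CONSENSUS",
    ifelse(frac_high >= thresholds$discussion_high &
             frac_low >= thresholds$discussion_low,
           "DISCUSSION", "NO_CONSENSUS")
  )
}

#' Combine preselection and consensus into the triage status
#'
#' Both outcomes in their top category give SELECTED (green); both in their
#' bottom category give NOT_SELECTED (red); every other combination is
#' UP_FOR_DISCUSSION (orange). This is the strictest total rule consistent
#' with a three-color triage and is a policy choice: an item is only waved
#' through when both the relevance and the agreement rule endorse it.
#'
#' @param preselection `"SELECTION"`, `"DISCUSSION"`, or `"NO_SELECTION"`.
#'   Vectorized.
#' @param consensus `"CONSENSUS"`, `"DISCUSSION"`, or `"NO_CONSENSUS"`.
#'   Vectorized.
#' @return Character vector: `"SELECTED"`, `"UP_FOR_DISCUSSION"`, or
#'   `"NOT_SELECTED"`.
#' @export
classify_item <- function(preselection, consensus) {
  ok_p <- preselection %in% c("SELECTION", "DISCUSSION", "NO_SELECTION")
  ok_c <- consensus %in% c("CONSENSUS", "DISCUSSION", "NO_CONSENSUS")
  if (!all(ok_p)) abort_domain("invalid preselection outcome")
  if (!all(ok_c)) abort_domain("invalid consensus outcome")
  ifelse(
    preselection == "SELECTION" & consensus == "CONSENSUS", "SELECTED",
    ifelse(preselection == "NO_SELECTION" & consensus == "NO_CONSENSUS",
           "NOT_SELECTED", "UP_FOR_DISCUSSION")
  )
}

#' @rdname classify_item
#' @param status Triage status vector.
#' @return [status_color()]: `"green"`, `"orange"`, or `"red"` — a pure
#'   function of the status.
#' @export
status_color <- function(status) {
  out <- c(
    SELECTED = "green", UP_FOR_DISCUSSION = "orange", NOT_SELECTED = "red"
  )[status]
  if (anyNA(out)) abort_domain("invalid triage status")
  unname(out)
}

#' Triage a whole round of item scores
#'
#' Applies [preselect()], [consensus_outcome()] and [classify_item()] to
#' every scorable item and tallies the statuses. Items flagged unscorable
#' (no evaluable ratings) are listed separately and excluded from
#' classification.
#'
#' @param scores Tibble from [score_round()].
#' @inheritParams preselect
#' @return A list: `verdicts` (tibble `item_id`, `preselection`,
#'   `consensus`, `status`, `color`), `summary` (named counts of SELECTED /
#'   UP_FOR_DISCUSSION / NOT_SELECTED), `unscorable` (character vector of
#'   item ids).
#' @export
triage_round <- function(scores, thresholds = delphi_thresholds()) {
  unscorable <- character()
  if ("unscorable" %in% names(scores)) {
    unscorable <- scores$item_id[scores$unscorable]
    scores <- scores[!scores$unscorable, ]
  }
  if (nrow(scores) == 0L) {
    verdicts <- tibble(
      item_id = character(), preselection = character(),
      consensus = character(), status = character(), color = character()
    )
  } else {
    pres <- preselect(scores$median, scores$top_pct, thresholds)
    cons <- consensus_outcome(scores$frac_high, scores$frac_low, thresholds)
    status <- classify_item(pres, cons)
    verdicts <- tibble(
      item_id = scores$item_id, preselection = pres, consensus = cons,
      status = status, color = status_color(status)
    )
  }
  summary <- c(
    SELECTED = sum(verdicts$status == "SELECTED"),
    UP_FOR_DISCUSSION = sum(verdicts$status == "UP_FOR_DISCUSSION"),
    NOT_SELECTED = sum(verdicts$status == "NOT_SELECTED")
  )
  list(verdicts = verdicts, summary = summary, unscorable = unscorable)
}
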