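#' Median relevance score of an item
#'
#' The sample median of the panelists' 1..9 Likert relevance ratings for one
#' item. With an even number of ratings this is the mean of the two middle
#' order statistics, so half-integer medians occur. Not-evaluable and missing
#' answers must already have been removed: scoring an item nobody could rate
#' is an error, never a silent zero.
#'
#' @param scores Integer vector of Likert scores, each in 1..9.
#' @return The median, a number in \[1, 9\].
#' @export
#' @examples
#' median_score(c(7, 7, 8)) # 7
#' median_score(c(6, 8)) # 7
median_score <- function(scores) {
  check_scores(scores)
  median(as.numeric(scores))
}

#' Tertile fractions of an item's scores
#'
#' The 9-point scale splits into equal tertiles: lowest 1-3, middle 4-6,
#' highest 7-9. Returns the share of evaluable scores falling in each; the
#' three fractions sum to one.
#'
#' @inheritParams median_score
#' @return Named numeric vector `c(frac_low, frac_mid, frac_high)`.
#' @export
#' @examples
#' tertile_fractions(c(1, 2, 8, 9)) # 0.5, 0, 0.5
tertile_fractions <- function(scores) {
  check_scores(scores)
  n <- length(scores)
  c(
    frac_low = sum(scores <= 3L) / n,
    frac_mid = sum(scores >= 4L & scores <= 6L) / n,
    frac_high = sum(scores >= 7L) / n
  )
}

check_scores <- function(scores) {
  if (length(scores) == 0L) abort_empty_scores()
  if (anyNA(scores)) abort_domain("scores contain NA; remove NE/missing before scoring")
  if (any(scores < 1L | scores > 9L)) abort_domain("scores must be integers in 1..9")
  invisible(scores)
}

#' Prioritization (top) percentage of a question
#'
#' Panelists rank the questions of a part in a top-3 or top-5. The question
#' ranked first earns k points (k = the part's ranking depth), the second
#' k - 1, and so on; a question left out of a panelist's list earns 0. The
#' top percentage is the summed points across the whole panel divided by the
#' maximum attainable, `panel_size * k`, times 100. The denominator counts
#' every active panelist, including those who omitted the question: with 14
#' panelists and a top-5, ten first-place votes and four omissions give
#' 50 / 70 = 71.4%.
#'
#' @param rankings A [ranking_set()].
#' @param question_id The question to score.
#' @param part The part (from the questionnaire's `parts`) the question
#'   belongs to; supplies the ranking depth k.
#' @param panel_size Number of active panelists in the round (an explicit
#'   parameter, never inferred from the rankings file).
#' @return Percentage in \[0, 100\].
#' @export
prioritization_pct <- function(rankings, question_id, part, panel_size) {
  if (panel_size < 1L) abort_domain("panel_size must be >= 1")
  k <- part$ranking_depth
  in_part <- vapply(part$questions, `[[`, character(1), "question_id")
  if (!question_id %in% in_part) {
    abort_domain(paste0("question '", question_id, "' is not in part '", part$part_id, "'"))
  }
  entries <- rankings$entries[rankings$entries$part_id == part$part_id, ]
  points <- 0
  for (qs in entries$ranked_questions) {
    r <- match(question_id, qs)
    if (!is.na(r)) points <- points + (k - r + 1L)
  }
  100 * points / (panel_size * k)
}

#' Score one item: median, tertile fractions, top percentage
#'
#' Combines the per-item Likert statistics with the parent question's
#' prioritization percentage. Ratings are collected per item but rankings per
#' question, so every sub-item inherits its parent question's top percentage.
#' `n_evaluable` counts numeric ratings only; explicit "not evaluable"
#' answers and missing answers are excluded from every denominator except the
#' prioritization one. An item with zero evaluable ratings is returned
#' flagged `unscorable` (with a warning) rather than scored.
#'
#' @param ratings A [rating_matrix()].
#' @param rankings A [ranking_set()].
#' @param item_id Id of the item to score.
#' @param question The parent question (list as from [new_question()]).
#' @param part The part holding the question.
#' @param panel_size Active panel size for the prioritization denominator.
#' @return One-row tibble: `item_id`, `n_evaluable`, `median`, `frac_low`,
#'   `frac_mid`, `frac_high`, `top_pct`, `unscorable`.
#' @export
score_item <- function(ratings, rankings, item_id, question, part, panel_size) {
  item_ids <- vapply(question$items, `[[`, character(1), "item_id")
  if (!item_id %in% item_ids) {
    abort_domain(paste0("item '", item_id, "' is not in question '", question$question_id, "'"))
  }
  rows <- ratings$ratings[ratings$ratings$item_id == item_id, ]
  evaluable <- rows$score[!is.na(rows$score)]
  top <- prioritization_pct(rankings, question$question_id, part, panel_size)
  if (length(evaluable) == 0L) {
    warn(paste0("item '", item_id, "' has no evaluable ratings; flagged UNSCORABLE"))
    return(tibble(
      item_id = item_id, n_evaluable = 0L, median = NA_real_,
      frac_low = NA_real_, frac_mid = NA_real_, frac_high = NA_real_,
      top_pct = top, unscorable = TRUE
    ))
  }
  tert <- tertile_fractions(evaluable)
  tibble(
    item_id = item_id,
    n_evaluable = length(evaluable),
    median = median_score(evaluable),
    frac_low = tert[["frac_low"]],
    frac_mid = tert[["frac_mid"]],
    frac_high = tert[["frac_high"]],
    top_pct = top,
    unscorable = FALSE
  )
}

#' Score every item of a questionnaire version
#'
#' @inheritParams score_item
#' @param questionnaire The `questionnaire_version` being rated.
#' @return Tibble with one [score_item()] row per item, in questionnaire
#'   order.
#' @export
score_round <- function(ratings, rankings, questionnaire, panel_size) {
  out <- list()
  for (part in questionnaire$parts) {
    for (question in part$questions) {
      for (it in question$items) {
        out[[length(out) + 1L]] <-
          score_item(ratings, rankings, it$item_id, question, part, panel_size)
      }
    }
  }
  dplyr::bind_rows(out)
}
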