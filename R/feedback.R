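#' Build a personalized feedback report for one panelist
#'
#' Between the questionnaire round and the consensus meeting each expert
#' receives a personal form showing, per item: the whole panel's score
#' distribution, the median and top percentage, the expert's own score and
#' comment, the other panelists' comments (anonymized), and the item's
#' triage status with its color. Other panelists' identities never appear.
#'
#' @param panelist_id The recipient; must be in the round's panel.
#' @param ratings A [rating_matrix()].
#' @param results Results tibble joining [score_round()] scores and
#'   [triage_round()] verdicts (columns `item_id`, `n_evaluable`, `median`,
#'   `top_pct`, `status` at minimum; `unscorable` rows are skipped).
#' @param questionnaire The `questionnaire_version`, for item order and
#'   text.
#' @return A `feedback_report` object with one block per classifiable item.
#' @export
build_report <- function(panelist_id, ratings, results, questionnaire) {
  if (!panelist_id %in% ratings$panel) {
    abort_domain(paste0("unknown panelist '", panelist_id, "'"))
  }
  tab <- item_table(questionnaire)
  if ("unscorable" %in% names(results)) results <- results[!results$unscorable, ]
  classifiable <- tab[tab$item_id %in% results$item_id, ]
  rr <- ratings$ratings
  blocks <- list()
  for (i in seq_len(nrow(classifiable))) {
    iid <- classifiable$item_id[i]
    res <- results[results$item_id == iid, ]
    rows <- rr[rr$item_id == iid, ]
    own <- rows[rows$panelist_id == panelist_id, ]
    own_score <- if (nrow(own) == 0L || (!own$not_evaluable && is.na(own$score))) {
      "missing"
    } else if (own$not_evaluable) {
      "not evaluable"
    } else {
      as.character(own$score)
    }
    own_comment <- if (nrow(own) == 1L && nzchar(own$comment)) own$comment else ""
    others <- rows[rows$panelist_id != panelist_id & nzchar(rows$comment), ]
    # deterministic anonymized order, independent of rater identity
    other_comments <- character()
    if (nrow(others) > 0L) {
      ord <- withr::with_seed(
        sum(utf8ToInt(iid)) + nrow(others),
        sample.int(nrow(others))
      )
      other_comments <- others$comment[ord]
    }
    dist <- tabulate(rows$score[!is.na(rows$score)], nbins = 9L)
    blocks[[length(blocks) + 1L]] <- list(
      item_id = iid,
      item_text = classifiable$item_text[i],
      question_id = classifiable$question_id[i],
      distribution = setNames(dist, as.character(1:9)),
      n_not_evaluable = sum(rows$not_evaluable),
      median = res$median,
      top_pct = res$top_pct,
      own_score = own_score,
      own_comment = own_comment,
      other_comments = other_comments,
      status = res$status,
      color = status_color(res$status)
    )
  }
  structure(
    list(
      panelist_id = panelist_id,
      round_label = ratings$round_label,
      blocks = blocks
    ),
    class = "feedback_report"
  )
}

#' @export
print.feedback_report <- function(x, ...) {
  cat("<feedback_report for '", x$panelist_id, "', ", x$round_label, "> ",
      length(x$blocks), " items\n", sep = "")
  invisible(x)
}

#' Render a feedback report as markdown
#'
#' Produces a deterministic markdown document: identical reports render to
#' byte-identical text. The panel's score distribution is shown as a 1-9
#' histogram line plus the count of "not evaluable" answers.
#'
#' @param report A [build_report()] result.
#' @param path Optional output path; when given the document is written
#'   there (UTF-8).
#' @return The markdown text as a single string, invisibly when `path` is
#'   given.
#' @export
render_markdown <- function(report, path = NULL) {
  lines <- c(
    paste0("# Feedback report — panelist ", report$panelist_id),
    "",
    paste0("Round: ", report$round_label),
    "",
    paste0(
      "This report shows, for each item, all panel scores, the median and ",
      "top percentage, your own score and comment, and the provisional ",
      "classification (green = selected, orange = up for discussion, ",
      "red = not selected)."
    ),
    ""
  )
  for (b in report$blocks) {
    hist_line <- paste(
      vapply(1:9, function(s) paste0(s, ":", b$distribution[[as.character(s)]]),
             character(1)),
      collapse = "  "
    )
    lines <- c(
      lines,
      paste0("## Item ", b$item_id, " — ", b$item_text),
      "",
      paste0("- Panel scores (score:count): ", hist_line,
             "  |  not evaluable: ", b$n_not_evaluable),
      paste0("- Median: ", format(b$median, nsmall = 0)),
      paste0("- Top percentage: ", formatC(b$top_pct, format = "f", digits = 1), "%"),
      paste0("- Your score: ", b$own_score),
      paste0("- Your comment: ", if (nzchar(b$own_comment)) b$own_comment else "(none)"),
      paste0("- Status: ", b$status, " (", b$color, ")")
    )
    if (length(b$other_comments) > 0L) {
      lines <- c(lines, "- Comments from other panelists (anonymized):")
      lines <- c(lines, paste0("    - ", b$other_comments))
    }
    lines <- c(lines, "")
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- tryCatch(
      file(path, open = "wb"),
      error = function(e) abort_io(paste0("cannot write ", path, ": ", conditionMessage(e)))
    )
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(text)), con)
    return(invisible(text))
  }
  text
}
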