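#' Panel ratings: container and CSV ingestion
#'
#' Ratings are stored long: one row per (panelist, item) response. A numeric
#' score is an integer 1..9 on the relevance Likert scale. A panelist who
#' explicitly chose "not evaluable" is kept as a row with `not_evaluable =
#' TRUE` (score `NA`); a (panelist, item) pair with no row at all — or a row
#' with an empty score cell — is MISSING. The two are never conflated: only
#' numeric scores enter medians and tertiles, but NE counts are reported.
#'
#' @param ratings Tibble with columns `panelist_id`, `item_id`, `score`
#'   (integer, `NA` when not numeric), `not_evaluable` (logical), `comment`
#'   (character).
#' @param panel Character vector of panelist ids active in the round.
#' @param round_label Label of the Delphi round.
#' @return A `rating_matrix` object.
#' @export
rating_matrix <- function(ratings, panel, round_label = "questionnaire_round") {
  ratings <- as_tibble(ratings)
  needed <- c("panelist_id", "item_id", "score", "not_evaluable", "comment")
  missing_cols <- setdiff(needed, names(ratings))
  if (length(missing_cols)) {
    abort_validation(paste0("ratings missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ratings$score <- as.integer(ratings$score)
  bad <- !is.na(ratings$score) & (ratings$score < 1L | ratings$score > 9L)
  if (any(bad)) {
    abort_validation(paste0(
      "score outside 1..9 for (", ratings$panelist_id[bad][1], ", ",
      ratings$item_id[bad][1], ")"
    ))
  }
  if (any(!is.na(ratings$score) & ratings$not_evaluable)) {
    abort_validation("a rating cannot be both numeric and not-evaluable")
  }
  key <- paste(ratings$panelist_id, ratings$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- ratings[duplicated(key), ][1, ]
    abort_validation(paste0(
      "duplicate rating for (", dup$panelist_id, ", ", dup$item_id, ")"
    ))
  }
  unknown <- setdiff(unique(ratings$panelist_id), panel)
  if (length(unknown)) {
    abort_validation(paste0("panelist(s) not in panel roster: ", paste(unknown, collapse = ", ")))
  }
  structure(
    list(round_label = as.character(round_label), panel = as.character(panel), ratings = ratings),
    class = "rating_matrix"
  )
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(
    "<rating_matrix '", x$round_label, "'> ", length(x$panel), " panelists, ",
    nrow(x$ratings), " ratings (", sum(x$ratings$not_evaluable),
    " not evaluable)\n",
    sep = ""
  )
  invisible(x)
}

#' Read panel ratings from a long-format CSV
#'
#' Expects UTF-8 comma-separated text with a header row and columns
#' `panelist_id,item_id,score,comment`. The score cell holds an integer 1..9,
#' the sentinel `"NE"` for an explicit "not evaluable" answer, or is empty
#' for a skipped item.
#'
#' @param path Path to the ratings CSV.
#' @param panel_roster Character vector of panelist ids allowed in this
#'   round; rows from other panelists are a validation error.
#' @param round_label Round label stored on the result.
#' @return A validated [rating_matrix()].
#' @export
read_ratings <- function(path, panel_roster, round_label = "questionnaire_round") {
  raw <- read_csv_strict(path, c("panelist_id", "item_id", "score", "comment"))
  score_txt <- trimws(raw$score)
  ne <- score_txt == "NE"
  blank <- score_txt == ""
  numeric_ok <- grepl("^-?[0-9]+$", score_txt)
  bad <- !(ne | blank | numeric_ok)
  if (any(bad)) {
    abort_parse(paste0(
      "malformed score '", score_txt[bad][1], "' at ", path, " line ",
      which(bad)[1] + 1L
    ))
  }
  score <- rep(NA_integer_, nrow(raw))
  score[numeric_ok] <- as.integer(score_txt[numeric_ok])
  ratings <- tibble(
    panelist_id = raw$panelist_id,
    item_id = raw$item_id,
    score = score,
    not_evaluable = ne,
    comment = raw$comment
  )
  # rows with an empty score cell are MISSING; keep them so counts round-trip
  rating_matrix(ratings, panel = panel_roster, round_label = round_label)
}

#' Write panel ratings back to the long CSV format
#'
#' @param rm A [rating_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(rm, path) {
  out <- rm$ratings
  score <- ifelse(out$not_evaluable, "NE", ifelse(is.na(out$score), "", as.character(out$score)))
  df <- data.frame(
    panelist_id = out$panelist_id, item_id = out$item_id,
    score = score, comment = out$comment,
    stringsAsFactors = FALSE
  )
  write_csv_strict(df, path)
}

#' Per-panelist top-k question rankings
#'
#' Each entry is one panelist's ordered prioritization list for one
#' questionnaire part: position 1 is the top-ranked question. A list may be
#' shorter than the part's ranking depth (panelists could leave slots empty)
#' but never longer, never repeats a question, and only names questions that
#' belong to the part.
#'
#' @param entries Tibble with columns `panelist_id`, `part_id`, and
#'   `ranked_questions` (a list-column of character vectors in rank order).
#' @param questionnaire The `questionnaire_version` the rankings refer to.
#' @param round_label Round label.
#' @return A `ranking_set` object.
#' @export
ranking_set <- function(entries, questionnaire, round_label = "questionnaire_round") {
  entries <- as_tibble(entries)
  needed <- c("panelist_id", "part_id", "ranked_questions")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols)) {
    abort_validation(paste0("rankings missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  qtab <- question_table(questionnaire)
  depths <- setNames(
    vapply(questionnaire$parts, `[[`, integer(1), "ranking_depth"),
    vapply(questionnaire$parts, `[[`, character(1), "part_id")
  )
  for (i in seq_len(nrow(entries))) {
    pid <- entries$part_id[i]
    qs <- entries$ranked_questions[[i]]
    if (!pid %in% names(depths)) {
      abort_validation(paste0("unknown part '", pid, "' in rankings"))
    }
    if (anyDuplicated(qs)) {
      abort_validation(paste0(
        "panelist '", entries$panelist_id[i], "' ranked question '",
        qs[duplicated(qs)][1], "' twice in part '", pid, "'"
      ))
    }
    if (length(qs) > depths[[pid]]) {
      abort_validation(paste0(
        "panelist '", entries$panelist_id[i], "' ranked ", length(qs),
        " questions in part '", pid, "' (depth ", depths[[pid]], ")"
      ))
    }
    outside <- setdiff(qs, qtab$question_id[qtab$part_id == pid])
    if (length(outside)) {
      abort_validation(paste0(
        "question '", outside[1], "' is not in part '", pid, "'"
      ))
    }
  }
  structure(
    list(round_label = as.character(round_label), entries = entries),
    class = "ranking_set"
  )
}

#' Read prioritization rankings from CSV
#'
#' Expects columns `panelist_id,part_id,ranked_questions`, the last holding a
#' semicolon-delimited ordered list (rank = position), e.g. `"q19;q21;q22"`.
#'
#' @inheritParams ranking_set
#' @param path Path to the rankings CSV.
#' @return A validated [ranking_set()].
#' @export
read_rankings <- function(path, questionnaire, round_label = "questionnaire_round") {
  raw <- read_csv_strict(path, c("panelist_id", "part_id", "ranked_questions"))
  lists <- lapply(raw$ranked_questions, function(cell) {
    cell <- trimws(cell)
    if (cell == "") character() else trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  })
  entries <- tibble(
    panelist_id = raw$panelist_id,
    part_id = raw$part_id,
    ranked_questions = lists
  )
  ranking_set(entries, questionnaire, round_label = round_label)
}

#' @rdname read_rankings
#' @param rs A [ranking_set()].
#' @export
write_rankings <- function(rs, path) {
  df <- data.frame(
    panelist_id = rs$entries$panelist_id,
    part_id = rs$entries$part_id,
    ranked_questions = vapply(rs$entries$ranked_questions, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  write_csv_strict(df, path)
}

#' Write and read a round's per-item results table
#'
#' One row per item with its descriptive statistics and verdicts:
#' `item_id,n_evaluable,median,frac_low,frac_mid,frac_high,top_pct,`
#' `preselection,consensus,status`. Numeric columns round-trip to at least
#' six decimal places.
#'
#' @param results Tibble combining item scores and verdicts (as produced by
#'   joining [score_round()] and [triage_round()] output).
#' @param path Output (or input) CSV path.
#' @return [write_results()] returns `path` invisibly; [read_results()]
#'   returns the results tibble.
#' @export
write_results <- function(results, path) {
  cols <- c(
    "item_id", "n_evaluable", "median", "frac_low", "frac_mid", "frac_high",
    "top_pct", "preselection", "consensus", "status"
  )
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols)) {
    abort_validation(paste0("results missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(results[, cols])
  for (col in c("median", "frac_low", "frac_mid", "frac_high", "top_pct")) {
    df[[col]] <- formatC(df[[col]], digits = 9, format = "g")
    df[[col]][df[[col]] %in% c("NA", " NA")] <- ""
  }
  write_csv_strict(df, path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  raw <- read_csv_strict(path, c(
    "item_id", "n_evaluable", "median", "frac_low", "frac_mid", "frac_high",
    "top_pct", "preselection", "consensus", "status"
  ))
  tibble(
    item_id = raw$item_id,
    n_evaluable = as.integer(raw$n_evaluable),
    median = num_or_na(raw$median),
    frac_low = num_or_na(raw$frac_low),
    frac_mid = num_or_na(raw$frac_mid),
    frac_high = num_or_na(raw$frac_high),
    top_pct = num_or_na(raw$top_pct),
    preselection = raw$preselection,
    consensus = raw$consensus,
    status = raw$status
  )
}

num_or_na <- function(x) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  out[x == ""] <- NA_real_
  out
}

# Shared CSV plumbing: UTF-8, header mandatory, all cells read as character.
read_csv_strict <- function(path, columns) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  raw <- tryCatch(
    read.csv(path, colClasses = "character", check.names = FALSE,
             fileEncoding = "UTF-8", na.strings = NULL),
    error = function(e) abort_parse(paste0("cannot parse ", path, ": ", conditionMessage(e)))
  )
  missing_cols <- setdiff(columns, names(raw))
  if (length(missing_cols)) {
    abort_parse(paste0(
      path, " is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  as_tibble(raw[, columns, drop = FALSE])
}

write_csv_strict <- function(df, path) {
  tryCatch(
    write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", quote = TRUE),
    error = function(e) abort_io(paste0("cannot write ", path, ": ", conditionMessage(e)))
  )
  invisible(path)
}
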