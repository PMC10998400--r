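#' Questionnaire structure: items, questions, parts, versions
#'
#' A questionnaire version is the unit the Delphi rounds transform: an ordered
#' list of parts, each holding an ordered list of questions, each holding one
#' or more rated items. A question without sub-items carries a single item
#' whose id equals the question id; sub-items use the dotted convention
#' (`"23.7"` is the seventh item under question 23).
#'
#' @param item_id,question_id,part_id Identifiers, unique at their level.
#' @param text Display text.
#' @param origin Where the item was drafted from: `"cp_fit"`, `"reflect52"`,
#'   `"both"`, or `"panel_added"`.
#' @param response_format One of `"likert_agreement"`, `"satisfaction"`,
#'   `"categorical"`, `"numeric_band"`, `"open"`.
#' @param items For [new_question()], a list of items from [new_item()];
#'   `NULL` creates the single implicit item with the question's id.
#' @param questions Non-empty list of questions from [new_question()].
#' @param title Part title.
#' @param ranking_depth Depth of the prioritization list panelists fill in
#'   for this part: 3 or 5.
#' @param parts List of parts from [new_part()].
#' @param version_label Label for this questionnaire version.
#' @param provenance Free-text note on the round that produced the version.
#'
#' @return [new_item()], [new_question()], [new_part()] return plain lists;
#'   [questionnaire_version()] returns a validated `questionnaire_version`
#'   object.
#' @export
#' @examples
#' q <- new_question("1", "What role do you assume?", "categorical")
#' p <- new_part("part1", "Caregiver data", list(q), ranking_depth = 5)
#' qv <- questionnaire_version(list(p), version_label = "draft")
#' n_items(qv)
new_item <- function(item_id, text = item_id, origin = "panel_added") {
  origin <- match.arg(origin, c("cp_fit", "reflect52", "both", "panel_added"))
  list(item_id = as.character(item_id), text = as.character(text), origin = origin)
}

#' @rdname new_item
#' @export
new_question <- function(question_id, text = question_id,
                         response_format = "likert_agreement", items = NULL) {
  response_format <- match.arg(
    response_format,
    c("likert_agreement", "satisfaction", "categorical", "numeric_band", "open")
  )
  question_id <- as.character(question_id)
  if (is.null(items)) {
    items <- list(new_item(question_id, text))
  }
  list(
    question_id = question_id, text = as.character(text),
    response_format = response_format, items = items
  )
}

#' @rdname new_item
#' @export
new_part <- function(part_id, title = part_id, questions, ranking_depth = 5) {
  list(
    part_id = as.character(part_id), title = as.character(title),
    questions = questions, ranking_depth = as.integer(ranking_depth)
  )
}

#' @rdname new_item
#' @export
questionnaire_version <- function(parts, version_label = "v1", provenance = "") {
  qv <- structure(
    list(
      version_label = as.character(version_label),
      provenance = as.character(provenance),
      parts = parts
    ),
    class = "questionnaire_version"
  )
  validate_questionnaire(qv)
}

#' Validate a questionnaire version
#'
#' Checks the structural invariants: ranking depths in \{3, 5\}, non-empty
#' parts and questions, and identifiers unique across the whole version.
#'
#' @param qv A `questionnaire_version`.
#' @return `qv`, invisibly usable, after validation; errors otherwise.
#' @export
validate_questionnaire <- function(qv) {
  if (!inherits(qv, "questionnaire_version")) {
    abort_validation("not a questionnaire_version object")
  }
  if (length(qv$parts) == 0L) abort_validation("questionnaire has no parts")
  part_ids <- vapply(qv$parts, `[[`, character(1), "part_id")
  if (anyDuplicated(part_ids)) {
    abort_validation(paste0("duplicate part id: ", part_ids[duplicated(part_ids)][1]))
  }
  for (part in qv$parts) {
    if (!part$ranking_depth %in% c(3L, 5L)) {
      abort_validation(paste0("part '", part$part_id, "': ranking_depth must be 3 or 5"))
    }
    if (length(part$questions) == 0L) {
      abort_validation(paste0("part '", part$part_id, "' has no questions"))
    }
    for (qq in part$questions) {
      if (length(qq$items) == 0L) {
        abort_validation(paste0("question '", qq$question_id, "' has no items"))
      }
    }
  }
  tab <- item_table(qv)
  if (anyDuplicated(tab$question_id[!duplicated(paste(tab$part_id, tab$question_id))])) {
    abort_validation("a question id appears in more than one part")
  }
  if (anyDuplicated(tab$item_id)) {
    abort_validation(paste0("duplicate item id: ", tab$item_id[duplicated(tab$item_id)][1]))
  }
  qv
}

#' Flat item and question tables for a questionnaire version
#'
#' @param qv A `questionnaire_version`.
#' @return [item_table()]: a tibble with one row per item
#'   (`part_id`, `question_id`, `item_id`, `item_text`, `origin`,
#'   `response_format`, `ranking_depth`). [question_table()]: one row per
#'   question. [n_items()] and [n_questions()] return counts.
#' @export
item_table <- function(qv) {
  rows <- list()
  for (part in qv$parts) {
    for (qq in part$questions) {
      for (it in qq$items) {
        rows[[length(rows) + 1L]] <- tibble(
          part_id = part$part_id,
          question_id = qq$question_id,
          item_id = it$item_id,
          item_text = it$text,
          origin = it$origin,
          response_format = qq$response_format,
          ranking_depth = part$ranking_depth
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(
      part_id = character(), question_id = character(), item_id = character(),
      item_text = character(), origin = character(),
      response_format = character(), ranking_depth = integer()
    ))
  }
  dplyr::bind_rows(rows)
}

#' @rdname item_table
#' @export
question_table <- function(qv) {
  dplyr::summarise(
    dplyr::group_by(item_table(qv), .data$part_id, .data$question_id),
    n_items = dplyr::n(), ranking_depth = .data$ranking_depth[1], .groups = "drop"
  )
}

#' @rdname item_table
#' @export
n_items <- function(qv) nrow(item_table(qv))

#' @rdname item_table
#' @export
n_questions <- function(qv) nrow(question_table(qv))

#' @export
print.questionnaire_version <- function(x, ...) {
  cat(
    "<questionnaire_version '", x$version_label, "'> ",
    length(x$parts), " parts, ", n_questions(x), " questions, ",
    n_items(x), " items\n",
    sep = ""
  )
  invisible(x)
}

#' Read and write questionnaire versions as YAML
#'
#' The on-disk form nests parts, questions, and items, with `ranking_depth`
#' per part, so a whole questionnaire version is one diff-able text file.
#'
#' @param path File path of a questionnaire YAML document.
#' @param qv A `questionnaire_version`.
#' @return [read_questionnaire()] returns a validated
#'   `questionnaire_version`; [write_questionnaire()] returns `path`
#'   invisibly.
#' @export
read_questionnaire <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$parts)) abort_parse(paste0("no 'parts' key in ", path))
  parts <- lapply(doc$parts, function(p) {
    questions <- lapply(p$questions, function(qq) {
      items <- if (is.null(qq$items)) NULL else lapply(qq$items, function(it) {
        new_item(it$item_id, it$text %||% it$item_id, it$origin %||% "panel_added")
      })
      new_question(
        qq$question_id, qq$text %||% qq$question_id,
        qq$response_format %||% "likert_agreement", items
      )
    })
    new_part(p$part_id, p$title %||% p$part_id, questions, p$ranking_depth %||% 5L)
  })
  questionnaire_version(
    parts,
    version_label = doc$version_label %||% "v1",
    provenance = doc$provenance %||% ""
  )
}

#' @rdname read_questionnaire
#' @export
write_questionnaire <- function(qv, path) {
  doc <- list(
    version_label = qv$version_label,
    provenance = qv$provenance,
    parts = lapply(qv$parts, function(p) {
      list(
        part_id = p$part_id, title = p$title, ranking_depth = p$ranking_depth,
        questions = lapply(p$questions, function(qq) {
          list(
            question_id = qq$question_id, text = qq$text,
            response_format = qq$response_format,
            items = lapply(qq$items, function(it) {
              list(item_id = it$item_id, text = it$text, origin = it$origin)
            })
          )
        })
      )
    })
  )
  tryCatch(
    yaml::write_yaml(doc, path),
    error = function(e) abort_io(paste0("cannot write ", path, ": ", conditionMessage(e)))
  )
  invisible(path)
}
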