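#' Decisions and decision ledgers
#'
#' The panel's consensus meeting and the final evaluation override the
#' automatic triage — items are reworded and promoted, selected items
#' dropped, new questions added — so human decisions are first-class input
#' data, not something inferred from verdicts. A ledger is an ordered list
#' of decisions for one stage; applying it to a questionnaire version yields
#' the next version plus an auditable change summary.
#'
#' Actions: `KEEP` retains the target; `DROP` removes it; `PROMOTE` rescues
#' an item the triage put up for discussion or rejected (promoting an
#' already-selected item is an error); `ADD` introduces a new question (its
#' payload); `MODIFY` rewords the target's text and never affects counts.
#' A target may be an item id or a question id — a question-level decision
#' applies to all of the question's items.
#'
#' @param target Item or question id (`NA` for `ADD`).
#' @param action One of `"KEEP"`, `"DROP"`, `"PROMOTE"`, `"ADD"`,
#'   `"MODIFY"`.
#' @param rationale Free-text reason recorded in the audit trail.
#' @param payload For `ADD`: a list describing the new question
#'   (`part_id`, `question_id`, `text`, `response_format`, optional `items`
#'   list). For `MODIFY`: a list with the new `text`.
#' @return [decision()] returns a plain list; [decision_ledger()] a
#'   validated `decision_ledger` object.
#' @export
decision <- function(target, action, rationale = "", payload = NULL) {
  action <- match.arg(action, c("KEEP", "DROP", "PROMOTE", "ADD", "MODIFY"))
  if (action == "ADD") {
    if (is.null(payload) || is.null(payload$question_id) || is.null(payload$part_id)) {
      abort_validation("ADD decision needs a payload with question_id and part_id")
    }
  } else if (is.na(target) || !nzchar(target)) {
    abort_validation(paste0(action, " decision needs a target id"))
  }
  list(
    target = if (action == "ADD") NA_character_ else as.character(target),
    action = action, rationale = as.character(rationale), payload = payload
  )
}

#' @rdname decision
#' @param decisions List of [decision()]s.
#' @param stage One of `"questionnaire_round"`, `"consensus_round"`,
#'   `"final_evaluation"`.
#' @export
decision_ledger <- function(decisions, stage) {
  stage <- match.arg(stage, c("questionnaire_round", "consensus_round", "final_evaluation"))
  targets <- vapply(decisions, `[[`, character(1), "target")
  targets <- targets[!is.na(targets)]
  if (anyDuplicated(targets)) {
    abort_validation(paste0(
      "more than one decision for target '", targets[duplicated(targets)][1], "'"
    ))
  }
  structure(list(stage = stage, decisions = decisions), class = "decision_ledger")
}

#' @export
print.decision_ledger <- function(x, ...) {
  acts <- vapply(x$decisions, `[[`, character(1), "action")
  cat("<decision_ledger '", x$stage, "'> ", length(x$decisions), " decisions (",
      paste(names(table(acts)), table(acts), sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read a decision ledger from YAML
#'
#' The document holds a `stage` and a `decisions` list of
#' `{target, action, rationale}` entries; `ADD` entries carry a
#' `new_question` payload, `MODIFY` entries a `text`.
#'
#' @param path Ledger YAML path.
#' @return A validated [decision_ledger()].
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$stage)) abort_parse(paste0("ledger ", path, " has no 'stage'"))
  decisions <- lapply(doc$decisions, function(d) {
    payload <- d$new_question %||% (if (!is.null(d$text)) list(text = d$text) else NULL)
    decision(d$target %||% NA_character_, d$action, d$rationale %||% "", payload)
  })
  decision_ledger(decisions, doc$stage)
}

#' Apply a decision ledger to a questionnaire version
#'
#' Produces the next questionnaire version and a change summary. The default
#' fate of an item not named in the ledger follows the triage verdicts when
#' they are given: SELECTED items are kept, everything else is dropped
#' unless explicitly promoted or kept. Without verdicts every item defaults
#' to kept, so an empty ledger leaves the version unchanged. A question
#' whose items all disappear is removed from the version.
#'
#' @param version The incoming `questionnaire_version`.
#' @param ledger A [decision_ledger()].
#' @param verdicts Optional verdict tibble from [triage_round()]
#'   (`$verdicts`), used for default fates and for validating `PROMOTE`.
#' @return A list: `version` (the new `questionnaire_version`) and `summary`
#'   (one-row tibble: `stage`, `items_in`, `kept`, `dropped`, `promoted`,
#'   `added`, `modified`, `items_out`, `questions_in`, `questions_out`).
#' @export
apply_ledger <- function(version, ledger, verdicts = NULL) {
  tab <- item_table(version)
  known_questions <- unique(tab$question_id)
  known_items <- tab$item_id

  status_of_item <- NULL
  if (!is.null(verdicts)) {
    status_of_item <- setNames(verdicts$status, verdicts$item_id)
  }

  # resolve each decision to the item level
  fate <- rep(NA_character_, nrow(tab)) # KEEP / DROP / PROMOTE
  names(fate) <- tab$item_id
  new_text <- setNames(rep(NA_character_, nrow(tab)), tab$item_id)
  question_new_text <- character()
  additions <- list()

  for (d in ledger$decisions) {
    if (d$action == "ADD") {
      additions[[length(additions) + 1L]] <- d$payload
      next
    }
    if (d$target %in% known_items) {
      ids <- d$target
    } else if (d$target %in% known_questions) {
      ids <- tab$item_id[tab$question_id == d$target]
    } else {
      abort_validation(paste0("decision targets unknown id '", d$target, "'"))
    }
    if (d$action == "MODIFY") {
      if (is.null(d$payload$text)) abort_validation("MODIFY decision needs a new text")
      if (d$target %in% known_questions) {
        question_new_text[d$target] <- d$payload$text
      } else {
        new_text[ids] <- d$payload$text
      }
      next
    }
    if (d$action == "PROMOTE") {
      if (is.null(status_of_item)) {
        abort_validation("PROMOTE requires verdicts for the incoming version")
      }
      st <- status_of_item[ids]
      if (any(!is.na(st) & st == "SELECTED")) {
        abort_validation(paste0(
          "PROMOTE of already-SELECTED item '", ids[!is.na(st) & st == "SELECTED"][1], "'"
        ))
      }
    }
    fate[ids] <- d$action
  }

  # default fates for untouched items
  default_fate <- function(item_id) {
    if (is.null(status_of_item)) return("KEEP")
    st <- status_of_item[item_id]
    if (!is.na(st) && st == "SELECTED") "KEEP" else "DROP"
  }
  for (id in tab$item_id) {
    if (is.na(fate[id])) fate[id] <- default_fate(id)
  }

  # rebuild the version part by part
  new_parts <- list()
  for (part in version$parts) {
    new_questions <- list()
    for (qq in part$questions) {
      kept_items <- list()
      for (it in qq$items) {
        if (fate[it$item_id] %in% c("KEEP", "PROMOTE")) {
          if (!is.na(new_text[it$item_id])) it$text <- new_text[[it$item_id]]
          kept_items[[length(kept_items) + 1L]] <- it
        }
      }
      if (length(kept_items) > 0L) {
        qq$items <- kept_items
        if (qq$question_id %in% names(question_new_text)) {
          qq$text <- question_new_text[[qq$question_id]]
        }
        new_questions[[length(new_questions) + 1L]] <- qq
      }
    }
    # keep the part shell even when empty: an ADD may repopulate it
    part$questions <- new_questions
    new_parts[[length(new_parts) + 1L]] <- part
  }

  n_added_items <- 0L
  for (payload in additions) {
    items <- if (is.null(payload$items)) NULL else lapply(payload$items, function(it) {
      new_item(it$item_id, it$text %||% it$item_id, it$origin %||% "panel_added")
    })
    qq <- new_question(
      payload$question_id, payload$text %||% payload$question_id,
      payload$response_format %||% "likert_agreement", items
    )
    n_added_items <- n_added_items + length(qq$items)
    idx <- which(vapply(new_parts, `[[`, character(1), "part_id") == payload$part_id)
    if (length(idx) != 1L) {
      abort_validation(paste0("ADD targets unknown part '", payload$part_id, "'"))
    }
    new_parts[[idx]]$questions <- c(new_parts[[idx]]$questions, list(qq))
  }
  new_parts <- Filter(function(p) length(p$questions) > 0L, new_parts)

  out <- questionnaire_version(
    new_parts,
    version_label = paste0(version$version_label, "+", ledger$stage),
    provenance = ledger$stage
  )
  summary <- tibble(
    stage = ledger$stage,
    items_in = nrow(tab),
    kept = sum(fate == "KEEP"),
    dropped = sum(fate == "DROP"),
    promoted = sum(fate == "PROMOTE"),
    added = n_added_items,
    modified = sum(!is.na(new_text)) + length(question_new_text),
    items_out = n_items(out),
    questions_in = length(known_questions),
    questions_out = n_questions(out)
  )
  list(version = out, summary = summary)
}

#' Audit trail across Delphi stages
#'
#' Replays a chain of questionnaire versions and ledgers and tabulates the
#' per-stage item and question counts, checking the conservation identities
#' `items_out = kept + promoted + added` and
#' `items_in = kept + promoted + dropped` at every stage, and that each
#' replayed version matches the version supplied for that stage.
#'
#' @param versions Ordered list of `questionnaire_version`s, length one more
#'   than `ledgers`.
#' @param ledgers Ordered list of [decision_ledger()]s.
#' @param verdicts Optional list (same length as `ledgers`) of verdict
#'   tibbles, `NULL` entries allowed.
#' @return Tibble with one row per stage (the [apply_ledger()] summaries).
#' @export
audit_trail <- function(versions, ledgers, verdicts = NULL) {
  if (length(versions) != length(ledgers) + 1L) {
    abort_validation("need exactly one more version than ledgers")
  }
  if (is.null(verdicts)) verdicts <- vector("list", length(ledgers))
  if (length(verdicts) != length(ledgers)) {
    abort_validation("verdicts list must match ledgers in length")
  }
  rows <- list()
  for (i in seq_along(ledgers)) {
    res <- apply_ledger(versions[[i]], ledgers[[i]], verdicts[[i]])
    s <- res$summary
    if (s$items_out != s$kept + s$promoted + s$added ||
        s$items_in != s$kept + s$promoted + s$dropped) {
      abort_validation(paste0("conservation violated at stage '", s$stage, "'"))
    }
    got <- sort(item_table(res$version)$item_id)
    want <- sort(item_table(versions[[i + 1L]])$item_id)
    if (!identical(got, want)) {
      abort_validation(paste0(
        "inconsistent chain: replaying stage '", s$stage,
        "' does not reproduce the next version"
      ))
    }
    rows[[i]] <- s
  }
  dplyr::bind_rows(rows)
}
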