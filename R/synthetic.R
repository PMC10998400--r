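#' Item response profiles for synthetic panels
#'
#' A profile is the latent behaviour of one question and its items: a
#' probability distribution over the 1..9 Likert scores that panelists draw
#' their ratings from, and a latent relevance in \[0, 1\] that drives how
#' often panelists put the question in their top-k list. Four stock profiles
#' mirror the outcome classes the triage rules distinguish:
#'
#' * `consensus_high` — at least 90% of the score mass on 7..9; high
#'   relevance. Should be selected.
#' * `polarized` — at least 30% of mass on 1..3 and 30% on 7..9. Should land
#'   up for discussion.
#' * `middling` — mass centred on 4..6; lukewarm relevance.
#' * `irrelevant` — at least 70% of mass on 1..6, concentrated low. Should
#'   not be selected.
#'
#' @param label Profile label.
#' @param score_probs Numeric vector of length 9 summing to 1.
#' @param latent_relevance Real in \[0, 1\].
#' @return An `item_profile` list.
#' @export
item_profile <- function(label, score_probs, latent_relevance) {
  if (length(score_probs) != 9L || abs(sum(score_probs) - 1) > 1e-9 || any(score_probs < 0)) {
    abort_validation("score_probs must be 9 non-negative probabilities summing to 1")
  }
  if (latent_relevance < 0 || latent_relevance > 1) {
    abort_validation("latent_relevance must be in [0, 1]")
  }
  structure(
    list(
      label = as.character(label),
      score_probs = as.numeric(score_probs),
      latent_relevance = as.numeric(latent_relevance)
    ),
    class = "item_profile"
  )
}

#' @rdname item_profile
#' @export
default_profiles <- function() {
  list(
    consensus_high = item_profile(
      "consensus_high",
      c(0.005, 0.005, 0.01, 0.02, 0.02, 0.04, 0.20, 0.35, 0.35), 0.90
    ),
    polarized = item_profile(
      "polarized",
      c(0.15, 0.15, 0.10, 0.05, 0.05, 0.05, 0.10, 0.15, 0.20), 0.50
    ),
    middling = item_profile(
      "middling",
      c(0.02, 0.05, 0.13, 0.20, 0.20, 0.20, 0.12, 0.05, 0.03), 0.30
    ),
    irrelevant = item_profile(
      "irrelevant",
      c(0.25, 0.25, 0.18, 0.12, 0.08, 0.05, 0.04, 0.02, 0.01), 0.05
    )
  )
}

#' Configuration of a synthetic Delphi panel
#'
#' Defaults mirror the scale of the study the package models: a 14-member
#' expert panel rating a 34-question questionnaire whose sub-questions give
#' 57 items, with one panelist dropping out after the first round.
#'
#' @param n_panelists Panel size (at least 2).
#' @param n_questions Number of questions.
#' @param seed Integer seed; mandatory, for exact reproducibility.
#' @param ne_rate Probability a panelist answers "not evaluable" for an
#'   item.
#' @param dropout_after_round1 Number of panelists leaving after round 1.
#' @param profile_weights Named probabilities used to assign a stock profile
#'   to each question when no explicit assignment is given.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_panelists = 14L, n_questions = 34L, seed,
                         ne_rate = 0.02, dropout_after_round1 = 1L,
                         profile_weights = c(
                           consensus_high = 0.60, polarized = 0.20,
                           middling = 0.12, irrelevant = 0.08
                         )) {
  if (missing(seed)) abort_validation("seed is mandatory for reproducibility")
  if (n_panelists < 2L) abort_validation("n_panelists must be >= 2")
  if (n_questions < 1L) abort_validation("n_questions must be >= 1")
  if (ne_rate < 0 || ne_rate >= 1) abort_validation("ne_rate must be in [0, 1)")
  if (dropout_after_round1 < 0L || dropout_after_round1 >= n_panelists) {
    abort_validation("dropout_after_round1 must leave at least one panelist")
  }
  if (abs(sum(profile_weights) - 1) > 1e-9) {
    abort_validation("profile_weights must sum to 1")
  }
  structure(
    list(
      n_panelists = as.integer(n_panelists),
      n_questions = as.integer(n_questions),
      seed = as.integer(seed),
      ne_rate = ne_rate,
      dropout_after_round1 = as.integer(dropout_after_round1),
      profile_weights = profile_weights
    ),
    class = "panel_config"
  )
}

#' The study-scale questionnaire skeleton
#'
#' Builds the default questionnaire structure the generator rates: five
#' parts, `n_questions` questions, and — at the default 34 questions — the
#' sub-question layout that yields 57 items (questions 12, 14, 21, 23, 24
#' and 27 carry 3, 5, 2, 8, 2 and 9 sub-items). For other sizes, roughly a
#' fifth of the questions get 2-4 sub-items, drawn deterministically from
#' the question index.
#'
#' @param n_questions Number of questions.
#' @return A `questionnaire_version`.
#' @export
study_questionnaire <- function(n_questions = 34L) {
  multi <- if (n_questions == 34L) {
    c("12" = 3L, "14" = 5L, "21" = 2L, "23" = 8L, "24" = 2L, "27" = 9L)
  } else {
    idx <- seq_len(n_questions)
    chosen <- idx[idx %% 5L == 0L]
    setNames(2L + (chosen %% 3L), as.character(chosen))
  }
  make_question <- function(qid) {
    k <- if (as.character(qid) %in% names(multi)) multi[[as.character(qid)]] else 1L
    items <- if (k == 1L) NULL else lapply(seq_len(k), function(j) {
      new_item(paste0(qid, ".", j), paste0("Sub-item ", j, " of question ", qid),
               origin = "cp_fit")
    })
    new_question(as.character(qid), paste0("Question ", qid), "likert_agreement", items)
  }
  # five parts as in the study: caregiver/practice data then four topic blocks
  bounds <- unique(pmin(n_questions, ceiling(n_questions * c(0.32, 0.42, 0.59, 0.76, 1))))
  starts <- c(1L, utils::head(bounds, -1) + 1L)
  part_ids <- c("part1", "part2_1", "part2_2", "part2_3", "part2_4")[seq_along(bounds)]
  parts <- list()
  for (i in seq_along(bounds)) {
    qids <- seq(starts[i], bounds[i])
    if (length(qids) == 0L) next
    depth <- if (i == 2L) 3L else 5L
    parts[[length(parts) + 1L]] <- new_part(
      part_ids[i], paste0("Part ", sub("part", "", part_ids[i])),
      lapply(qids, make_question), ranking_depth = depth
    )
  }
  questionnaire_version(parts, version_label = "draft", provenance = "drafting")
}

#' Generate a synthetic Delphi panel round
#'
#' Draws a complete questionnaire round: per-question profiles, independent
#' per-(panelist, item) Likert ratings from the profile's score
#' distribution (with an `ne_rate` chance of "not evaluable"), and
#' per-panelist top-k rankings per part drawn by Plackett-Luce-style
#' sequential sampling with weights proportional to latent relevance times
#' a lognormal panelist-specific perturbation. The same seed always yields
#' byte-identical outputs.
#'
#' @param config A [panel_config()].
#' @param profile_assignment Optional named character vector mapping
#'   question ids to profile labels; unassigned questions are drawn from
#'   `config$profile_weights`.
#' @param profiles Named list of [item_profile()]s.
#' @return A list: `questionnaire`, `ratings` ([rating_matrix()]),
#'   `rankings` ([ranking_set()]), `truth` (tibble `question_id`,
#'   `item_id`, `profile`, `latent_relevance`), `panel`,
#'   `panel_after_dropout`.
#' @export
generate_panel <- function(config, profile_assignment = NULL,
                           profiles = default_profiles()) {
  if (!inherits(config, "panel_config")) abort_validation("config must be a panel_config")
  qv <- study_questionnaire(config$n_questions)
  tab <- item_table(qv)
  qids <- unique(tab$question_id)
  panel <- sprintf("p%02d", seq_len(config$n_panelists))

  withr::with_seed(config$seed, {
    assigned <- setNames(rep(NA_character_, length(qids)), qids)
    if (!is.null(profile_assignment)) {
      unknown <- setdiff(names(profile_assignment), qids)
      if (length(unknown)) {
        abort_validation(paste0("profile assigned to unknown question '", unknown[1], "'"))
      }
      bad <- setdiff(profile_assignment, names(profiles))
      if (length(bad)) abort_validation(paste0("unknown profile label '", bad[1], "'"))
      assigned[names(profile_assignment)] <- profile_assignment
    }
    todo <- is.na(assigned)
    assigned[todo] <- sample(
      names(config$profile_weights), sum(todo),
      replace = TRUE, prob = config$profile_weights
    )

    # ratings: independent per (panelist, item) given the question's profile
    rating_rows <- vector("list", length(panel))
    for (p in seq_along(panel)) {
      prof <- assigned[tab$question_id]
      ne <- stats::runif(nrow(tab)) < config$ne_rate
      score <- integer(nrow(tab))
      for (i in seq_len(nrow(tab))) {
        score[i] <- sample.int(9L, 1L, prob = profiles[[prof[i]]]$score_probs)
      }
      rating_rows[[p]] <- tibble(
        panelist_id = panel[p],
        item_id = tab$item_id,
        score = ifelse(ne, NA_integer_, score),
        not_evaluable = ne,
        comment = ""
      )
    }
    ratings <- rating_matrix(
      dplyr::bind_rows(rating_rows), panel, round_label = "questionnaire_round"
    )

    # rankings: Plackett-Luce sequential draws weighted by latent relevance
    relev <- vapply(assigned, function(l) profiles[[l]]$latent_relevance, numeric(1))
    entries <- list()
    for (p in panel) {
      for (part in qv$parts) {
        part_qids <- vapply(part$questions, `[[`, character(1), "question_id")
        k <- min(part$ranking_depth, length(part_qids))
        w <- pmax(relev[part_qids], 0.01) * exp(stats::rnorm(length(part_qids), 0, 0.4))
        picked <- sample(part_qids, k, replace = FALSE, prob = w)
        entries[[length(entries) + 1L]] <- tibble(
          panelist_id = p, part_id = part$part_id, ranked_questions = list(picked)
        )
      }
    }
    rankings <- ranking_set(
      dplyr::bind_rows(entries), qv, round_label = "questionnaire_round"
    )

    dropouts <- if (config$dropout_after_round1 > 0L) {
      sample(panel, config$dropout_after_round1)
    } else {
      character()
    }
  })

  truth <- tibble(
    question_id = tab$question_id,
    item_id = tab$item_id,
    profile = unname(assigned[tab$question_id]),
    latent_relevance = vapply(
      assigned[tab$question_id], function(l) profiles[[l]]$latent_relevance, numeric(1)
    )
  )
  list(
    questionnaire = qv, ratings = ratings, rankings = rankings, truth = truth,
    panel = panel, panel_after_dropout = setdiff(panel, dropouts)
  )
}

#' Profile-recovery experiment for the triage rules
#'
#' Generates, scores, and triages `n_reps` synthetic panels and tabulates
#' how often each true item profile lands in each triage status — a
#' confusion table validating that the selection rules recover the intended
#' classes: consensus-high items should be dominated by SELECTED, irrelevant
#' items by NOT_SELECTED, polarized items by UP_FOR_DISCUSSION.
#'
#' @param config A [panel_config()]; replicate r uses seed
#'   `config$seed + r - 1`.
#' @param n_reps Number of replicates (>= 1).
#' @param profile_assignment Passed to [generate_panel()].
#' @param thresholds A [delphi_thresholds()].
#' @return Tibble with one row per profile: `profile`, `n` (item-replicate
#'   count), and the proportions `SELECTED`, `UP_FOR_DISCUSSION`,
#'   `NOT_SELECTED`, `UNSCORABLE`, which sum to 1 per row.
#' @export
recovery_experiment <- function(config, n_reps, profile_assignment = NULL,
                                thresholds = delphi_thresholds()) {
  if (n_reps < 1L) abort_validation("n_reps must be >= 1")
  tallies <- list()
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- generate_panel(cfg, profile_assignment)
    scores <- score_round(sim$ratings, sim$rankings, sim$questionnaire,
                          panel_size = cfg$n_panelists)
    tri <- triage_round(scores, thresholds)
    status <- setNames(tri$verdicts$status, tri$verdicts$item_id)
    st <- unname(status[sim$truth$item_id])
    st[is.na(st)] <- "UNSCORABLE"
    tallies[[r]] <- tibble(profile = sim$truth$profile, status = st)
  }
  long <- dplyr::count(dplyr::bind_rows(tallies), .data$profile, .data$status)
  out <- list()
  for (prof in unique(long$profile)) {
    sub <- long[long$profile == prof, ]
    n <- sum(sub$n)
    get <- function(s) (sub$n[sub$status == s] %0% 0L) / n
    out[[prof]] <- tibble(
      profile = prof, n = n,
      SELECTED = get("SELECTED"),
      UP_FOR_DISCUSSION = get("UP_FOR_DISCUSSION"),
      NOT_SELECTED = get("NOT_SELECTED"),
      UNSCORABLE = get("UNSCORABLE")
    )
  }
  dplyr::bind_rows(out)
}

`%0%` <- function(x, default) if (length(x) == 0L) default else x
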