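fixture_chain <- function() {
  v1 <- read_questionnaire(study_fixture("initial_questionnaire_synthetic.yaml"))
  verdicts <- utils::read.csv(study_fixture("round1_verdicts_synthetic.csv"),
                              colClasses = "character")
  led2 <- read_ledger(study_fixture("ledger_consensus_synthetic.yaml"))
  led3 <- read_ledger(study_fixture("ledger_final_synthetic.yaml"))
  list(v1 = v1, verdicts = tibble::as_tibble(verdicts), led2 = led2, led3 = led3)
}

test_that("the consensus-round ledger turns 57 triaged items into 44 items over 31 questions", {
  ch <- fixture_chain()
  expect_equal(n_items(ch$v1), 57L)
  expect_equal(n_questions(ch$v1), 34L)
  expect_identical(
    as.integer(table(ch$verdicts$status)[c("SELECTED", "UP_FOR_DISCUSSION", "NOT_SELECTED")]),
    c(34L, 16L, 7L)
  )
  res <- apply_ledger(ch$v1, ch$led2, ch$verdicts)
  expect_equal(n_items(res$version), 44L)
  expect_equal(n_questions(res$version), 31L)
  expect_equal(res$summary$kept, 31L)
  expect_equal(res$summary$promoted, 12L)
  expect_equal(res$summary$added, 1L)
  expect_equal(res$summary$dropped, 14L)
})

test_that("the final-evaluation ledger drops one question, leaving 30 questions and 43 items", {
  ch <- fixture_chain()
  v2 <- apply_ledger(ch$v1, ch$led2, ch$verdicts)$version
  res <- apply_ledger(v2, ch$led3)
  expect_equal(n_questions(res$version), 30L)
  expect_equal(n_items(res$version), 43L)
  # same shape as the published final instrument fixture
  fq <- read_questionnaire(study_fixture("final_questionnaire.yaml"))
  expect_equal(n_questions(fq), 30L)
  expect_equal(n_items(fq), 43L)
})

test_that("an empty ledger leaves the version unchanged", {
  qv <- mini_questionnaire()
  led <- decision_ledger(list(), "consensus_round")
  res <- apply_ledger(qv, led)
  expect_equal(item_table(res$version)$item_id, item_table(qv)$item_id)
  expect_equal(res$summary$kept, n_items(qv))
  expect_equal(res$summary$dropped, 0L)
  expect_equal(res$summary$promoted, 0L)
  expect_equal(res$summary$added, 0L)
})

test_that("ledger validation rejects unknown targets, double decisions, and bad promotions", {
  qv <- mini_questionnaire()
  verd <- tibble::tibble(
    item_id = item_table(qv)$item_id,
    status = c("SELECTED", "UP_FOR_DISCUSSION", "UP_FOR_DISCUSSION", "NOT_SELECTED", "SELECTED")
  )
  expect_error(
    apply_ledger(qv, decision_ledger(list(decision("ghost", "DROP")), "consensus_round")),
    class = "randelphi_validation_error"
  )
  expect_error(
    decision_ledger(list(decision("q1", "DROP"), decision("q1", "KEEP")), "consensus_round"),
    class = "randelphi_validation_error"
  )
  # PROMOTE of an already-selected item
  expect_error(
    apply_ledger(qv, decision_ledger(list(decision("q1", "PROMOTE")), "consensus_round"), verd),
    class = "randelphi_validation_error"
  )
  # PROMOTE with no verdicts at all
  expect_error(
    apply_ledger(qv, decision_ledger(list(decision("q2.1", "PROMOTE")), "consensus_round")),
    class = "randelphi_validation_error"
  )
  # ADD into a part that does not exist
  bad_add <- decision(NA, "ADD", payload = list(part_id = "nope", question_id = "z9"))
  expect_error(
    apply_ledger(qv, decision_ledger(list(bad_add), "consensus_round")),
    class = "randelphi_validation_error"
  )
})

test_that("MODIFY rewords without changing counts; question decisions cascade to items", {
  qv <- mini_questionnaire()
  led <- decision_ledger(list(
    decision("q2.1", "MODIFY", payload = list(text = "reworded sub one")),
    decision("q3", "MODIFY", payload = list(text = "reworded question"))
  ), "consensus_round")
  res <- apply_ledger(qv, led)
  expect_equal(n_items(res$version), n_items(qv))
  tab <- item_table(res$version)
  expect_identical(tab$item_text[tab$item_id == "q2.1"], "reworded sub one")
  expect_equal(res$summary$modified, 2L)

  # dropping a whole question removes all its items and the question itself
  res2 <- apply_ledger(qv, decision_ledger(list(decision("q2", "DROP")), "consensus_round"))
  expect_equal(n_items(res2$version), n_items(qv) - 2L)
  expect_false("q2" %in% question_table(res2$version)$question_id)
})

test_that("conservation holds for randomly generated ledgers and no question is orphaned", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      sim <- generate_panel(panel_config(seed = 500L + rep, n_questions = 12L))
      qv <- sim$questionnaire
      tab <- item_table(qv)
      status <- sample(c("SELECTED", "UP_FOR_DISCUSSION", "NOT_SELECTED"),
                       nrow(tab), replace = TRUE)
      verd <- tibble::tibble(item_id = tab$item_id, status = status)
      decisions <- list()
      for (i in seq_len(nrow(tab))) {
        if (runif(1) > 0.4) next
        st <- status[i]
        action <- if (st == "SELECTED") {
          sample(c("KEEP", "DROP"), 1)
        } else {
          sample(c("PROMOTE", "DROP"), 1)
        }
        decisions[[length(decisions) + 1L]] <- decision(tab$item_id[i], action)
      }
      if (runif(1) < 0.5) {
        decisions[[length(decisions) + 1L]] <- decision(
          NA, "ADD",
          payload = list(part_id = qv$parts[[1]]$part_id, question_id = "new_q",
                         text = "added question")
        )
      }
      led <- decision_ledger(decisions, "consensus_round")
      res <- apply_ledger(qv, led, verd)
      s <- res$summary
      expect_equal(s$items_out, s$kept + s$promoted + s$added)
      expect_equal(s$items_in, s$kept + s$promoted + s$dropped)
      expect_true(all(question_table(res$version)$n_items >= 1))
    }
  })
})

test_that("audit_trail replays the study chain and rejects inconsistent ones", {
  ch <- fixture_chain()
  v2 <- apply_ledger(ch$v1, ch$led2, ch$verdicts)$version
  v3 <- apply_ledger(v2, ch$led3)$version
  trail <- audit_trail(list(ch$v1, v2, v3), list(ch$led2, ch$led3),
                       list(ch$verdicts, NULL))
  expect_equal(nrow(trail), 2L)
  expect_equal(trail$items_in, c(57L, 44L))
  expect_equal(trail$items_out, c(44L, 43L))
  expect_equal(trail$questions_out, c(31L, 30L))
  # single-stage chain gives a one-row report
  one <- audit_trail(list(v2, v3), list(ch$led3))
  expect_equal(nrow(one), 1L)
  # swapping the final version in breaks the chain
  expect_error(
    audit_trail(list(ch$v1, v2, v2), list(ch$led2, ch$led3), list(ch$verdicts, NULL)),
    class = "randelphi_validation_error"
  )
  expect_error(audit_trail(list(v2), list(ch$led3)), class = "randelphi_validation_error")
})
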