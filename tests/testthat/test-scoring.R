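# Independent straight-line oracles, kept free of the package's own helpers.
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}
oracle_tertiles <- function(x) {
  low <- 0; mid <- 0; high <- 0
  for (s in x) {
    if (s <= 3) low <- low + 1 else if (s <= 6) mid <- mid + 1 else high <- high + 1
  }
  c(low, mid, high) / length(x)
}

test_that("median_score matches hand-worked and oracle values", {
  expect_equal(median_score(c(7, 7, 8)), 7)
  expect_equal(median_score(c(6, 8)), 7)
  # 14 scores: nine 8s and five 3s; 7th and 8th order statistics are both 8
  expect_equal(median_score(c(rep(8, 9), rep(3, 5))), 8)
  expect_error(median_score(integer()), class = "randelphi_empty_scores_error")
  withr::with_seed(21, {
    for (i in 1:200) {
      x <- sample.int(9L, sample(1:30, 1), replace = TRUE)
      expect_equal(median_score(x), oracle_median(x))
    }
  })
})

test_that("raising any single score never lowers the median", {
  withr::with_seed(22, {
    for (i in 1:200) {
      x <- sample.int(9L, sample(1:15, 1), replace = TRUE)
      j <- sample(seq_along(x), 1)
      y <- x
      y[j] <- min(9L, y[j] + sample.int(3L, 1))
      expect_gte(median_score(y), median_score(x))
    }
  })
})

test_that("tertile fractions use the 1-3 / 4-6 / 7-9 bins and sum to one", {
  expect_equal(unname(tertile_fractions(c(9, 9, 9, 9))), c(0, 0, 1))
  expect_equal(unname(tertile_fractions(c(1, 2, 8, 9))), c(0.5, 0, 0.5))
  expect_error(tertile_fractions(numeric()), class = "randelphi_empty_scores_error")
  withr::with_seed(23, {
    for (i in 1:1000) {
      x <- sample.int(9L, sample(1:50, 1), replace = TRUE)
      f <- tertile_fractions(x)
      expect_equal(sum(f), 1, tolerance = 1e-9)
      expect_equal(unname(f), oracle_tertiles(x))
    }
  })
})

test_that("prioritization percentage follows the points model", {
  qv <- mini_questionnaire()
  # a dedicated top-5 questionnaire for the worked example
  q_many <- lapply(1:6, function(i) new_question(paste0("m", i)))
  part5 <- new_part("p5", "p5", q_many, ranking_depth = 5)
  qv5 <- questionnaire_version(list(part5))
  panel14 <- sprintf("p%02d", 1:14)
  entries <- dplyr::bind_rows(lapply(panel14[1:10], function(p) {
    tibble::tibble(panelist_id = p, part_id = "p5", ranked_questions = list("m1"))
  }))
  rs <- ranking_set(entries, qv5)
  # 10 first places x 5 points over 14 x 5 possible = 50/70
  expect_equal(prioritization_pct(rs, "m1", part5, 14), 100 * 50 / 70)
  expect_equal(round(prioritization_pct(rs, "m1", part5, 14), 1), 71.4)
  # nobody ranked m2
  expect_equal(prioritization_pct(rs, "m2", part5, 14), 0)
  # everyone first: 100
  all_first <- ranking_set(
    dplyr::bind_rows(lapply(panel14, function(p) {
      tibble::tibble(panelist_id = p, part_id = "p5", ranked_questions = list("m1"))
    })), qv5
  )
  expect_equal(prioritization_pct(all_first, "m1", part5, 14), 100)
  # top-3: a ranks t1 first (3 pts), b second (2 pts), c third (1 pt),
  # panel of 10 => (3+2+1)/(10*3) = 20%
  q3p <- lapply(1:3, function(i) new_question(paste0("t", i)))
  partT <- new_part("pt", "pt", q3p, ranking_depth = 3)
  qvT <- questionnaire_version(list(partT))
  rsT <- ranking_set(
    tibble::tibble(
      panelist_id = c("a", "b", "c"), part_id = "pt",
      ranked_questions = list("t1", c("t2", "t1"), c("t2", "t3", "t1"))
    ), qvT
  )
  expect_equal(prioritization_pct(rsT, "t1", partT, 10), 20.0)
  expect_error(prioritization_pct(rsT, "zz", partT, 10), class = "randelphi_domain_error")
  expect_error(prioritization_pct(rsT, "t1", partT, 0), class = "randelphi_domain_error")
})

test_that("prioritization is 0 iff no points and 100 iff unanimous first place", {
  q_many <- lapply(1:5, function(i) new_question(paste0("m", i)))
  part <- new_part("p", "p", q_many, ranking_depth = 5)
  qv <- questionnaire_version(list(part))
  panel <- sprintf("p%02d", 1:8)
  withr::with_seed(24, {
    for (i in 1:50) {
      entries <- dplyr::bind_rows(lapply(panel, function(p) {
        k <- sample(0:5, 1)
        tibble::tibble(
          panelist_id = p, part_id = "p",
          ranked_questions = list(sample(paste0("m", 1:5), k))
        )
      }))
      rs <- ranking_set(entries, qv)
      for (q in paste0("m", 1:5)) {
        pct <- prioritization_pct(rs, q, part, length(panel))
        expect_gte(pct, 0)
        expect_lte(pct, 100)
        ranked_anywhere <- any(vapply(entries$ranked_questions, function(l) q %in% l, logical(1)))
        expect_identical(pct > 0, ranked_anywhere)
        all_first <- all(vapply(entries$ranked_questions, function(l) identical(l[1], q), logical(1)))
        expect_identical(pct == 100, all_first)
      }
    }
  })
})

test_that("score_item combines the statistics and inherits the question's top percentage", {
  qv <- mini_questionnaire()
  panel <- sprintf("p%02d", 1:14)
  rm <- full_ratings(qv, panel, function(p, i) 9L)
  rs <- uniform_rankings(qv, panel, list(part1 = c("q1", "q2"), part2 = c("q3", "q4")))
  part1 <- qv$parts[[1]]
  q2 <- part1$questions[[2]]
  s <- score_item(rm, rs, "q2.1", q2, part1, panel_size = 14)
  expect_equal(s$median, 9)
  expect_equal(s$frac_high, 1)
  expect_equal(s$n_evaluable, 14L)
  # q2 ranked second in a top-3 by all 14: 14*2 / (14*3)
  expect_equal(s$top_pct, 100 * 28 / 42)
  # sub-items inherit the parent question's top percentage
  s2 <- score_item(rm, rs, "q2.2", q2, part1, panel_size = 14)
  expect_equal(s2$top_pct, s$top_pct)

  # one NE answer drops n_evaluable to 13
  rm2 <- rm
  idx <- which(rm2$ratings$panelist_id == "p01" & rm2$ratings$item_id == "q1")
  rm2$ratings$score[idx] <- NA_integer_
  rm2$ratings$not_evaluable[idx] <- TRUE
  q1 <- part1$questions[[1]]
  s3 <- score_item(rm2, rs, "q1", q1, part1, panel_size = 14)
  expect_equal(s3$n_evaluable, 13L)

  # zero evaluable ratings: flagged UNSCORABLE with a warning, not scored
  rm3 <- rm
  hit <- rm3$ratings$item_id == "q1"
  rm3$ratings$score[hit] <- NA_integer_
  rm3$ratings$not_evaluable[hit] <- TRUE
  expect_warning(
    s4 <- score_item(rm3, rs, "q1", q1, part1, panel_size = 14),
    "UNSCORABLE"
  )
  expect_true(s4$unscorable)
  expect_true(is.na(s4$median))
})

test_that("score_round agrees with a brute-force recomputation on a full synthetic panel", {
  sim <- generate_panel(panel_config(seed = 77L))
  qv <- sim$questionnaire
  scores <- score_round(sim$ratings, sim$rankings, qv, panel_size = 14)
  expect_equal(nrow(scores), 57L)
  tab <- item_table(qv)
  rr <- sim$ratings$ratings
  for (i in seq_len(nrow(tab))) {
    iid <- tab$item_id[i]
    got <- scores[scores$item_id == iid, ]
    x <- rr$score[rr$item_id == iid]
    x <- x[!is.na(x)]
    expect_equal(got$n_evaluable, length(x))
    if (length(x) > 0) {
      expect_equal(got$median, oracle_median(x), tolerance = 1e-9)
      tert <- oracle_tertiles(x)
      expect_equal(c(got$frac_low, got$frac_mid, got$frac_high), tert, tolerance = 1e-9)
    }
    # brute-force top percentage of the parent question
    part <- NULL
    for (p in qv$parts) if (p$part_id == tab$part_id[i]) part <- p
    k <- part$ranking_depth
    pts <- 0
    ent <- sim$rankings$entries
    for (j in seq_len(nrow(ent))) {
      if (ent$part_id[j] != part$part_id) next
      pos <- which(ent$ranked_questions[[j]] == tab$question_id[i])
      if (length(pos) == 1) pts <- pts + k - pos + 1
    }
    expect_equal(got$top_pct, 100 * pts / (14 * k), tolerance = 1e-9)
  }
})
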