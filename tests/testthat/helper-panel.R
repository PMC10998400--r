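# Shared builders for small in-code fixtures.

mini_questionnaire <- function() {
  q1 <- new_question("q1", "First question", "likert_agreement")
  q2 <- new_question("q2", "Second question", "likert_agreement",
                     items = list(new_item("q2.1", "sub one"), new_item("q2.2", "sub two")))
  q3 <- new_question("q3", "Third question", "satisfaction")
  q4 <- new_question("q4", "Fourth question", "categorical")
  p1 <- new_part("part1", "Part one", list(q1, q2), ranking_depth = 3)
  p2 <- new_part("part2", "Part two", list(q3, q4), ranking_depth = 3)
  questionnaire_version(list(p1, p2), version_label = "test")
}

# a rating matrix with every panelist rating every item of qv
full_ratings <- function(qv, panel, score_fun) {
  tab <- item_table(qv)
  rows <- list()
  for (p in panel) {
    for (i in seq_len(nrow(tab))) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        panelist_id = p, item_id = tab$item_id[i],
        score = as.integer(score_fun(p, tab$item_id[i])),
        not_evaluable = FALSE, comment = ""
      )
    }
  }
  rating_matrix(dplyr::bind_rows(rows), panel)
}

# random valid rating matrix over qv, with NE and missing pairs
random_rating_matrix <- function(qv, panel, ne_prob = 0.1, miss_prob = 0.1) {
  tab <- item_table(qv)
  rows <- list()
  for (p in panel) {
    for (i in seq_len(nrow(tab))) {
      u <- stats::runif(1)
      if (u < miss_prob) next
      ne <- u < miss_prob + ne_prob
      rows[[length(rows) + 1L]] <- tibble::tibble(
        panelist_id = p, item_id = tab$item_id[i],
        score = if (ne) NA_integer_ else sample.int(9L, 1L),
        not_evaluable = ne,
        comment = if (stats::runif(1) < 0.2) paste0("note ", i) else ""
      )
    }
  }
  rating_matrix(dplyr::bind_rows(rows), panel)
}

# rankings where every panelist files the same list per part
uniform_rankings <- function(qv, panel, lists) {
  entries <- list()
  for (p in panel) {
    for (pid in names(lists)) {
      entries[[length(entries) + 1L]] <- tibble::tibble(
        panelist_id = p, part_id = pid, ranked_questions = list(lists[[pid]])
      )
    }
  }
  ranking_set(dplyr::bind_rows(entries), qv)
}

write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(paste0(paste(lines, collapse = "\n"), "\n"))), con)
  path
}
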