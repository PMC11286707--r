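test_that("item statistics match hand-worked values and the quantile oracle", {
  unanimous <- item_stats(rep(5, 22))
  expect_equal(unanimous$agreement_pct, 100)
  expect_equal(unanimous$median, 5)
  expect_equal(unanimous$p25, 5)
  expect_equal(unanimous$iqr, 0)

  v <- c(2, 3, 4, 4, 4, 5, 5)  # position (7+1)*0.25 = 2 -> second sorted value
  st <- item_stats(v)
  expect_equal(st$agreement_pct, 100 * 5 / 7)
  expect_equal(st$median, 4)
  expect_equal(st$p25, 3)
  expect_equal(st$p75, oracle_quantile(v, 0.75))

  # 17 of 22 agreeing: the "approximately three-quarters" level
  seventeen <- c(rep(5, 9), rep(4, 8), rep(3, 3), rep(2, 2))
  expect_equal(round(item_stats(seventeen)$agreement_pct, 1), 77.3)

  # random vectors against the independent interpolation oracle
  set.seed(3)
  for (rep in 1:25) {
    x <- sample(1:5, sample(3:22, 1), replace = TRUE)
    st <- item_stats(x)
    expect_equal(st$p25, oracle_quantile(x, 0.25))
    expect_equal(st$p75, oracle_quantile(x, 0.75))
    expect_equal(st$median, oracle_median(x))
    expect_equal(st$iqr, st$p75 - st$p25)
    expect_true(st$p25 <= st$median && st$median <= st$p75)
  }
})

test_that("missing responses are excluded from numerator and denominator", {
  with_na <- c(5, 5, 4, NA, NA, 2)
  st <- item_stats(with_na)
  expect_identical(st$n_responses, 4L)
  expect_equal(st$agreement_pct, 75)
  expect_equal(st$p25, oracle_quantile(with_na, 0.25))
  expect_equal(item_stats(c(4, 4, NA)), item_stats(c(4, 4)))
  expect_error(item_stats(c(NA, NA)), "missing")
})

test_that("all-missing items are reported by name at matrix level", {
  m <- likert_matrix(tidyr::expand_grid(
    item_id = c("good", "empty"), panellist_id = c("p1", "p2")
  ) |> dplyr::mutate(response = ifelse(item_id == "good", 4L, NA_integer_)))
  expect_error(delphi_item_stats(m), "empty")
})

test_that("decision clauses fire as stated, with the final-round tightening", {
  d <- decide_items(tibble::tibble(
    item_id = c("incl", "excl", "edge", "mid"),
    median = c(5, 3, 4, 3.5), p25 = c(4.25, 2, 3.8, 3)
  ), final_round = FALSE)
  expect_identical(as.character(d$verdict), c("retain", "exclude", "modify", "modify"))
  expect_match(d$rule_trace[1], "inclusion criterion met")
  expect_match(d$rule_trace[4], "no clause applies")

  df <- decide_items(dplyr::select(d, -"verdict", -"rule_trace"), final_round = TRUE)
  expect_identical(as.character(df$verdict), c("retain", "exclude", "exclude", "exclude"))
  expect_match(df$rule_trace[3], "P25 3.8 < 4")
})

test_that("verdicts match the brute-force oracle over all vectors up to n = 8", {
  for (final in c(FALSE, TRUE)) {
    for (n in 1:8) {
      vecs <- likert_multisets(n)
      stats <- purrr::map_dfr(vecs, item_stats)
      got <- as.character(decide_items(stats, final_round = final)$verdict)
      want <- vapply(vecs, oracle_verdict, character(1), final_round = final)
      expect_identical(got, want)
    }
  }
})

test_that("the P25 gate is one-sidedly stricter than 75% agreement", {
  # enumerate all response vectors up to n = 8: the two readings of the
  # inclusion rule disagree only at the boundary, and always in the same
  # direction (agreement >= 75% but P25 < 4), never the reverse
  disagreements <- 0L
  for (n in 1:8) {
    for (v in likert_multisets(n)) {
      st <- item_stats(v)
      p25_gate <- st$median >= 4 && st$p25 >= 4
      pct_gate <- st$median >= 4 && st$agreement_pct >= 75
      if (p25_gate != pct_gate) {
        disagreements <- disagreements + 1L
        expect_true(pct_gate && !p25_gate)
        expect_gte(st$agreement_pct, 75)
      }
    }
  }
  expect_identical(disagreements, 83L)
  # pinned boundary case: exactly 75% agreement, P25 interpolates below 4
  st <- item_stats(c(3, 4, 4, 4))
  expect_equal(st$agreement_pct, 75)
  expect_equal(st$p25, 3.25)
  expect_identical(as.character(decide_items(st)$verdict), "modify")
})

test_that("raising any single response never demotes a retain verdict", {
  set.seed(7)
  for (rep in 1:40) {
    x <- sample(1:5, sample(4:12, 1), replace = TRUE)
    base <- as.character(decide_items(item_stats(x))$verdict)
    i <- sample(seq_along(x), 1)
    if (x[i] < 5) {
      x[i] <- x[i] + 1L
      up <- as.character(decide_items(item_stats(x))$verdict)
      if (base == "retain") expect_identical(up, "retain")
      rank <- c(exclude = 1L, modify = 2L, retain = 3L)
      expect_gte(rank[[up]], rank[[base]])
    }
  }
})

test_that("rounds partition items and carry forward modify verdicts plus new items", {
  m <- generate_responses(branch_profile("retain", seed = 21), n_items = 4)
  r1 <- run_delphi_round(m, 1, max_rounds = 3, new_items = c("suggested_1"))
  expect_true(all(r1$decisions$verdict == "retain"))
  expect_identical(r1$carried_forward, "suggested_1")

  mixed <- dplyr::bind_rows(
    as_tibble(generate_responses(branch_profile("modify", seed = 22), 2)),
    as_tibble(generate_responses(branch_profile("exclude", seed = 23), 2,
                                 item_prefix = "ex"))
  )
  r2 <- run_delphi_round(mixed, 2, max_rounds = 3)
  d <- r2$decisions
  # conservation: every opened item ends in exactly one bucket
  retained <- d$item_id[d$verdict == "retain"]
  excluded <- d$item_id[d$verdict == "exclude"]
  expect_setequal(unique(mixed$item_id), c(retained, excluded, r2$carried_forward))
  expect_length(intersect(r2$carried_forward, c(retained, excluded)), 0L)

  # re-rating an item already decided in a prior round is an error
  history <- tibble::tibble(item_id = d$item_id,
                            verdict = as.character(d$verdict))
  closed <- c(retained, excluded)
  if (length(closed) > 0L) {
    expect_error(run_delphi_round(mixed, 3, history = history), closed[1L])
  }

  # in the final round nothing is carried forward
  r3 <- run_delphi_round(mixed, 3, max_rounds = 3)
  expect_length(r3$carried_forward, 0L)
  expect_false(any(r3$decisions$verdict == "modify"))

  # feedback: one group record per decided item, responses echoed per panellist
  expect_identical(nrow(r2$feedback$group), nrow(d))
  expect_identical(nrow(r2$feedback$individual), nrow(mixed))
  expect_true(all(c("group_median", "group_p25") %in% names(r2$feedback$individual)))
})

test_that("a three-round synthetic replication ends with 19 retained items", {
  # round 1: 19 eventual keepers (strong consensus) + 6 contested items
  keepers <- generate_responses(branch_profile("retain", seed = 31), 19,
                                item_prefix = "keep")
  contested <- generate_responses(branch_profile("modify", seed = 32), 4,
                                  item_prefix = "mod")
  rejected <- generate_responses(branch_profile("exclude", seed = 33), 2,
                                 item_prefix = "rej")
  r1 <- run_delphi_round(dplyr::bind_rows(keepers, contested, rejected), 1)
  expect_identical(sum(r1$decisions$verdict == "retain"), 19L)

  # rounds 2-3: the contested items never clear the P25 gate
  hist <- tibble::tibble(item_id = r1$decisions$item_id,
                         verdict = as.character(r1$decisions$verdict))
  open2 <- as_tibble(generate_responses(branch_profile("modify", seed = 34),
                                        length(r1$carried_forward))) |>
    dplyr::mutate(item_id = rep(sort(r1$carried_forward),
                                times = dplyr::n() / length(r1$carried_forward)))
  r2 <- run_delphi_round(likert_matrix(open2), 2, history = hist)
  r3 <- run_delphi_round(likert_matrix(open2), 3,
                         history = dplyr::bind_rows(hist,
                           tibble::tibble(item_id = r2$decisions$item_id[r2$decisions$verdict == "exclude"],
                                          verdict = "exclude")))
  total_retained <- sum(r1$decisions$verdict == "retain") +
    sum(r2$decisions$verdict == "retain") +
    sum(r3$decisions$verdict == "retain")
  expect_identical(total_retained, 19L)
  expect_length(r3$carried_forward, 0L)
})

test_that("panel percentages use one-decimal rounding, half away from zero", {
  out <- panel_summary(data.frame(category = c("United Kingdom", "More than 15 years", "None"),
                                  count = c(7, 14, 0)), total = 22)
  expect_equal(out$percentage, c(31.8, 63.6, 0))
  expect_identical(out$display[1], "7 (31.8)")
  # per-group totals when no override supplied
  grouped <- panel_summary(data.frame(group = c("a", "a", "b"),
                                      category = c("x", "y", "z"),
                                      count = c(1, 3, 2)))
  expect_equal(grouped$percentage, c(25, 75, 100))
  expect_error(panel_summary(data.frame(category = "x", count = 0)), "positive")
  expect_error(panel_summary(data.frame(category = "x", count = -1), total = 22),
               "non-negative")
})

test_that("likert matrices read and write both CSV layouts", {
  m <- generate_responses(consensus_profile(n_panellists = 4, p_agree = 0.8,
                                            missing_rate = 0.2, seed = 9), 6)
  wide_path <- withr::local_tempfile(fileext = ".csv")
  write_likert(m, wide_path)
  expect_identical(as_tibble(read_likert(wide_path)) |> dplyr::arrange(item_id, panellist_id),
                   as_tibble(m) |> dplyr::arrange(item_id, panellist_id))
  long_path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(as_tibble(m), long_path)
  expect_identical(as_tibble(read_likert(long_path)), as_tibble(m))
  expect_error(likert_matrix(data.frame(item_id = "a", panellist_id = "p",
                                        response = 7)), "1-5")
})
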