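# Delphi consensus engine: 5-point Likert statistics and the
# percentile-based retain/modify/exclude rules used to validate the tool.

.likert_levels <- 1:5

#' Construct a Likert response matrix
#'
#' Validates and stores a panel's 5-point Likert responses in long form
#' (one row per item x panellist; Strongly agree = 5 ... Strongly
#' disagree = 1; missing allowed). Statistics require at least one
#' non-missing response per item, checked at analysis time so that an
#' all-missing item is reported by name.
#'
#' @param data Data frame with columns `item_id`, `panellist_id`,
#'   `response` (integer 1-5 or `NA`).
#' @return A `likert_matrix` tibble.
#' @seealso [read_likert()], [delphi_item_stats()]
#' @export
likert_matrix <- function(data) {
  data <- as_tibble(data)
  req <- c("item_id", "panellist_id", "response")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Likert data is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  resp <- data$response
  if (!all(is.na(resp) | resp %in% .likert_levels)) {
    bad <- unique(resp[!is.na(resp) & !resp %in% .likert_levels])
    abort(paste0("Responses must be integers 1-5 or missing; found: ",
                 paste(bad, collapse = ", ")))
  }
  data$item_id <- as.character(data$item_id)
  data$panellist_id <- as.character(data$panellist_id)
  data$response <- as.integer(resp)
  dup <- duplicated(data[, c("item_id", "panellist_id")])
  if (any(dup)) {
    abort(paste0("Duplicate (item, panellist) response(s), e.g. item ",
                 data$item_id[dup][1L]))
  }
  structure(data[, req], class = c("likert_matrix", class(as_tibble(data))))
}

#' Read a Likert response matrix from CSV
#'
#' Accepts either wide format (first column `item_id`, one column per
#' panellist, cells 1-5 or blank) or long format (columns `item_id`,
#' `panellist_id`, `response`); the format is detected from the header.
#'
#' @param path Path to the CSV file.
#' @return A `likert_matrix`.
#' @export
read_likert <- function(path) {
  if (!file.exists(path)) abort(paste0("Responses file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("item_id", "panellist_id", "response") %in% names(df))) {
    return(likert_matrix(df))
  }
  if (!"item_id" %in% names(df) || ncol(df) < 2L) {
    abort("Responses CSV must be long (item_id, panellist_id, response) or wide (item_id + one column per panellist).")
  }
  long <- tidyr::pivot_longer(df, -"item_id", names_to = "panellist_id",
                              values_to = "response",
                              values_transform = as.integer)
  likert_matrix(long)
}

#' Write a Likert matrix to wide CSV
#'
#' @param matrix A `likert_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_likert <- function(matrix, path) {
  wide <- tidyr::pivot_wider(as_tibble(matrix), names_from = "panellist_id",
                             values_from = "response")
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

# Weighted-average quantile at position (n+1)p: stats::quantile type 6,
# the convention of the statistics software named in the validation study.
.quantile_types <- c("weighted-average" = 6L, "linear" = 7L)

#' Per-item Likert statistics
#'
#' Computes, for one item's responses, the summary statistics fed to the
#' consensus decision rules: the number of non-missing responses, the
#' percentage of respondents agreeing or strongly agreeing (response >= 4),
#' the median, and the 25th/75th percentiles with their interquartile
#' range. Missing responses are excluded from both the numerator and the
#' denominator. Quantiles use weighted-average interpolation at position
#' (n+1)p by default (`quantile_method = "weighted-average"`); nothing is
#' rounded internally.
#'
#' @param responses Vector of Likert responses (1-5, `NA` allowed).
#' @param quantile_method `"weighted-average"` (default) or `"linear"`
#'   (sample-quantile interpolation at position 1 + (n-1)p).
#' @return A one-row tibble: `n_responses`, `agreement_pct`, `median`,
#'   `p25`, `p75`, `iqr`.
#' @examples
#' item_stats(c(2, 3, 4, 4, 4, 5, 5))
#' @export
item_stats <- function(responses, quantile_method = "weighted-average") {
  if (!quantile_method %in% names(.quantile_types)) {
    abort(paste0("Unknown quantile method: '", quantile_method, "'."))
  }
  x <- responses[!is.na(responses)]
  if (length(x) == 0L) abort("All responses are missing; statistics are undefined.")
  if (!all(x %in% .likert_levels)) {
    abort("Responses must lie on the 5-point scale (1-5).")
  }
  qs <- unname(stats::quantile(x, c(0.25, 0.75),
                               type = .quantile_types[[quantile_method]]))
  tibble(
    n_responses = length(x),
    agreement_pct = 100 * mean(x >= 4),
    median = stats::median(x),
    p25 = qs[1L],
    p75 = qs[2L],
    iqr = qs[2L] - qs[1L]
  )
}

#' Per-item statistics for a whole response matrix
#'
#' @param matrix A `likert_matrix` (or coercible data frame).
#' @inheritParams item_stats
#' @return A tibble with one row per item (`item_id` + the [item_stats()]
#'   columns), in first-appearance item order.
#' @export
delphi_item_stats <- function(matrix, quantile_method = "weighted-average") {
  m <- if (inherits(matrix, "likert_matrix")) matrix else likert_matrix(matrix)
  items <- unique(m$item_id)
  all_missing <- vapply(items, function(it) {
    all(is.na(m$response[m$item_id == it]))
  }, logical(1))
  if (any(all_missing)) {
    abort(paste0("Item(s) with no responses: ",
                 paste(items[all_missing], collapse = ", ")))
  }
  purrr::map_dfr(items, function(it) {
    dplyr::bind_cols(
      tibble(item_id = it),
      item_stats(m$response[m$item_id == it], quantile_method = quantile_method)
    )
  })
}

#' Apply the consensus decision rules to item statistics
#'
#' The validation design retains an item when its median is 4 or 5 with a
#' 25th percentile of at least 4 (equivalently, when at least 75% of
#' respondents agree or strongly agree); excludes an item whose median is 3
#' or lower in any round; and otherwise (median high enough but P25 below
#' 4) modifies the item for re-rating in the next round. In the final
#' round no further rating is possible, so every item failing the
#' inclusion criterion is excluded. A median strictly between 3 and 4 —
#' possible with an even panel — satisfies none of the stated clauses and
#' is treated conservatively as modify (exclude in the final round); the
#' rule trace records when this edge fires.
#'
#' @param stats A tibble of item statistics from [delphi_item_stats()] (or
#'   any data frame with `median` and `p25` columns; an `item_id` column is
#'   carried through).
#' @param final_round Logical: is this the last permitted round?
#' @return The input with `verdict` (factor retain/modify/exclude),
#'   `final_round` and `rule_trace` columns appended.
#' @examples
#' decide_items(data.frame(median = c(5, 3, 4), p25 = c(4.25, 2, 3.8)),
#'              final_round = TRUE)
#' @export
decide_items <- function(stats, final_round = FALSE) {
  stats <- as_tibble(stats)
  if (!all(c("median", "p25") %in% names(stats))) {
    abort("`stats` must have `median` and `p25` columns.")
  }
  one <- function(med, p25) {
    if (med >= 4 && p25 >= 4) {
      c("retain", sprintf("median %g >= 4 with P25 %g >= 4: inclusion criterion met", med, p25))
    } else if (med <= 3) {
      c("exclude", sprintf("median %g <= 3: exclusion criterion met", med))
    } else if (med < 4) {
      # non-integer median strictly between 3 and 4: no stated clause applies
      if (final_round) {
        c("exclude", sprintf("median %g between 3 and 4 (no clause applies); final round: excluded conservatively", med))
      } else {
        c("modify", sprintf("median %g between 3 and 4 (no clause applies): modified conservatively", med))
      }
    } else if (final_round) {
      c("exclude", sprintf("final round: median %g >= 4 but P25 %g < 4: not accepted", med, p25))
    } else {
      c("modify", sprintf("median %g >= 4 but P25 %g < 4: modify per panel suggestions", med, p25))
    }
  }
  res <- purrr::map2(stats$median, stats$p25, one)
  stats$verdict <- factor(vapply(res, `[`, character(1), 1L),
                          levels = c("retain", "modify", "exclude"))
  stats$final_round <- final_round
  stats$rule_trace <- vapply(res, `[`, character(1), 2L)
  stats
}

#' Run one Delphi round
#'
#' Computes per-item statistics and verdicts for the items open in a round,
#' with the final-round acceptance rule applied when `round_number ==
#' max_rounds`. Items with a modify verdict, together with any newly
#' suggested items (`new_items`, a manual input: turning free-text panel
#' comments into survey items is human judgement, not computation), are
#' carried forward to the next round. Feedback mirrors the controlled
#' feedback sent to panellists after each round: a group summary per item
#' and each panellist's own responses alongside the group statistics.
#'
#' @param matrix A `likert_matrix` covering exactly the items open in this
#'   round.
#' @param round_number Integer round index, starting at 1.
#' @param max_rounds Total permitted rounds (3 in the tool's validation).
#' @param new_items Character vector of newly suggested item ids to open in
#'   the next round.
#' @param history Optional decisions tibble from earlier rounds (columns
#'   `item_id`, `verdict`); an item already retained or excluded may not be
#'   re-rated and raises an error.
#' @param comments Optional tibble (`item_id`, `panellist_id`, `comment`)
#'   echoed verbatim into the feedback.
#' @inheritParams item_stats
#' @return An `mrf_round_result`: list with `round_number`, `final_round`,
#'   `decisions` (per-item stats + verdicts), `carried_forward`, and
#'   `feedback` (`$group`, `$individual`, `$comments`).
#' @export
run_delphi_round <- function(matrix, round_number, max_rounds = 3L,
                             new_items = character(), history = NULL,
                             comments = NULL,
                             quantile_method = "weighted-average") {
  if (round_number < 1L || round_number > max_rounds) {
    abort(sprintf("round_number must be in 1..max_rounds (got %s of %s).",
                  round_number, max_rounds))
  }
  m <- if (inherits(matrix, "likert_matrix")) matrix else likert_matrix(matrix)
  if (!is.null(history)) {
    closed <- history$item_id[history$verdict %in% c("retain", "exclude")]
    reopened <- intersect(unique(m$item_id), closed)
    if (length(reopened) > 0L) {
      abort(paste0("Item(s) already decided in a prior round: ",
                   paste(reopened, collapse = ", ")))
    }
  }
  final_round <- round_number == max_rounds
  decisions <- decide_items(
    delphi_item_stats(m, quantile_method = quantile_method),
    final_round = final_round
  )
  carried <- union(as.character(decisions$item_id[decisions$verdict == "modify"]),
                   new_items)
  individual <- dplyr::left_join(
    as_tibble(m),
    dplyr::select(decisions, "item_id", group_agreement_pct = "agreement_pct",
                  group_median = "median", group_p25 = "p25", group_iqr = "iqr"),
    by = "item_id"
  )
  structure(
    list(
      round_number = as.integer(round_number),
      max_rounds = as.integer(max_rounds),
      final_round = final_round,
      decisions = decisions,
      carried_forward = carried,
      feedback = list(
        group = decisions,
        individual = individual,
        comments = if (is.null(comments)) tibble(item_id = character(),
                                                 panellist_id = character(),
                                                 comment = character())
                   else as_tibble(comments)
      )
    ),
    class = "mrf_round_result"
  )
}

#' @export
print.mrf_round_result <- function(x, ...) {
  tab <- table(x$decisions$verdict)
  cat(sprintf("<mrf_round_result> round %d of %d%s: %d item(s) — retained %d, modified %d, excluded %d; %d carried forward\n",
              x$round_number, x$max_rounds,
              if (x$final_round) " (final)" else "",
              nrow(x$decisions), tab[["retain"]], tab[["modify"]], tab[["exclude"]],
              length(x$carried_forward)))
  invisible(x)
}

#' @rdname run_delphi_round
#' @param x An `mrf_round_result`.
#' @param ... Unused.
#' @method tidy mrf_round_result
#' @export
tidy.mrf_round_result <- function(x, ...) {
  dplyr::mutate(x$decisions, round_number = x$round_number, .before = 1L)
}

#' @rdname run_delphi_round
#' @method glance mrf_round_result
#' @export
glance.mrf_round_result <- function(x, ...) {
  tab <- table(x$decisions$verdict)
  tibble(
    round_number = x$round_number,
    max_rounds = x$max_rounds,
    final_round = x$final_round,
    n_items = nrow(x$decisions),
    n_retained = tab[["retain"]],
    n_modified = tab[["modify"]],
    n_excluded = tab[["exclude"]],
    n_carried_forward = length(x$carried_forward),
    mean_agreement_pct = mean(x$decisions$agreement_pct)
  )
}

# round half away from zero at `digits` decimals (display convention for
# panel percentages; base round() is round-half-even)
round_half_away <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Summarise panel demographics
#'
#' Converts demographic counts of a Delphi panel into count (percentage)
#' rows, the presentation used for panel characteristics tables.
#' Percentages are per category out of `total` (by default the sum of
#' counts within each `group`, or overall if no `group` column is present),
#' rounded to one decimal, half away from zero.
#'
#' @param demographics Data frame with columns `category` and `count`, and
#'   optionally `group` (e.g. "Country", "Highest level of education").
#' @param total Optional panel size overriding the per-group sum (use when
#'   a partial table is supplied).
#' @return A tibble with `percentage` and a formatted `display` column
#'   (`"7 (31.8)"`) appended.
#' @examples
#' panel_summary(data.frame(category = c("UK", "Canada"), count = c(7, 5)), total = 22)
#' @export
panel_summary <- function(demographics, total = NULL) {
  d <- as_tibble(demographics)
  if (!all(c("category", "count") %in% names(d))) {
    abort("`demographics` must have `category` and `count` columns.")
  }
  if (any(d$count < 0)) abort("Counts must be non-negative.")
  grouped <- "group" %in% names(d)
  if (is.null(total)) {
    if (grouped) {
      d <- d |> dplyr::group_by(.data$group) |>
        dplyr::mutate(.total = sum(.data$count)) |> dplyr::ungroup()
    } else {
      d$.total <- sum(d$count)
    }
  } else {
    d$.total <- total
  }
  if (any(d$.total <= 0)) abort("Total count must be positive.")
  d$percentage <- round_half_away(100 * d$count / d$.total, 1L)
  d$display <- sprintf("%d (%.1f)", as.integer(d$count), d$percentage)
  dplyr::select(d, -".total")
}
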