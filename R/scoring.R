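#' Score a single medication
#'
#' Resolves one raw medication name against the catalog and computes its
#' points contribution. A drug listed in more than one medication class
#' receives the highest score among its classes (the max rule); a drug not
#' in any class contributes 0 and is flagged unresolved rather than dropped.
#'
#' @param raw_name A single non-empty medication name.
#' @param catalog An `mrf_catalog`; defaults to the packaged tool,
#'   [mrf_catalog_v1()].
#' @return A one-row tibble with columns `raw_name`, `normalized_name`,
#'   `resolved`, `classes` (list-column of class ids), `n_classes`,
#'   `class_name`, `tier`, `mechanism` (of the highest-scoring class) and
#'   `contribution` (integer in 0..3).
#' @examples
#' score_medication("furosemide")
#' score_medication("ascorbic acid")
#' @export
score_medication <- function(raw_name, catalog = mrf_catalog_v1()) {
  hits <- lookup_drug(catalog, raw_name)
  if (nrow(hits) == 0L) {
    return(tibble(
      raw_name = raw_name,
      normalized_name = attr(hits, "normalized_name"),
      resolved = FALSE,
      classes = list(character()),
      n_classes = 0L,
      class_name = NA_character_,
      tier = NA_character_,
      mechanism = NA_character_,
      contribution = 0L
    ))
  }
  top <- hits[which.max(hits$score), , drop = FALSE]
  tibble(
    raw_name = raw_name,
    normalized_name = attr(hits, "normalized_name"),
    resolved = TRUE,
    classes = list(hits$class_id),
    n_classes = nrow(hits),
    class_name = top$name,
    tier = as.character(top$tier),
    mechanism = top$mechanism,
    contribution = as.integer(top$score)
  )
}

#' Score a patient's medication list
#'
#' Computes the overall medication-related falls risk of a patient by
#' summing the per-medication points: 3 for each high-risk medication, 2
#' for each moderate-risk, 1 for each low-risk, with the highest score
#' taken when a drug falls into more than one class. Medications appearing
#' more than once under the same normalised generic name are scored once
#' (the tool scores medications, not prescription lines). Unresolved items
#' contribute 0 and are reported. A referral flag is raised when the
#' patient takes at least one high- or moderate-risk medication, the
#' trigger for a medication review and fall-prevention referral.
#'
#' @param meds A character vector of medication names, or a data frame with
#'   a `medication` column (e.g. from [read_med_list()]). May be empty.
#' @param catalog An `mrf_catalog`; defaults to [mrf_catalog_v1()].
#' @return An `mrf_patient_score` object; see [tidy()][generics::tidy] for
#'   the per-medication breakdown and [glance()][generics::glance] for the
#'   one-row summary (`total`, tier counts, `unresolved_count`,
#'   `referral_flag`).
#' @examples
#' score <- score_patient(c("Furosemide 40mg", "bisoprolol", "digoxin"))
#' score
#' glance(score)
#' @export
score_patient <- function(meds, catalog = mrf_catalog_v1()) {
  if (is.data.frame(meds)) {
    if (!"medication" %in% names(meds)) {
      abort("`meds` data frame must have a `medication` column.")
    }
    meds <- as.character(meds$medication)
  }
  meds <- meds[!is.na(meds) & nzchar(stringr::str_trim(meds))]
  if (length(meds) == 0L) {
    entries <- score_medication("placeholder", catalog)[0, ]
    entries$n_listed <- integer()
  } else {
    entries <- purrr::map_dfr(meds, score_medication, catalog = catalog)
    entries <- entries |>
      dplyr::mutate(.ord = dplyr::row_number()) |>
      dplyr::group_by(.data$normalized_name) |>
      dplyr::mutate(n_listed = dplyr::n()) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$.ord) |>
      dplyr::select(-".ord")
  }
  tier_counts <- vapply(
    .tier_levels,
    function(t) sum(!is.na(entries$tier) & entries$tier == t),
    integer(1)
  )
  structure(
    list(
      entries = entries,
      total = as.integer(sum(entries$contribution)),
      tier_counts = tier_counts,
      unresolved_count = as.integer(sum(!entries$resolved)),
      referral_flag = any(entries$contribution >= 2L),
      catalog_version = attr(catalog, "version")
    ),
    class = "mrf_patient_score"
  )
}

#' @export
print.mrf_patient_score <- function(x, ...) {
  cat("<mrf_patient_score> total =", x$total, "points;",
      sum(x$tier_counts), "scored medication(s)",
      sprintf("(high %d, moderate %d, low %d)", x$tier_counts[["high"]],
              x$tier_counts[["moderate"]], x$tier_counts[["low"]]), "\n")
  if (x$unresolved_count > 0L) {
    cat("  unresolved (contribute 0):", x$unresolved_count, "\n")
  }
  cat(if (isTRUE(x$referral_flag)) {
    "  referral advised: patient takes high- or moderate-risk medication(s)\n"
  } else {
    "  no referral trigger: no high- or moderate-risk medications\n"
  })
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname score_patient
#' @param x An `mrf_patient_score`.
#' @param ... Unused.
#' @method tidy mrf_patient_score
#' @export
tidy.mrf_patient_score <- function(x, ...) {
  x$entries
}

#' @rdname score_patient
#' @method glance mrf_patient_score
#' @export
glance.mrf_patient_score <- function(x, ...) {
  tibble(
    total = x$total,
    n_medications = nrow(x$entries),
    n_high = x$tier_counts[["high"]],
    n_moderate = x$tier_counts[["moderate"]],
    n_low = x$tier_counts[["low"]],
    unresolved_count = x$unresolved_count,
    referral_flag = x$referral_flag,
    catalog_version = x$catalog_version
  )
}

#' Read a patient medication list
#'
#' Reads a plain-text file (one medication per line) or a CSV with a
#' `medication` column into a tibble suitable for [score_patient()].
#'
#' @param path Path to the medication list file.
#' @return A tibble with a `medication` column.
#' @export
read_med_list <- function(path) {
  if (!file.exists(path)) abort(paste0("Medication list file not found: ", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"medication" %in% names(df)) {
      abort("CSV medication list must have a `medication` column.")
    }
    tibble(medication = as.character(df$medication))
  } else {
    lines <- readr::read_lines(path, progress = FALSE)
    tibble(medication = lines[nzchar(stringr::str_trim(lines))])
  }
}

#' Serialise a patient score report
#'
#' Renders an [score_patient()] result as human-readable text, TSV, or JSON.
#' The JSON form is lossless: [parse_report()] reconstructs the score object
#' and re-rendering yields identical JSON.
#'
#' @param score An `mrf_patient_score`.
#' @param format One of `"text"`, `"json"`, `"tsv"`.
#' @return A single character string.
#' @export
render_report <- function(score, format = c("text", "json", "tsv")) {
  stopifnot(inherits(score, "mrf_patient_score"))
  if (length(format) > 1L) format <- format[[1L]]
  if (!format %in% c("text", "json", "tsv")) {
    abort(paste0("Unknown report format: '", format, "' (use text, json or tsv)."))
  }
  e <- score$entries
  if (format == "json") {
    payload <- list(
      catalog_version = score$catalog_version,
      total = score$total,
      tier_counts = as.list(score$tier_counts),
      unresolved_count = score$unresolved_count,
      referral_flag = score$referral_flag,
      medications = purrr::pmap(e, function(raw_name, normalized_name, resolved,
                                            classes, n_classes, class_name, tier,
                                            mechanism, contribution, n_listed) {
        list(raw_name = raw_name, normalized_name = normalized_name,
             resolved = resolved, classes = as.list(classes),
             class_name = class_name, tier = tier, mechanism = mechanism,
             contribution = contribution, n_listed = n_listed)
      })
    )
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         null = "null", digits = NA, pretty = TRUE)))
  }
  if (format == "tsv") {
    flat <- e |>
      dplyr::mutate(classes = purrr::map_chr(.data$classes, paste, collapse = ";")) |>
      dplyr::select("raw_name", "normalized_name", "resolved", "classes",
                    "class_name", "tier", "contribution", "n_listed")
    con <- textConnection("tsv_out", "w", local = TRUE)
    utils::write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    close(con)
    return(paste0(paste(tsv_out, collapse = "\n"), "\n",
                  "# total\t", score$total,
                  "\treferral\t", tolower(score$referral_flag), "\n"))
  }
  lines <- c(sprintf("MRF patient score (catalog v%s)", score$catalog_version), "")
  if (nrow(e) == 0L) {
    lines <- c(lines, "  (no medications supplied)")
  } else {
    for (i in seq_len(nrow(e))) {
      if (e$resolved[i]) {
        lines <- c(lines, sprintf(
          "  %-28s -> %s [%s, %d point%s]%s",
          e$raw_name[i], e$class_name[i], e$tier[i], e$contribution[i],
          if (e$contribution[i] == 1L) "" else "s",
          if (e$n_classes[i] > 1L) sprintf("  (in %d classes; highest score taken)",
                                           e$n_classes[i]) else ""
        ), sprintf("  %-28s    mechanism: %s", "", e$mechanism[i]))
      } else {
        lines <- c(lines, sprintf(
          "  %-28s -> WARNING: not in any catalog class (0 points)", e$raw_name[i]))
      }
      if (e$n_listed[i] > 1L) {
        lines <- c(lines, sprintf("  %-28s    listed %d times; scored once",
                                  "", e$n_listed[i]))
      }
    }
  }
  lines <- c(lines, "",
             sprintf("  Total MRF score: %d (high %d, moderate %d, low %d, unresolved %d)",
                     score$total, score$tier_counts[["high"]],
                     score$tier_counts[["moderate"]], score$tier_counts[["low"]],
                     score$unresolved_count),
             if (isTRUE(score$referral_flag)) {
               "  Referral advised: patient takes high- or moderate-risk medication(s)."
             } else {
               "  No referral trigger: no high- or moderate-risk medications."
             })
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname render_report
#' @param json A JSON string produced by `render_report(..., format = "json")`.
#' @export
parse_report <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  entries <- purrr::map_dfr(p$medications, function(m) {
    tibble(
      raw_name = m$raw_name,
      normalized_name = m$normalized_name,
      resolved = m$resolved,
      classes = list(as.character(unlist(m$classes))),
      n_classes = length(m$classes),
      class_name = m$class_name %||% NA_character_,
      tier = m$tier %||% NA_character_,
      mechanism = m$mechanism %||% NA_character_,
      contribution = as.integer(m$contribution),
      n_listed = as.integer(m$n_listed)
    )
  })
  if (length(p$medications) == 0L) {
    entries <- score_medication("placeholder")[0, ]
    entries$n_listed <- integer()
  }
  structure(
    list(
      entries = entries,
      total = as.integer(p$total),
      tier_counts = vapply(p$tier_counts, as.integer, integer(1))[.tier_levels],
      unresolved_count = as.integer(p$unresolved_count),
      referral_flag = isTRUE(p$referral_flag),
      catalog_version = p$catalog_version
    ),
    class = "mrf_patient_score"
  )
}
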