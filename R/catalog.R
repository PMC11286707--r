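#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
NULL

# Fixed, total tier -> points mapping: the tool's ranking system.
.tier_levels <- c("high", "moderate", "low")
.tier_scores <- c(high = 3L, moderate = 2L, low = 1L)

.tier_definitions <- c(
  high     = "may commonly cause or contribute to falling risk on their own or in combination",
  moderate = "may cause falls especially in combination",
  low      = "possibly cause falls, particularly in combination"
)

#' Points assigned to each falls-risk tier
#'
#' The MRF tool ranks medication classes into three falls-risk tiers and
#' assigns fixed points: high-risk medications score three points,
#' moderate-risk two and low-risk one. The mapping is total and fixed; it is
#' not configurable.
#'
#' @param tier Character vector of tier labels (`"high"`, `"moderate"`,
#'   `"low"`).
#' @return Integer vector of points in `{3, 2, 1}`.
#' @examples
#' tier_score(c("high", "low"))
#' @export
tier_score <- function(tier) {
  if (!all(tier %in% .tier_levels)) {
    abort(paste0(
      "Unknown risk tier(s): ",
      paste(setdiff(unique(tier), .tier_levels), collapse = ", "),
      ". Tiers are 'high', 'moderate', 'low'."
    ))
  }
  unname(.tier_scores[tier])
}

#' Falls-risk tier definitions
#'
#' Returns the tier definitions presented alongside every survey round of the
#' tool's validation: high-risk classes may commonly cause or contribute to
#' falling risk, moderate-risk classes may cause falls especially in
#' combination, and low-risk classes possibly cause falls.
#'
#' @return A tibble with columns `tier`, `score`, `definition`.
#' @export
tier_definitions <- function() {
  tibble(
    tier = .tier_levels,
    score = unname(.tier_scores[.tier_levels]),
    definition = unname(.tier_definitions[.tier_levels])
  )
}

# ---------------------------------------------------------------------------
# Drug-name normalisation
# ---------------------------------------------------------------------------

.unit_token_re <- "^[0-9][0-9.,/]*(mg|g|mcg|microgram(s|mes)?|ml|mls|ng|iu|unit(s)?|mmol|%)?(/[a-z0-9.%]+)?$"

.form_tokens <- c(
  "tablet", "tablets", "tab", "tabs", "capsule", "capsules", "cap", "caps",
  "caplet", "caplets", "liquid", "syrup", "solution", "suspension",
  "injection", "inj", "patch", "patches", "cream", "ointment", "gel",
  "spray", "drops", "suppository", "suppositories", "sachet", "sachets",
  "inhaler", "oral", "topical", "sublingual", "mg", "ml", "mcg", "g",
  "micrograms", "microgram", "units", "unit", "mr", "m/r", "sr", "xl",
  "la", "cr", "er", "modified", "release", "modified-release",
  "prolonged", "prolonged-release", "slow", "forte", "retard", "strong"
)

.salt_tokens <- c(
  "hydrochloride", "hcl", "sodium", "maleate", "tartrate", "bitartrate",
  "sulfate", "sulphate", "citrate", "besilate", "besylate", "mesilate",
  "mesylate", "fumarate", "succinate", "phosphate", "potassium", "calcium",
  "dihydrate", "monohydrate", "hemihydrate", "hydrobromide"
)

#' Normalise a raw medication name
#'
#' Deterministic, dictionary-free normalisation applied before any catalog
#' lookup: case-fold and trim; drop dose/strength tokens (numbers with or
#' without units such as `40mg`, `2.5`, `0.5%`), formulation tokens
#' (`tablets`, `capsules`, `m/r`, ...), and trailing salt tokens
#' (`hydrochloride`, `sodium`, `maleate`, ...). Leading salt words are kept,
#' so `"sodium valproate"` survives intact while `"valproate sodium"`
#' reduces to `"valproate"` (resolved via the catalog synonym table).
#' Synonym and brand-name resolution is *not* performed here; it belongs to
#' the catalog (see [lookup_drug()]).
#'
#' The function is idempotent: `normalize_drug_name(normalize_drug_name(x))`
#' equals `normalize_drug_name(x)`.
#'
#' @param x Character vector of raw medication names.
#' @return Character vector of normalised names.
#' @examples
#' normalize_drug_name("FUROSEMIDE 40mg tablets")
#' @export
normalize_drug_name <- function(x) {
  if (!is.character(x)) abort("`x` must be a character vector of drug names.")
  s <- stringr::str_to_lower(stringr::str_trim(x))
  s <- stringr::str_replace_all(s, "[(),;:\\[\\]]", " ")
  vapply(stringr::str_split(s, "\\s+"), function(tokens) {
    tokens <- tokens[nzchar(tokens)]
    keep <- !grepl(.unit_token_re, tokens) & !(tokens %in% .form_tokens)
    tokens <- tokens[keep]
    # strip trailing salt tokens only; a leading salt word is part of the INN
    while (length(tokens) > 1L && tokens[length(tokens)] %in% .salt_tokens) {
      tokens <- tokens[-length(tokens)]
    }
    paste(tokens, collapse = " ")
  }, character(1))
}

# ---------------------------------------------------------------------------
# Catalog construction and validation
# ---------------------------------------------------------------------------

#' Construct an MRF medication catalog
#'
#' Builds a validated catalog of tiered medication classes from a data frame
#' with one row per class. A catalog is the content of the screening tool:
#' each class carries a falls-risk tier (with its fixed score), a mechanism
#' statement explaining how the class increases falls risk, its member
#' generic drug names, and an optional alias-to-generic synonym table. A
#' normalised drug-name index is built so that one drug may resolve to more
#' than one class (the highest-score rule then applies at scoring time).
#'
#' @param classes Data frame with columns `class_id`, `name`, `tier`,
#'   `mechanism`, and list-columns `members` (character vectors of generic
#'   names) and `synonyms` (named character vectors mapping alias ->
#'   generic; may be empty). An optional `score` column is checked against
#'   the fixed tier mapping. An optional logical `reconstructed` column
#'   marks classes whose identity was reconstructed rather than transcribed.
#' @param version Catalog version string.
#' @param provenance Free-text provenance statement.
#' @return An `mrf_catalog`: a tibble of classes with attributes
#'   `version`, `provenance` and `drug_index`.
#' @seealso [load_catalog()], [mrf_catalog_v1()], [validate_catalog()]
#' @export
mrf_catalog <- function(classes, version = "custom", provenance = "user-supplied") {
  classes <- as_tibble(classes)
  required <- c("class_id", "name", "tier", "mechanism", "members")
  missing_cols <- setdiff(required, names(classes))
  if (length(missing_cols) > 0L) {
    abort(paste0("Catalog is missing required field(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(classes) == 0L) abort("Catalog has no classes.")
  if (anyDuplicated(classes$class_id)) {
    abort(paste0("Duplicate class_id: ",
                 paste(unique(classes$class_id[duplicated(classes$class_id)]),
                       collapse = ", ")))
  }
  if (any(is.na(classes$name) | !nzchar(classes$name))) {
    abort("Field `name` must be non-empty for every class.")
  }
  if (!all(classes$tier %in% .tier_levels)) {
    abort(paste0("Field `tier` has invalid value(s): ",
                 paste(setdiff(unique(classes$tier), .tier_levels), collapse = ", ")))
  }
  if ("score" %in% names(classes)) {
    expected <- tier_score(classes$tier)
    bad <- which(as.integer(classes$score) != expected)
    if (length(bad) > 0L) {
      abort(paste0("Field `score` contradicts the fixed tier mapping for class ",
                   paste(classes$class_id[bad], collapse = ", "),
                   " (high=3, moderate=2, low=1)."))
    }
  }
  classes$score <- tier_score(classes$tier)
  if (any(is.na(classes$mechanism) | !nzchar(classes$mechanism))) {
    abort("Field `mechanism` must be non-empty for every class.")
  }
  if (!is.list(classes$members)) classes$members <- as.list(classes$members)
  empty_members <- vapply(classes$members, function(m) length(m) == 0L || all(!nzchar(m)), logical(1))
  if (any(empty_members)) {
    abort(paste0("Field `members` is empty for class ",
                 paste(classes$class_id[empty_members], collapse = ", ")))
  }
  if (!"synonyms" %in% names(classes)) {
    classes$synonyms <- rep(list(character()), nrow(classes))
  }
  if (!"reconstructed" %in% names(classes)) {
    classes$reconstructed <- FALSE
  }
  classes$reconstructed <- isTRUE_vec(classes$reconstructed)
  classes$tier <- factor(classes$tier, levels = .tier_levels)

  idx <- build_drug_index(classes)
  structure(
    classes[, c("class_id", "name", "tier", "score", "mechanism",
                "members", "synonyms", "reconstructed")],
    version = version,
    provenance = provenance,
    drug_index = idx,
    class = c("mrf_catalog", class(as_tibble(classes)))
  )
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

build_drug_index <- function(classes) {
  rows <- purrr::pmap(
    list(classes$class_id, classes$members, classes$synonyms),
    function(cid, members, synonyms) {
      member_keys <- normalize_drug_name(members)
      out <- tibble(key = member_keys, generic = members, class_id = cid)
      synonyms <- unlist(synonyms)
      if (length(synonyms) > 0L) {
        bad <- !(synonyms %in% members)
        if (any(bad)) {
          abort(paste0("Synonym target(s) not in `members` for class ", cid,
                       ": ", paste(unique(synonyms[bad]), collapse = ", ")))
        }
        out <- dplyr::bind_rows(out, tibble(
          key = normalize_drug_name(names(synonyms)),
          generic = unname(synonyms),
          class_id = cid
        ))
      }
      out
    }
  )
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Load an MRF catalog from a JSON file
#'
#' Reads a human-editable JSON catalog file (top level: `version`,
#' `provenance`, `classes`) and returns a validated [mrf_catalog()]. All
#' member and synonym names are normalised into the drug index at load time.
#'
#' @param path Path to a catalog JSON file.
#' @return An `mrf_catalog`.
#' @examples
#' cat_path <- system.file("extdata", "mrf_catalog_v1.json", package = "mrfscore")
#' catalog <- load_catalog(cat_path)
#' nrow(catalog)
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("Catalog file not found: ", path))
  if (file.size(path) == 0L) abort(paste0("Catalog file is empty: ", path))
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("Catalog file is not valid JSON: ", conditionMessage(e)))
  )
  if (is.null(raw$classes) || length(raw$classes) == 0L) {
    abort("Catalog field `classes` is missing or empty.")
  }
  classes <- purrr::map_dfr(raw$classes, function(cl) {
    tibble(
      class_id = cl$class_id %||% NA_character_,
      name = cl$name %||% "",
      tier = cl$tier %||% NA_character_,
      score = as.integer(cl$score %||% tier_score(cl$tier %||% "high")),
      mechanism = cl$mechanism %||% "",
      members = list(as.character(unlist(cl$members))),
      synonyms = list(unlist(cl$synonyms) %||% character()),
      reconstructed = isTRUE(cl$reconstructed)
    )
  })
  if (any(is.na(classes$class_id))) abort("Field `class_id` is missing for at least one class.")
  if (any(is.na(classes$tier))) abort("Field `tier` is missing for at least one class.")
  mrf_catalog(classes,
              version = raw$version %||% "unversioned",
              provenance = raw$provenance %||% "unspecified")
}

#' The packaged MRF catalog (version 1)
#'
#' Loads the catalog shipped with the package: the final Delphi-validated
#' tool of 19 medication classes, partitioned into 10 high-risk, 8
#' moderate-risk and 1 low-risk class. Fifteen classes are transcribed from
#' the published description of the final tool; four (marked
#' `reconstructed`) were reconstructed from the tool's source falls-risk
#' list because they are not individually named in the accessible text —
#' see `vignette("mrf-methods")`.
#'
#' @return An `mrf_catalog` with 19 classes.
#' @examples
#' catalog <- mrf_catalog_v1()
#' table(catalog$tier)
#' @export
mrf_catalog_v1 <- function() {
  load_catalog(system.file("extdata", "mrf_catalog_v1.json", package = "mrfscore"))
}

#' @export
print.mrf_catalog <- function(x, ...) {
  cat("<mrf_catalog> version ", attr(x, "version"), ": ",
      nrow(x), " classes (",
      paste(sprintf("%s=%d", levels(x$tier), as.integer(table(x$tier))), collapse = ", "),
      ")\n", sep = "")
  NextMethod()
}

#' Validate an MRF catalog
#'
#' Runs every structural invariant over a catalog and returns a report, one
#' row per check, rather than throwing: unique non-empty identifiers, valid
#' tiers with the fixed score mapping, non-empty mechanism statements and
#' member lists, a drug index consistent with the classes (every indexed
#' name resolves to exactly the classes that list it), and — when
#' `reference_counts` is supplied — the expected number of classes per tier.
#' For the packaged catalog the reference partition is 10 high / 8 moderate
#' / 1 low.
#'
#' @param catalog An `mrf_catalog`.
#' @param reference_counts Optional named integer vector
#'   (`c(high = , moderate = , low = )`) of expected class counts per tier.
#' @return A tibble with columns `check`, `pass` (logical) and `detail`.
#' @examples
#' validate_catalog(mrf_catalog_v1(), reference_counts = c(high = 10, moderate = 8, low = 1))
#' @export
validate_catalog <- function(catalog, reference_counts = NULL) {
  stopifnot(inherits(catalog, "mrf_catalog"))
  checks <- list()
  add <- function(check, pass, detail) {
    checks[[length(checks) + 1L]] <<- tibble(check = check, pass = pass, detail = detail)
  }
  add("class_id_unique", !anyDuplicated(catalog$class_id),
      paste0(nrow(catalog), " classes"))
  add("names_nonempty", all(nzchar(catalog$name)), "class display names")
  add("tiers_valid", all(catalog$tier %in% .tier_levels),
      "tier labels in {high, moderate, low}")
  add("scores_match_tiers", all(catalog$score == tier_score(as.character(catalog$tier))),
      "high=3, moderate=2, low=1")
  empty_members <- vapply(catalog$members, function(m) length(m) == 0L, logical(1))
  add("members_nonempty", !any(empty_members),
      if (any(empty_members)) paste0("empty members: ",
        paste(catalog$class_id[empty_members], collapse = ", ")) else "every class lists drugs")
  add("mechanisms_nonempty", all(nzchar(catalog$mechanism)),
      "falls-risk mechanism stated for every class")

  idx <- attr(catalog, "drug_index")
  rebuilt <- build_drug_index(catalog)
  consistent <- identical(
    dplyr::arrange(idx, .data$key, .data$class_id),
    dplyr::arrange(rebuilt, .data$key, .data$class_id)
  )
  add("drug_index_consistent", consistent,
      "every indexed name maps to exactly the classes that list it")

  tier_tab <- table(factor(catalog$tier, levels = .tier_levels))
  if (!is.null(reference_counts)) {
    ok <- all(as.integer(tier_tab[names(reference_counts)]) == as.integer(reference_counts))
    add("tier_counts", ok,
        paste0("observed ", paste(sprintf("%s=%d", names(tier_tab), as.integer(tier_tab)),
                                  collapse = "/"),
               "; expected ", paste(sprintf("%s=%d", names(reference_counts),
                                            as.integer(reference_counts)), collapse = "/")))
  } else {
    add("tier_counts", TRUE,
        paste0("observed ", paste(sprintf("%s=%d", names(tier_tab), as.integer(tier_tab)),
                                  collapse = "/")))
  }
  dplyr::bind_rows(checks)
}

#' Look up a medication in the catalog
#'
#' Normalises a raw medication name ([normalize_drug_name()]), resolves
#' catalog synonyms and brand names, and returns every catalog class that
#' lists the drug. A drug outside all 19 classes is not an error: real
#' medication lists contain such items by design, and the empty result
#' carries status `"unresolved"` so scoring can report it.
#'
#' @param catalog An `mrf_catalog`.
#' @param raw_name A single non-empty medication name as supplied (any case,
#'   with or without dose/formulation text).
#' @return A tibble of matching classes (columns `class_id`, `name`, `tier`,
#'   `score`, `mechanism`, `generic`) with attributes `normalized_name` and
#'   `status` (`"resolved"` or `"unresolved"`).
#' @examples
#' catalog <- mrf_catalog_v1()
#' lookup_drug(catalog, "FUROSEMIDE 40mg tablets")
#' @export
lookup_drug <- function(catalog, raw_name) {
  stopifnot(inherits(catalog, "mrf_catalog"))
  if (length(raw_name) != 1L || is.na(raw_name) || !nzchar(stringr::str_trim(raw_name))) {
    abort("`raw_name` must be a single non-empty medication name.")
  }
  key <- normalize_drug_name(raw_name)
  idx <- attr(catalog, "drug_index")
  hits <- idx[idx$key == key, , drop = FALSE]
  out <- dplyr::inner_join(
    dplyr::select(as_tibble(catalog), "class_id", "name", "tier", "score", "mechanism"),
    dplyr::select(hits, "class_id", "generic"),
    by = "class_id"
  )
  attr(out, "normalized_name") <- key
  attr(out, "status") <- if (nrow(out) > 0L) "resolved" else "unresolved"
  out
}
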