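# Seeded generators: synthetic Delphi response matrices with controlled
# consensus structure, and patient medication lists with controlled tier
# mixes, so the whole pipeline is testable without any external data.

# evaluate `code` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Define a consensus profile for synthetic panel responses
#'
#' A profile fixes the marginal response distribution of a synthetic
#' panellist on the 5-point scale, either directly (`probs`, a length-5
#' probability vector over responses 1..5) or through a target agreement
#' probability `p_agree` = P(response >= 4). When derived from `p_agree`,
#' the agreement mass is split evenly between Agree (4) and Strongly agree
#' (5) and the remainder is spread 0.5/0.3/0.2 over Neutral/Disagree/
#' Strongly disagree — a unimodal shape typical of expert panels near
#' consensus. Responses are drawn independently across panellists and
#' items, mirroring an anonymous panel design.
#'
#' @param n_panellists Panel size (default 22, a typical expert panel).
#' @param p_agree Target probability of a response >= 4 (ignored if
#'   `probs` given).
#' @param probs Optional explicit probability vector over responses 1..5.
#' @param missing_rate Probability a response is missing (0 <= rate < 1).
#' @param seed Integer seed; every generator call keyed by it is
#'   bit-reproducible.
#' @return A `consensus_profile` list.
#' @examples
#' consensus_profile(p_agree = 0.77, seed = 1)
#' @export
consensus_profile <- function(n_panellists = 22L, p_agree = NULL, probs = NULL,
                              missing_rate = 0, seed = 1L) {
  if (n_panellists < 1L) abort("`n_panellists` must be at least 1.")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1): an all-missing panel is degenerate.")
  }
  if (is.null(probs)) {
    if (is.null(p_agree)) abort("Supply either `p_agree` or `probs`.")
    if (p_agree < 0 || p_agree > 1) abort("`p_agree` must lie in [0, 1].")
    probs <- c((1 - p_agree) * c(0.2, 0.3, 0.5), p_agree / 2, p_agree / 2)
  }
  if (length(probs) != 5L || any(probs < 0) || sum(probs) <= 0) {
    abort("`probs` must be 5 non-negative values with positive sum.")
  }
  probs <- probs / sum(probs)
  structure(
    list(n_panellists = as.integer(n_panellists), probs = probs,
         p_agree = sum(probs[4:5]), missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "consensus_profile"
  )
}

#' Canonical profiles targeting each decision branch
#'
#' Convenience profiles whose response distributions make a given verdict
#' overwhelmingly likely for a panel of the profile's size: `"retain"`
#' concentrates mass on 4-5 (median 5, P25 >= 4), `"modify"` yields a
#' median of 4 with a P25 below 4 (about 65% agreement), and `"exclude"`
#' concentrates mass on 1-3 (median <= 3).
#'
#' @param branch One of `"retain"`, `"modify"`, `"exclude"`.
#' @inheritParams consensus_profile
#' @return A `consensus_profile`.
#' @export
branch_profile <- function(branch = c("retain", "modify", "exclude"),
                           n_panellists = 22L, missing_rate = 0, seed = 1L) {
  branch <- match.arg(branch)
  probs <- switch(branch,
    retain  = c(0, 0, 0.02, 0.28, 0.70),
    modify  = c(0, 0.05, 0.30, 0.45, 0.20),
    exclude = c(0.30, 0.40, 0.20, 0.08, 0.02)
  )
  consensus_profile(n_panellists = n_panellists, probs = probs,
                    missing_rate = missing_rate, seed = seed)
}

#' Generate a synthetic Likert response matrix
#'
#' Draws an items x panellists matrix of 5-point responses from a
#' [consensus_profile()]: one categorical draw per (item, panellist) cell,
#' independent across panellists, with cells knocked out at the profile's
#' missing rate (at least one response per item is always kept so that
#' statistics remain defined). Identical seeds give byte-identical
#' matrices.
#'
#' @param profile A `consensus_profile`.
#' @param n_items Number of items to generate (>= 1).
#' @param item_prefix Prefix for generated item ids.
#' @return A `likert_matrix` with `n_items * n_panellists` rows.
#' @examples
#' m <- generate_responses(consensus_profile(p_agree = 0.77, seed = 42), n_items = 3)
#' delphi_item_stats(m)
#' @export
generate_responses <- function(profile, n_items, item_prefix = "item") {
  stopifnot(inherits(profile, "consensus_profile"))
  if (n_items < 1L) abort("`n_items` must be at least 1.")
  np <- profile$n_panellists
  items <- sprintf("%s_%04d", item_prefix, seq_len(n_items))
  panellists <- sprintf("P%02d", seq_len(np))
  with_seed(profile$seed, {
    resp <- sample(1:5, n_items * np, replace = TRUE, prob = profile$probs)
    if (profile$missing_rate > 0) {
      miss <- stats::runif(n_items * np) < profile$missing_rate
      mat <- matrix(miss, nrow = n_items)
      # keep one response per item so statistics stay defined
      for (i in which(rowSums(!mat) == 0L)) {
        mat[i, sample.int(np, 1L)] <- FALSE
      }
      resp[as.vector(mat)] <- NA_integer_
    }
    likert_matrix(tibble(
      item_id = rep(items, times = np),
      panellist_id = rep(panellists, each = n_items),
      response = as.integer(resp)
    ))
  })
}

# generic names outside every catalog class: realistic non-FRID filler
.non_frid_pool <- c(
  "paracetamol", "simvastatin", "atorvastatin", "aspirin", "omeprazole",
  "lansoprazole", "levothyroxine", "metformin", "amoxicillin",
  "ascorbic acid", "folic acid", "colecalciferol", "salbutamol",
  "beclometasone", "alendronic acid", "ferrous fumarate", "allopurinol",
  "cetirizine", "loratadine", "ranitidine"
)

#' Generate a synthetic patient medication list
#'
#' Draws a medication list with a controlled falls-risk tier composition:
#' per-medication tier labels come from a multinomial over
#' `c(high, moderate, low, unknown)`, then distinct generic names are
#' sampled without replacement from the catalog members of each tier
#' (`unknown` draws from a built-in pool of non-FRID generics outside
#' every catalog class). Because names are distinct, the expected patient
#' total has the closed form
#' `n * (3 p_high + 2 p_moderate + 1 p_low)` (see [expected_total()]).
#'
#' @param n_meds Number of medications to draw (0 allowed).
#' @param tier_mix Named proportions over
#'   `c(high =, moderate =, low =, unknown =)`; must sum to 1 (missing
#'   names default to 0).
#' @param catalog An `mrf_catalog`; defaults to [mrf_catalog_v1()].
#' @param seed Integer seed.
#' @return A tibble with columns `medication` and `true_tier`, shuffled.
#' @examples
#' generate_med_list(5, c(high = 1), seed = 7)
#' @export
generate_med_list <- function(n_meds, tier_mix, catalog = mrf_catalog_v1(),
                              seed = 1L) {
  mix <- c(high = 0, moderate = 0, low = 0, unknown = 0)
  if (is.null(names(tier_mix)) || !all(names(tier_mix) %in% names(mix))) {
    abort("`tier_mix` must be named with tiers among high, moderate, low, unknown.")
  }
  mix[names(tier_mix)] <- tier_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    abort("`tier_mix` proportions must be non-negative and sum to 1.")
  }
  if (n_meds == 0L) {
    return(tibble(medication = character(), true_tier = character()))
  }
  pools <- c(
    lapply(c("high", "moderate", "low"), function(t) {
      unique(unlist(catalog$members[catalog$tier == t]))
    }),
    list(.non_frid_pool)
  )
  names(pools) <- names(mix)
  empty_requested <- mix > 0 & vapply(pools, length, integer(1)) == 0L
  if (any(empty_requested)) {
    abort(paste0("Catalog has no members for requested tier(s): ",
                 paste(names(mix)[empty_requested], collapse = ", ")))
  }
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, n_meds, mix))
    names(counts) <- names(mix)
    over <- counts > vapply(pools, length, integer(1))
    if (any(over)) {
      abort(paste0("Requested more distinct medications than available for tier(s): ",
                   paste(names(counts)[over], collapse = ", "),
                   " (reduce n_meds or broaden the mix)."))
    }
    drawn <- purrr::map2_dfr(names(counts), counts, function(t, k) {
      if (k == 0L) return(tibble(medication = character(), true_tier = character()))
      tibble(medication = sample(pools[[t]], k), true_tier = t)
    })
    drawn[sample.int(nrow(drawn)), ]
  })
}

#' Closed-form expected patient total under a tier mix
#'
#' @param n_meds Number of medications drawn.
#' @param tier_mix Named proportions as in [generate_med_list()].
#' @return Expected total score `n * (3 p_high + 2 p_moderate + p_low)`.
#' @export
expected_total <- function(n_meds, tier_mix) {
  mix <- c(high = 0, moderate = 0, low = 0, unknown = 0)
  mix[names(tier_mix)] <- tier_mix
  unname(n_meds * (3 * mix[["high"]] + 2 * mix[["moderate"]] + mix[["low"]]))
}
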