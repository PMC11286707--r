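# Fixtures built in code, plus independent oracles used to check the
# implementation (the oracles never call the functions they verify).

# -- tiny synthetic catalogs -------------------------------------------------

toy_catalog <- function() {
  mrf_catalog(tibble::tibble(
    class_id = c("alpha_high", "beta_moderate", "gamma_low"),
    name = c("alpha class", "beta class", "gamma class"),
    tier = c("high", "moderate", "low"),
    mechanism = c("sedation", "hypotension", "weak evidence"),
    members = list(c("alphadrug", "dualdrug"),
                   c("betadrug", "dualdrug"),
                   "gammadrug"),
    synonyms = list(c(branda = "alphadrug"), character(), character())
  ), version = "toy", provenance = "test fixture")
}

# one class per tier with a deep member pool, for sampling-heavy checks
wide_catalog <- function(n_per_tier = 15L) {
  mrf_catalog(tibble::tibble(
    class_id = c("wide_high", "wide_moderate", "wide_low"),
    name = paste("wide", c("high", "moderate", "low")),
    tier = c("high", "moderate", "low"),
    mechanism = "synthetic",
    members = lapply(c("h", "m", "l"),
                     function(p) sprintf("%sdrug%02d", p, seq_len(n_per_tier))),
    synonyms = list(character(), character(), character())
  ), version = "wide")
}

# one class per tier subset, with a shared drug per subset, to brute-force
# the highest-score rule over every non-empty subset of {high, moderate, low}
subset_catalog <- function() {
  tiers <- c("high", "moderate", "low")
  subsets <- unlist(lapply(1:3, function(k) {
    asplit(utils::combn(tiers, k), 2)
  }), recursive = FALSE)
  rows <- purrr::imap_dfr(subsets, function(sub, i) {
    drug <- paste0("drug", i)
    tibble::tibble(
      class_id = paste0("cls_", i, "_", sub),
      name = paste0("class ", i, " ", sub),
      tier = sub,
      mechanism = "synthetic",
      members = list(drug),
      synonyms = list(character())
    )
  })
  list(catalog = mrf_catalog(rows, version = "subsets"),
       subsets = subsets,
       drugs = paste0("drug", seq_along(subsets)))
}

# -- independent oracles -----------------------------------------------------

# weighted-average quantile at position (n+1)p, interpolated by hand
oracle_quantile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  pos <- (n + 1) * p
  if (pos <= 1) return(x[1])
  if (pos >= n) return(x[n])
  lo <- floor(pos)
  x[lo] + (pos - lo) * (x[lo + 1] - x[lo])
}

# midpoint median by hand
oracle_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# consensus verdict re-derived from first principles
oracle_verdict <- function(x, final_round) {
  med <- oracle_median(x)
  p25 <- oracle_quantile(x, 0.25)
  if (med >= 4 && p25 >= 4) return("retain")
  if (med <= 3) return("exclude")
  if (final_round) "exclude" else "modify"
}

# all multisets of {1..5}^n (order-free response vectors) via stars and bars
likert_multisets <- function(n) {
  cmb <- utils::combn(n + 4L, n)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j] - 0:(n - 1L))
}

# demographics of the 22-member validation panel (counts from the published
# characteristics table; percentages asserted against its printed values)
panel_counts <- function() {
  tibble::tribble(
    ~group, ~category, ~count,
    "country", "United Kingdom", 7,
    "country", "Canada", 5,
    "country", "USA", 2,
    "country", "Ireland", 2,
    "country", "Australia", 1,
    "country", "Belgium", 1,
    "country", "Sweden", 1,
    "country", "Malaysia", 1,
    "country", "Turkey", 1,
    "country", "France", 1,
    "employment", "Academic/researcher", 10,
    "employment", "Clinical academic doctor", 5,
    "employment", "Doctor", 4,
    "employment", "Pharmacist", 2,
    "employment", "Clinical academic pharmacist", 1,
    "experience", "1-5 years", 2,
    "experience", "6-10 years", 4,
    "experience", "11-15 years", 2,
    "experience", "More than 15 years", 14,
    "education", "PhD", 11,
    "education", "MSc", 1,
    "education", "MD", 4,
    "education", "Doctor of pharmacy", 2,
    "education", "Graduate/professional degree", 4
  )
}
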