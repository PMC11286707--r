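---
title: "Methods: the MRF score and its Delphi consensus engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MRF score and its Delphi consensus engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrfscore)
library(dplyr)
```

## The screening and scoring model

Medication use is an established, modifiable risk factor for falls in older
people. The Medication-Related Fall (MRF) tool screens a patient's
medication list against an explicit catalog of fall-risk-increasing
medication classes and converts it into a single score usable to prioritise
patients for medication review.

The model is deliberately simple:

* Every catalog class carries a falls-risk **tier** with a fixed point
  value: **high = 3**, **moderate = 2**, **low = 1**. The tier definitions
  (presented with every survey round during the tool's validation) are:
  high-risk classes *may commonly cause or contribute to falling risk* on
  their own or in combination; moderate-risk classes *may cause falls
  especially in combination*; low-risk classes *possibly cause falls*,
  particularly in combination.
* A drug listed in more than one class contributes the **highest** of its
  class scores (never the sum of them).
* The patient total is the **sum** of per-medication contributions. The
  same generic drug listed as several products is scored once: the tool
  scores medications, not prescription lines.
* A patient taking **any** high- or moderate-risk medication is flagged
  for a medication review and fall-prevention referral. No numeric total
  threshold is built in, because the predictive validity and risk
  threshold of the total score remain open questions; the command-line
  interface exposes an optional user-set `--threshold` instead.
* Tier definitions mention combination effects, but the arithmetic is a
  plain sum: no interaction terms, and no dose-, duration- or
  route-dependent adjustment.

```{r worked}
s <- score_patient(c("Furosemide 40mg tablets", "bendroflumethiazide",
                     "amlodipine", "digoxin", "ascorbic acid"))
glance(s)
```

## The packaged catalog and its provenance

The shipped catalog (`mrf_catalog_v1()`,
`inst/extdata/mrf_catalog_v1.json`) is the final consensus-validated
version of the tool: **19 medication classes — 10 high-risk, 8
moderate-risk, 1 low-risk**. The catalog file is deliberately a single
human-editable JSON document with explicit `version` and `provenance`
fields, so the tool's clinical content can be audited and amended without
code changes.

Fifteen of the 19 classes are transcribed directly from the published
description of the final tool (for example: loop diuretics,
first-generation anti-epileptics and non-selective alpha-blockers are
high-risk; thiazides, beta-blockers, ACE inhibitors/ARBs, dihydropyridine
calcium channel blockers and second-generation anti-epileptics are
moderate-risk). The remaining three moderate-risk classes and the single
low-risk class are not individually named in the accessible text of the
source; they were **reconstructed** from the tool's stated origin (the
NHS Scotland polypharmacy falls-risk list) as opioids, nitrates and
hypoglycaemic agents (moderate) and digoxin (low). These four carry
`reconstructed: true` in the catalog file. Users with access to the
published table can replace them by editing the JSON; every structural
check (19 classes, 10/8/1 partition) will still be enforced at load time.
Classes on which the validation panel did **not** reach consensus — SNRIs,
selective alpha-blockers, prochlorperazine, cyclizine, dopaminergic
anti-parkinsonian drugs, SSRIs and eye preparations — are deliberately
absent, and the test suite asserts their absence.

Member drug lists use generic (INN-style) names; brand names live only in
the per-class synonym tables. Membership is editorial (commonly dispensed
UK generics) and intentionally conservative.

## Drug-name normalisation

Lookup must survive the messiness of real medication lists
("FUROSEMIDE 40mg tablets") without any external terminology service, so
normalisation is deterministic and dictionary-free: case-fold and trim;
drop dose/strength tokens (numbers with or without units), formulation
tokens (tablets, capsules, m/r, ...); then strip *trailing* salt tokens
(hydrochloride, tartrate, ...). Leading salt words are preserved —
"sodium valproate" is an INN, while "valproate sodium" reduces to
"valproate" and resolves through the synonym table. The function is
idempotent, and unresolved names are never an error: they score 0, are
counted, and are flagged in reports so a reviewer sees exactly what was
not assessed. Combination products are naturally handled by the max rule:
a name resolving to several classes contributes the highest single score,
a conservative choice flagged for clinical review in reports
(`n_classes > 1`).

## The Delphi consensus engine

The tool's content validity was established by a three-round Delphi
survey: an expert panel rated agreement with each proposed class/tier
statement on a 5-point Likert scale (Strongly agree = 5 ... Strongly
disagree = 1). The engine reproduces that analysis:

* **Per-item statistics** (`item_stats()`): number of responses,
  percentage agreeing or strongly agreeing (response ≥ 4), median, P25,
  P75 and IQR. Missing responses are excluded from numerator and
  denominator alike ("percentage of respondents" semantics). Nothing is
  rounded internally; display rounding is one decimal, half away from
  zero.
* **Decision rules** (`decide_items()`):
  * **retain** iff median ≥ 4 **and** P25 ≥ 4;
  * **exclude** if median ≤ 3, in any round;
  * otherwise **modify** (re-rate next round) — except in the final
    round, where every item failing the inclusion criterion is excluded.

  Every verdict carries a `rule_trace` naming the clause that fired.
* **Rounds** (`run_delphi_round()`): modify verdicts plus newly suggested
  items are carried forward; re-rating an already-decided item is an
  error; feedback mirrors the controlled feedback of a Delphi design —
  a group summary per item plus each panellist's own responses. Turning
  free-text comments into new survey items is human judgement and stays a
  manual input (`new_items`), never computation.

### Numerical conventions and edge cases

* **Quantile interpolation.** No interpolation convention is universal.
  We adopt weighted-average interpolation at position $(n+1)p$ — the
  default definition in SPSS, the software used in the tool's validation
  analysis — which is `stats::quantile(type = 6)`. The method is exposed
  as `quantile_method` ("weighted-average" or "linear"). For
  responses $(2,3,4,4,4,5,5)$, position $(7+1)\cdot0.25 = 2$ gives
  P25 = 3. The validation study's printed contested-class statistic
  (P25 = 3.8 with 22 raters) is not exactly reconstructible from integer
  responses under common conventions without the raw data; we therefore
  never force agreement with it, but feeding the printed statistics
  (median 4, P25 3.8) into the final-round rule reproduces the published
  verdict: not included.
* **Even panels.** The median of an even number of integer responses can
  be non-integer. Retention is implemented as median ≥ 4, so a median of
  4.5 qualifies. A median strictly between 3 and 4 satisfies none of the
  three stated clauses; it is treated conservatively as modify (exclude
  in the final round), and the rule trace records that no stated clause
  applied.
* **P25 gate vs 75% agreement.** The inclusion rule is commonly glossed
  as "at least 75% of respondents agreeing or strongly agreeing". The
  two readings are *nearly* equivalent but not identical under
  interpolation: exhaustive enumeration of all response multisets up to
  $n = 8$ finds 83 boundary cases, all in one direction — agreement
  exactly at or just above 75% while the interpolated P25 falls below 4
  (e.g. $(3,4,4,4)$: agreement 75%, P25 = 3.25). The P25 rule is the
  operative criterion here; agreement% is reported descriptively.

## The synthetic-data generators

No raw panel responses are published, so the package ships seeded
generators that emulate the study's design for testing and calibration:

* `generate_responses()` draws one categorical response per
  (item, panellist) cell, independent across panellists — an anonymous
  panel design argues for independence. A `consensus_profile()` is
  parameterised either by an explicit distribution over 1..5 or by a
  target agreement probability `p_agree`; in the latter case the
  agreement mass is split evenly between 4 and 5 and the remainder spread
  0.5/0.3/0.2 over 3/2/1, a unimodal shape typical of expert panels near
  consensus. Defaults mirror the study conditions: 22 panellists, 5-point
  scale. Missing responses are knocked out independently at
  `missing_rate` (an item is never left with zero responses). Identical
  seeds give byte-identical matrices; every generator call uses a single
  pseudorandom stream keyed by its seed and restores the caller's RNG
  state.
* `generate_med_list()` draws per-medication tiers from a multinomial
  over `c(high, moderate, low, unknown)` and then samples *distinct*
  generic names without replacement within each tier (unknowns come from
  a built-in pool of non-FRID generics). Distinctness keeps the expected
  patient total in closed form,
  $E[\text{total}] = n(3p_h + 2p_m + p_l)$, exact even after
  dedup-by-normalised-name; the trade-off is that a requested tier can
  exhaust its member pool (an error suggesting a smaller list or broader
  mix). Note the packaged catalog has a single low-risk drug, so mixes
  with substantial `low` mass are best exercised against a synthetic
  catalog with deeper pools, as the tests do.

What the generators do **not** emulate: rater correlation, learning or
anchoring across rounds, panel attrition, and the qualitative
comment-sorting that produced new items between rounds. Passing tests
therefore demonstrate the correctness of the statistics and decision
rules and the calibration of the generators — not that the package would
reproduce a real panel's round-by-round trajectory.

Interesting realism check, computed rather than asserted: at the study's
panel size (22) and overall agreement level (0.77), generated items
frequently land exactly in the modify/exclude boundary region with P25
around 3.75–3.8 — the region the validation study reported for its
contested classes.

## Problem sizes and determinism

The test-suite and acceptance-script simulation sizes were chosen as the
smallest at which the checked properties are statistically stable:
exhaustive rule enumeration up to $n = 8$ raters (1,286 response
multisets, checked in both round modes); 500 items × 22 panellists for
agreement calibration (binomial SE ≈ 0.4 percentage points); 300 items
per point on a five-point agreement grid for retention monotonicity; 120
generated six-drug lists for the closed-form mean check. All stochastic
checks run under fixed seeds and compare against sampling-error bounds
computed from first principles, never against tuned constants.

## Known limitations

* The four reconstructed catalog classes are editorial until replaced by
  a verbatim transcription; counts and all named inclusions/exclusions
  are honoured regardless.
* No ATC/RxNorm/SNOMED coding: synonym coverage is only as good as the
  catalog's synonym tables.
* The score is a screening prioritiser. Its predictive validity and any
  total-score threshold are explicitly out of scope, as is any dose,
  duration, renal-function or orthostatic-vitals adjustment.
* Combination products score as one entry under the max rule; whether
  they should count as two medications is a clinical judgement the
  report surfaces but does not make.
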