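# mrfscore

Medication-related falls-risk screening and scoring, with the Delphi
consensus machinery used to content-validate such tools.

Falls are a leading cause of injury and hospital admission in older
people, and fall-risk-increasing drugs (FRIDs) are one of the few
modifiable risk factors. The Medication-Related Fall (**MRF**) screening
and scoring tool is an explicit catalog of 19 medication classes in three
falls-risk tiers; `mrfscore` implements it end to end for clinical
pharmacists, medicines-optimisation services and researchers:

* **The catalog** — the validated 19-class tool (10 high-risk, 8
  moderate-risk, 1 low-risk) shipped as an auditable JSON file, with
  loading, schema validation and deterministic drug-name lookup
  (case/dose/salt normalisation plus a synonym table; no external
  terminology service).
* **The score** — for a patient on medications $m_1,\dots,m_k$ with
  deduplicated generic names,

  $$\mathrm{MRF} = \sum_i \max_{c \,\ni\, m_i} s(c), \qquad
    s(c) \in \{3 \text{ (high)},\ 2 \text{ (moderate)},\ 1 \text{ (low)}\},$$

  i.e. each medication contributes the highest score among the classes
  that list it, and the patient total is the plain sum. Any high- or
  moderate-risk medication raises a referral flag for medication review
  and fall-prevention strategies.
* **The Delphi engine** — per-item 5-point Likert statistics (agreement
  %, median, P25/P75/IQR with the weighted-average interpolation
  convention), the consensus decision rules (retain iff median ≥ 4 and
  P25 ≥ 4; exclude if median ≤ 3; otherwise modify, tightening to
  exclude in the final round), multi-round orchestration with per-item
  and per-panellist feedback, and panel demographics summaries.
* **Seeded generators** — synthetic panel response matrices with
  controlled agreement and synthetic medication lists with controlled
  tier mixes, so everything is testable offline.

All user-facing functions take data frames and return tibbles; fitted
results have `tidy()`, `glance()` and `autoplot()` methods; a thin CLI
(`exec/mrf`) exposes `score`, `catalog validate`, `delphi analyze` and
`simulate`.

## Worked example

```r
library(mrfscore)

s <- score_patient(c("Furosemide 40mg tablets", "bendroflumethiazide",
                     "amlodipine", "digoxin", "ascorbic acid"))
s
#> <mrf_patient_score> total = 8 points; 4 scored medication(s) (high 1, moderate 2, low 1)
#>   unresolved (contribute 0): 1
#>   referral advised: patient takes high- or moderate-risk medication(s)
```

Furosemide (loop diuretic, high risk) contributes 3 points,
bendroflumethiazide and amlodipine (thiazide and dihydropyridine CCB,
moderate) 2 each, digoxin (low) 1 — total 8 — and ascorbic acid is outside
every catalog class, so it contributes 0 but is reported rather than
silently dropped. Because the patient takes high/moderate-risk
medications, a medication-review referral is advised. `tidy(s)` gives the
per-medication breakdown, `glance(s)` the one-row summary,
`render_report(s, "json")` a lossless machine-readable report, and
`autoplot(s)` the contribution chart.

The consensus side works the same way:

```r
m <- generate_responses(consensus_profile(p_agree = 0.77, n_panellists = 22,
                                          seed = 42), n_items = 5)
run_delphi_round(m, round_number = 3)
#> <mrf_round_result> round 3 of 3 (final): 5 item(s) — retained 1, modified 0, excluded 4; 0 carried forward
```

From the command line:

```sh
mrf score --meds patient.txt --format json
mrf catalog validate packaged
mrf delphi analyze --responses round3.csv --round 3 --format json
mrf simulate responses --items 50 --p-agree 0.77 --seed 7 --out round.csv
```

Exit codes: 0 success, 2 validation/usage failure, 1 unexpected error.

See `vignettes/mrf-methods.Rmd` for the model's assumptions, the
catalog's provenance (including which four classes are reconstructed
rather than transcribed), the quantile convention, decision-rule edge
cases, and what the synthetic generators do and do not emulate.

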