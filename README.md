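# surveyguard

Rule-based screening of fraudulent submissions to small web-based health
surveys.

Web surveys of small, hard-to-reach populations — the motivating case is a
cohort of older gay and bisexual prostate-cancer survivors recruited online —
are attractive targets for compensation-seeking spam. When a majority of
submissions can be fraudulent, and no external registry exists to verify
respondents, validity rests entirely on a deduplication and cross-validation
protocol applied to the submissions themselves. `surveyguard` packages such a
protocol as reusable, tested code for analysts who must adjudicate a
submissions table after (or during) a recruitment wave.

## The method

Each submission is scored against a registry of suspicion indicators
("strikes") in four families:

- **Deduplication signals** computed over the whole batch: shared IP
  addresses; email handles whose run-length character-class signature (e.g.
  `abc123` → `L3D3`) clusters on one host domain; submissions that start
  within seconds of another's end (chained entries); completion in the early
  hours of the local morning; identical improbable values (e.g. a shared
  impossible birth date).
- **Metadata plausibility**: completion faster than 30 minutes for a 45–60
  minute instrument; an IP-derived region that contradicts the respondent's
  zip-code region (resolved offline against a bundled lookup table).
- **Clinical plausibility** for a prostate-cancer instrument: diagnosis age
  under 40 (observed spam claimed 18–35), PSA > 20 ng/mL, Gleason total > 6,
  all core clinical items "forgotten", impossible treatment orderings
  (prostatectomy followed by watchful waiting), treatment/provider mismatches
  (radiation from a urologist), orientation-specific rehabilitation without
  provider disclosure, and discrimination reported only on peripheral
  attributes.
- **Response style** (the classic eight suspicious-survey characteristics):
  straight-lining in grids, high item nonresponse, blank/gibberish/duplicated
  free text, all options of a multiple-response block selected, failed
  instructed-verification items.

Strikes are combined by a *k*-strikes rule (default k = 3, and k ≥ 2 is
enforced): no single indicator can invalidate a complete submission. A
submission with strikes s is

- **invalid** if it is incomplete, or s ≥ k,
- **review** (queued for a human) if 1 ≤ s < k,
- **valid** if s = 0.

Because spam *evolves* — later waves in the motivating study kept plausible
clinical values while retaining their metadata signatures — the protocol is
versioned: each configuration carries an effective window, a retrospective
pass re-applies one uniform final configuration after recruitment, and a
drift monitor tracks per-rule hit rates among flagged submissions in rolling
windows, alerting when a rule's rate jumps between windows.

A seeded synthetic-cohort generator produces valid respondents (age from a
truncated normal calibrated to mean 63.42 y, SD 8.19 y on [40, 95]; 45–60
minute durations; geo-consistent IPs; personalised emails) and labelled spam
waves — blatant "naive" spam and "evolved" spam that only metadata can
convict — including a dual-link diversion scenario, so the full pipeline is
verifiable without any external data.

## Worked example

```r
library(surveyguard)

sc <- cohort_scenario(
  n_valid = 120,
  waves = list(
    list(start_day = 5,  n = 40, profile = "naive",   channel_id = "A"),
    list(start_day = 40, n = 30, profile = "evolved", channel_id = "A")
  )
)
cohort    <- generate_cohort(sc, seed = 7)
decisions <- run_protocol(cohort$records, default_rule_config(), default_geo_table())

table(decisions$status)
#> invalid   valid
#>      70     120

confusion_metrics(decisions, cohort$labels)
#> <evaluation_summary>
#>   190 submissions: 120 valid / 0 review / 70 invalid (36.8% invalid)
#>   confusion (spam positive): TP=70 FP=0 TN=120 FN=0
#>   sensitivity 1.0000, specificity 1.0000, ppv 1.0000
```

All 70 spam records (both waves) accumulate at least three strikes and are
rejected; no genuine respondent is flagged. The drift monitor, run on the
spam decisions, shows why the protocol must be dynamic — between the naive
window and the evolved window every clinical and response-style rule
collapses to a hit rate of 0 while the email-convention, adjacency and
odd-hour signatures persist (no alert is raised for them):

```r
spam_ids <- cohort$labels$submission_id[cohort$labels$label != "valid"]
monitor_drift(decisions[decisions$submission_id %in% spam_ids, ])
#> <drift_report> 2 window(s), 14 alert(s)
#>   geo_mismatch: 1.00 -> 0.00 at window 5
#>   psa_implausible: 0.40 -> 0.00 at window 5
#>   treatment_sequence: 1.00 -> 0.00 at window 5
#>   straight_lining: 1.00 -> 0.00 at window 5
#>   ...
```

The generated valid cohort matches the demographic model it emulates:

```r
summarize_cohort(cohort$records[cohort$labels$label == "valid", ])
#>       n n_age mean_age sd_age treated_fraction
#> 1   120   120     63.8   8.43            0.692
```

A command-line wrapper over the same functions lives at
`inst/scripts/validate.R`:

```sh
Rscript inst/scripts/validate.R --in submissions.csv --config rules.json \
        --out decisions.csv --audit audit/
```

It writes the decision table, the manual review queue, a reject file for
malformed rows, and a Markdown + JSON audit report with a per-record
case-study narrative.

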