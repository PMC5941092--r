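---
title: "Methods: screening fraudulent web-survey submissions with surveyguard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening fraudulent web-survey submissions with surveyguard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveyguard)
```

## The screening model

`surveyguard` adjudicates web-survey submissions with a rule-based,
human-in-the-loop protocol rather than a learned classifier. The design
assumption is a small study (hundreds of submissions, not tens of
thousands) of a hard-to-reach population, where no external registry can
verify respondents and where the cost of rejecting a genuine participant is
high. Three consequences follow:

1. **Evidence accumulates; nothing convicts alone.** Every indicator is a
   *strike*, and a complete submission is auto-invalidated only at
   `strike_threshold_k` strikes (default 3). The configuration refuses
   k < 2 outright: any single indicator — a shared IP (couples share
   routers), a fast completion (skip patterns exist), a Gleason score of 7
   (clinically common) — has innocent explanations. Submissions with 1 to
   k−1 strikes go to a *review queue* for human adjudication; the package
   never auto-resolves them.
2. **Incomplete submissions are invalid by rule**, regardless of strikes.
   This mirrors an a-priori analysis-inclusion criterion, not a fraud
   judgement.
3. **The protocol is dynamic.** Configurations are versioned with effective
   windows; a retrospective pass re-applies one uniform final configuration
   so that mid-study rule changes cannot leave the analysed dataset
   inconsistently screened; and a drift monitor watches for spam evolving
   past one rule family while another keeps firing.

## Indicator registry

`rule_registry()` enumerates every rule with a category and, for the
per-record rules, the classic suspicious-survey characteristic it
operationalises. The per-record indicators cover exactly the eight
characteristics of the Baker/Downes-Le Guin taxonomy; the dataset-level
deduplication signals (duplicate IP, email convention, temporal adjacency,
odd hour, shared anomaly) are deduplication evidence and carry no
taxonomy tag.

```{r}
rule_registry()
```

Two operationalisations deserve comment:

- **Email convention.** The handle is reduced to a run-length
  character-class signature (letters, digits, other): `abc123` → `L3D3`,
  `john.smith` → `L4O1L5`. A cluster of `email_cluster_min` (default 3)
  submissions sharing (host domain, signature) is flagged. This captures
  "generated batch" conventions without hard-coding any single pattern,
  while personalised handles spread across many signatures.
- **All-options-selected.** The instrument's multiple-response block is
  realised on the discrimination inventory: a strike fires when the
  selected set covers the entire configured vocabulary (peripheral ∪ core
  attributes). The schema has no separate screener multi-select field, so
  no extra column was introduced for this rule.

## Tunable parameters

All thresholds live in one `rule_config` object, serialisable to JSON/YAML;
absent keys take the defaults below, unknown keys are rejected by name.

| parameter | default | units | rationale |
|---|---|---|---|
| `duration_min_minutes` | 30 | min | speeding floor for a 45–60 min instrument; strict inequality (exactly 30 does not strike) |
| `relative_speed_fraction` | 1/3 (off by default) | — | optional cohort-relative speeding test against the batch median |
| `age_dx_min` | 40 | years | diagnosis under 40 is of order 1-in-10,000 for prostate cancer; generalises the 18–35 range observed in spam |
| `psa_max` | 20 | ng/mL | PSA at diagnosis above this is statistically unlikely |
| `gleason_max` | 6 | — | listed in the protocol although Gleason 7 is common; mitigated by k ≥ 2 (a lone Gleason strike can never invalidate) |
| `grid_min_items` | 5 | items | grids shorter than this are exempt from the differentiation index |
| `differentiation_threshold` | 0.2 | — | distinct/answered at or below this is straight-lining |
| `nonresponse_threshold` | 0.2 | fraction | missing grid items above this strikes (strictly greater) |
| `gibberish_vowel_fraction` | 0.5 | fraction | tokens bearing a vowel below this is gibberish |
| `email_cluster_min` | 3 | records | convention clusters need 3 members |
| `adjacency_gap_seconds` | 60 | s | operationalises "seconds after"; the field reports no number, so it is configurable |
| `odd_hour_window` | 00:00–05:00 | local clock | half-open; "early hours of the morning" |
| `shared_anomaly_min` | 3 | records | identical-improbable-value groups need 3 members |
| `strike_threshold_k` | 3 | strikes | the k-strikes rule; k ≥ 2 enforced |
| `drift_window_days` / `drift_delta` | 7 / 0.3 | days / rate | rolling window width and alert jump size |

No quantitative threshold exists in the source protocol for nonresponse or
differentiation; the 0.2 defaults are this package's choice, exposed in the
configuration precisely because they are choices.

## Timestamps, eras and the dedup context

Timestamps are stored as ISO-8601 strings with explicit UTC offsets. The
odd-hour rule reads the *wall clock as written* (completion at 02:30 local
is suspicious wherever the server lives); adjacency and duration use the
absolute instant. Duration is always recomputed from the timestamps when
both are present — a supplied duration column is a fallback, never an
override, so there is a single source of truth.

Era assignment uses the submission's end date (local calendar date): a
record becomes adjudicable when it completes. Effective windows of a
configuration history must be disjoint, and a record outside every window
is an error naming the record — silent fall-through would un-screen it.

The deduplication context is built **once** over the whole batch. With a
multi-era history the context's thresholds come from the final era's
configuration — the most refined form of the protocol — while each era's
`enabled_rules` still controls which strikes are admitted for its records.
The alternative (one context per era) would make group membership depend on
which era a *neighbouring* record fell in, which is harder to audit.

Drift hit rates are computed *among flagged submissions* (records with at
least one strike), not among all submissions, so a change in spam style is
visible even as spam volume varies. Windows with no flagged submissions are
skipped; alerts compare consecutive non-empty windows.

## The synthetic cohort generator

The generator emulates the study conditions the toolkit was built around:

- **Valid respondents.** Age is sampled from a truncated normal on
  [40, 95] years. The parent (μ, σ) are solved numerically so that the
  *truncated* distribution has exactly the target moments (mean 63.42 y,
  SD 8.19 y): truncating a normal(63.42, 8.19) at those bounds would
  shrink the realized SD by about 0.08 y, so the parent σ sits slightly
  above the target. Sampling is by inverse CDF, which keeps the stream
  reproducible. Durations are uniform on 45–60 min with daytime (08:00–22:00
  local) completion; IPs are distinct and consistent with the zip region in
  the bundled synthetic geo table; emails are personalised with varied
  handle shapes; grids are varied, text prompts answered, verification
  items passed; 69.4% report successful treatment.
- **Naive spam** triggers many indicators by construction: 5–25 min
  durations, diagnosis ages 18–35 *or* wholly "forgotten" clinical items,
  PSA 21–45, Gleason 7–10, an impossible treatment sequence with a
  provider mismatch, disclosure-inconsistent rehabilitation,
  peripheral-only discrimination, straight-lined grids, blank text, failed
  verification, one shared birth date, convention emails on a single host,
  shared IPs inconsistent with the claimed zip, and chained submissions in
  the 00:00–05:00 window. Any subset of three suffices for rejection, so
  sensitivity on naive waves is 1 by construction.
- **Evolved spam** draws every *response* field from the valid
  distributions — under a clinical-rules-only configuration it is
  indistinguishable from genuine respondents — but keeps the scenario's
  metadata signatures (default: email convention, temporal adjacency,
  odd-hour completion; at least three required) plus the short duration.
  This is the drift-detection fixture: clinical hit rates collapse between
  a naive and an evolved wave while the metadata rates persist.
- **Dual-link diversion** routes all valid records completing on or after
  `diversion_day` to channel B while spam stays on channel A, emulating
  the countermeasure of leaving a compromised link open as a honeypot.

Random streams are split per block: the valid cohort is drawn first under
the scenario seed, then each wave under a seed derived from (seed, wave
index). Adding a wave therefore never perturbs the valid records at a fixed
seed, and a fixed seed yields byte-identical cohorts and reports.

**What the generator does not emulate**: reCAPTCHA solving, browser
fingerprints, VPN exit nodes, cookie behaviour (ballot-box cookies are a
boolean field only), partial-completion patterns, or spam that mimics
personalised email handles. A pass on synthetic data therefore shows the
pipeline implements the protocol faithfully — it does not show the protocol
defeats every real-world adversary, and the drift monitor exists precisely
because real spam moved.

## Numerical and degenerate-input choices

- Presentation percentages use **half-up** rounding at the requested number
  of decimals (base R's `round()` is round-half-even); internal values are
  never rounded.
- The adjacency gap test is on the half-open interval (0, gap]: a
  submission starting the very second another ends *is* flagged at gap 60,
  a simultaneous end/start (gap 0) is not. The flagged set equals the
  brute-force all-ordered-pairs check, implemented with a sorted
  end-time index.
- The odd-hour window is half-open: an end at exactly 05:00 does not strike.
- The truncated-normal moment match minimises squared moment error with
  Nelder–Mead to a relative tolerance of 1e-12; the objective is smooth and
  the solution is unique in the relevant region.
- Geo lookups are total functions: an unresolvable IP prefix or zip yields
  `"unknown"`, and an unknown on either side produces *no* strike (absence
  of evidence is not evidence).
- Malformed rows (unparseable timestamps, end before start, Gleason outside
  2–10, negative PSA, malformed zip, duplicate submission id) are
  quarantined to a reject table with the row number and violated
  invariant — one bad row never aborts a batch.
- A cohort of one record reports its age SD as missing; an empty decision
  table is an error for `proportion_invalid` (0/0 has no meaning) but fine
  for `write_decision_table` (header-only CSV).
- Fewer than two non-empty drift windows yield an empty report with no
  alerts rather than an error, since early in a study this is the normal
  state.

## Problem sizes

The test suite exercises dedup oracles on batches up to 50 records
(where brute-force all-pairs comparison is the reference), detector
properties on cohorts of 100–290 records — the scale of the studies this
protocol targets — and demographic parameter recovery on a valid cohort of
100,000, where the sample mean and SD of age land within ±0.1 years of the
63.42/8.19 targets. The acceptance script regenerates that 100,000-record
cohort from scratch at the supplied seed.

## Known limitations

- The email-signature heuristic can cluster three genuine respondents whose
  handles coincide in shape and host; at a few hundred records this affects
  on the order of 1–2% of valid submissions and yields a single dedup
  strike — review status at most, never auto-invalidation.
- The gibberish heuristic (vowel-bearing token fraction plus verbatim
  duplication) is deliberately simple and pluggable; the symptom is named
  by the field, the method is not.
- One screener state is stored per submission; reconstructing repeated
  entry attempts with changing screener answers is future work.
- The forbidden-transition and provider-compatibility matrices are the
  minimal sets reproducing the documented examples; a study's own clinical
  expert should extend them through the configuration.
- Review-status records are counted as *not invalid* in confusion metrics
  by default (they were resolved by human contact in the motivating study);
  `review_as_invalid = TRUE` gives the strict reading.
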