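---
title: "Scoring methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of how CAPL-2 scoring works,
which choices were genuinely open when it was built, and what its tests do
and do not establish.

## The scoring procedure

CAPL-2 assesses physical literacy in 8–12-year-olds across four domains.
Each domain score is a sum of component scores with a single-missing
reweighting rule; the overall score is the same construction over the four
domains.

**Physical competence (/30).** Three 10-point protocol scores. The PACER
shuttle run is scored `min(floor(laps_20m / 5), 10)`; laps run on a 15 m
course are first converted to a 20 m equivalent via a lookup chart, and
only whole lap counts in 1–229 are accepted. The plank hold earns one
point per 12 seconds, capped at 10. Each CAMSA obstacle-course trial
combines a 0–14 skill-checklist score with a 1–14 binned time score into a
1–28 skill+time score; the better of the two trials divided by 2.8 gives
the 0–10 CAMSA score. Both trials are required: the protocol is defined as
the maximum *over two trials*, so one missing trial makes the CAMSA score
missing rather than silently scoring a single attempt.

**Daily behaviour (/30).** A week of pedometer logs is validated day by
day: wear time is `time_off − time_on − non_wear/60` decimal hours (missing
non-wear counts as zero; inverted or missing on/off pairs invalidate the
day), and a day is valid when its step count is a whole number in
1,000–30,000 *and* wear time is at least 10 h. At least four valid days are
needed for a step average. "Fewer than four" is resolved as: exactly three
valid days → impute a fourth by sampling one of the three values uniformly
(the rule presupposes three existing valid days); two or fewer → missing.
The average maps through monotone bins to a 0–25 step score, and the
self-reported active-days item (0–7) maps to 0–5 (capped at 5 by default).
Unlike every other domain, daily behaviour has **no** reweighting: either
part missing makes the domain missing. This asymmetry is deliberate — the
reference outputs for this domain show missing wherever either part is
missing, and a two-component domain reweighted from one component would
just rescale a single protocol.

**Motivation and confidence (/30).** Four 7.5-point subscales. The two
CSAPPA subscales (predilection: items 1/3/5; adequacy: items 2/4/6) map
each 4-level response onto `{0.6, 1.2, 1.8, 2.5}` points. This map is the
unique 4-level map consistent with the documented subscale range
(1.8–7.5) and every observed subscale value (for instance 5.4 = 3 × 1.8
rules out nearby alternatives). The two BREQ subscales award half the 1–5
response per item (1.5–7.5 per subscale).

**Knowledge and understanding (/10).** Four 1-point multiple-choice items,
scored against answer keys that accept either the response code or the
verbatim answer string, plus a fill-in-the-blanks story scored 0–6. The
0–6 range contradicts one prose description of the instrument ("zero to
five") but is required by the observed score values (which include 6) and
by the domain's 0–10 total (4 × 1 + 6); we treat the prose as an erratum.
A blank left empty scores 0 rather than propagating missingness — the
fill-in score is a count, and the reference outputs contain no missing
values for it even where other fields are missing.

**Reweighting.** With components `c_1..c_k` of maxima `m_1..m_k` and total
`M = Σ m_i`, a domain with exactly one missing component `c_j` is scored
`(Σ available) × M / (M − m_j)`; with two or more missing it is missing.
The same rule scores the overall 0–100 physical literacy total over
(pc, db, mc, ku) with maxima (30, 30, 30, 10).

**Interpretation and status.** Interpretive categories (beginning <
progressing < achieving < excelling) are looked up in a normative table by
protocol × gender × integer age, with `[lower, upper)` intervals and the
top interval closed at the protocol maximum, so a perfect score is
`excelling`, not out of range. The plank is normed on the raw hold time in
seconds rather than its 0–10 score — the lookup input is per-protocol
configurable for this reason. Domain status is classified by strict
precedence: missing score → `incomplete`; else missing interpretation →
`missing interpretation`; else any missing component → `missing protocol`
(possible because reweighting can produce a score despite a missing
component); else `complete`. This is the only precedence ordering
consistent with the reference status outputs.

## Quiet validation

Raw field data are messy, so validators are total functions: any scalar in,
a value or `NA` out, never an error. Ages coerce numeric strings, accept
[8, 12], and floor (age-specific lookups are keyed on integer age; 8.5 is a
valid 8-year-old, 12.9 is out of the validated range). Gender accepts the
case-insensitive synonym sets {girl, g, female, f, 1} and
{boy, b, male, m, 0}. Scale items coerce numeric strings and accept whole
numbers in range. Clock times accept exactly two dialects — `H:MM am/pm`
and 24-hour `HH:MM[:SS]` — plus numeric decimal hours in [0, 24); no
locale-aware parsing. Errors are reserved for programming mistakes:
unknown protocol names, mismatched rename vectors, unreadable files, and
invalid configs all raise.

## Tunable parameters

All protocol constants live in `inst/extdata/scoring-config.json`
(override via `capl_config(path)`):

| Table | Units | Default | Status |
|---|---|---|---|
| `pacer$laps_per_point`, `max_score` | laps, points | 5, 10 | recovered from reference outputs |
| `pacer$valid_lap_range` | 20 m laps | [1, 229] | documented |
| `pacer$conversion_15m` | laps → laps | `max(1, floor(n·15/20))` chart | **provisional/synthetic** |
| `plank$seconds_per_point` | s/point | 12 (cap 10) | **provisional** (consistent with all reference integer scores) |
| `camsa$time_bins` | s → 1–14 pts | ≤14 s = 14, +2 s/−1 pt, >38 s = 1 | **provisional** |
| `steps` bounds | steps/day, h | 1,000–30,000; ≥10 h | **provisional** |
| `steps$bins_lower` | steps/day → 1–25 | 3,000 + 625·(k−1) | **provisional** |
| `self_report$map` | days → points | `min(days, 5)` | **provisional** |
| `csappa$points`, orientations | points | {0.6, 1.2, 1.8, 2.5}; items 3, 4 reversed | map recovered; **orientations provisional** |
| `answer_keys` | — | documented codes/strings | documented |
| `fill_in_the_blanks` | — | six one-word keys | **provisional/synthetic** |

The normative table (`inst/extdata/norms-synthetic.csv`, override via
`capl_norms(path)`) is likewise a synthetic stand-in — the real thresholds
derive from a normative cohort of over 10,000 Canadian children and are
manual content. The synthetic defaults place category cut points at 35 % /
55 % / 75 % of each score range, drifting +2 % per year of age and +1 %
for boys on fitness protocols, and plank thresholds at 40/80/130 s for
8-year-olds growing with age. These are *shape-realistic placeholders*:
interpretation outputs under packaged norms are structurally correct
(validated partitions, correct lookup semantics) but not normatively
meaningful, which is why every interpretation test injects toy norms with
hand-checkable cut points. Users with the manual must supply the real
tables before interpreting children.

## The demo-data generator

`capl_demo_data()` emulates what field teams actually submit: ages 8–12;
gender under sixteen mixed encodings; PACER laps on both course lengths;
plank holds 0–300 s; CAMSA skill/time pairs; step counts 500–30,000
(deliberately including counts below the validity floor); clock strings in
both dialects with on-times in the morning and off-times in the evening;
Likert items; knowledge items answered sometimes by code, sometimes
verbatim (15 % of responses use the correct verbatim string); and every
cell independently missing with probability 0.05. It does **not** emulate
real covariance structure — fitness, motivation and knowledge are
independent draws — nor systematically skewed missingness, nor
transcription errors beyond the encodings listed. A green test on demo
data therefore establishes that the scoring rules, missing-value algebra,
and plumbing are correct, not that any distributional claim about real
cohorts holds.

## Numerical choices

* Scores are reported unrounded; the CAMSA score is an exact multiple of
  1/2.8 and the tests verify `score × 2.8` is integral to 1e-9.
* Step imputation draws from one seeded generator per scoring run
  (`seed` argument, default 1), visiting records in row order; the caller's
  RNG state is saved and restored. Whether the original instrument's
  implementation redraws per call is unspecified; fixing a per-run seed
  makes results bit-reproducible.
* Norm intervals are `[lower, upper)` with the top interval closed;
  partition validation tolerates 1e-9 edge mismatches.
* Out-of-range component scores passed directly to domain functions are
  treated as invalid (missing), never clamped.
* Ages above 12 are not clamped for interpretation of older children; they
  are simply outside the validated range and return `NA`.

## Known limitations

* Packaged conversion chart, bins, fill-in-the-blanks key, and norms are
  provisional synthetic stand-ins (see above); scoring rules that *are*
  documented — pacer rule, reweighting, ranges, precedence — are exact.
* Only CAPL-2 is supported, not the first edition's protocols.
* xlsx export uses a minimal single-sheet writer (numbers and inline
  strings, no formatting); round-trip is tested against an independent
  reader.
* The reference outputs this package is regression-tested against contain
  two internal inconsistencies (a physical-competence vector computed with
  fractional CAMSA scores dropped, and a motivation-and-confidence vector
  missing one subscale); the documented formulas are implemented and only
  self-consistent reference rows serve as fixtures.
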