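---
title: "Passive smartphone sensing of depressed mood: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive smartphone sensing of depressed mood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodsense)
```

# The problem

Self-report depression screening requires active engagement, which is
precisely what depressed patients struggle to sustain. Digital phenotyping
replaces (or augments) questionnaires with behavioural signals a smartphone
collects passively: when the screen is on, where the phone goes, how the
owner moves, and — here — a learned facial-expression embedding captured
weekly. This package implements a complete smartphone-only pipeline from raw
event tables to a depressed-mood prediction evaluated against both
questionnaire cut-points and clinician diagnosis, together with a synthetic
cohort generator that makes every stage testable without clinical data.

The behavioural features target two DSM-5 major-depression symptoms that
leave traces in sensor data — sleep change, and diminished interest and
activity — plus affect expressed in the face.

# The feature model

Each participant is reduced to a 33-dimensional vector, in the fixed order
given by `featureNames()`.

## Sleep and usage (14 features)

Nightly sleep is proxied by the **longest screen-off interval of the day**.
Screen events are deduplicated so ON/OFF alternate; every maximal OFF→ON
span is a candidate interval. Two filters remove implausible candidates:
intervals lying entirely within local 12:00–18:00 (an afternoon-only gap
cannot be night sleep — intervals merely overlapping that window survive),
and intervals longer than 24 h (logging artefacts). Days run **noon to noon
on the local clock**, candidates are assigned by interval midpoint, and the
estimate is attributed to the calendar date on which the noon-to-noon window
ends, so overnight sleep is never split across days. Days attributed past
the last fully covered noon-to-noon window are dropped: after the final
logged bedtime only daytime gaps remain, and keeping them would fabricate a
short "sleep" on a day the study no longer observed. Usage is the summed
screen-on time per local calendar day, split at midnight.

Both daily series are summarised by seven statistics — max, min, mean, SD
(n−1 denominator, 0 for a single day), and linearly interpolated quartiles
Q1/Q2/Q3 — giving 14 features in hours.

## Mobility (2 features)

GPS fixes are clustered with DBSCAN under the haversine great-circle metric.
The radius and density parameters are tunable (`featureConfig()`); the
defaults are **eps = 300 m** — about the scale of a building plus GPS error,
so home, work and other meaningful places form separate clusters — and
**min_samples = 5**, so a place must be observed repeatedly before it
counts. Cluster numbering follows timestamp order and is fully
deterministic.

* **Location entropy** (nats): −Σᵢ pᵢ ln pᵢ, where pᵢ is the fraction of
  non-noise fixes in cluster i — a count-based estimate that assumes
  approximately uniform temporal sampling of fixes. One or zero clusters
  give 0; all-noise gives a missing feature. Low entropy means homebound
  behaviour.
* **Location variance**: ln(σ²_lat + σ²_lon) in squared degrees, population
  (n-denominator) variances, floored at ε = 1e−12 deg² before the log so a
  single-place participant stays finite instead of −∞.

Logs are natural throughout. Population variance follows the σ² notation of
the feature definition; the seven-statistic summaries use the sample SD —
both choices are stated here because convention, not the data, decides them.

## Physical activity (1 feature)

Activity-transition events give ENTER/EXIT episodes for eight classes.
The feature is the mean, over observed days, of hours spent in
**stationary, running and walking** — the class set the study protocol
counts as physical activity, cycling being excluded as confusable with
vehicle travel. Whether "stationary" belongs in a physical-activity measure
is genuinely arguable; the package implements the protocol as stated and
offers a locomotion-only alternative ({walking, running, walking-or-running})
via `included_classes`, without guessing the original intent. An ENTER
left open at the window end is closed there.

## Expression (16 features)

The pipeline consumes 16-dimensional expression embeddings as data; the
embedding network itself (a metric-learning model over face images) is out
of scope and hidden behind a pluggable interface. The participant-level
representation is the element-wise mean of the weekly embeddings — the
simplest aggregate, chosen because nothing in the protocol constrains it.
`stubFaceEmbedder()` provides a deterministic unit-norm stand-in used in
tests; it is labelled a stub and claims no expression semantics.

# Labels and protocol

PHQ-9 (9 items, 0–3 each, total 0–27) labels a participant depressed at
**total ≥ 10**; CESD-R (20 items, total 0–60 in this administration)
at **total ≥ 13**, the Korean calibration. Severity bands default to the
five-band scheme (normal 0–4, minimum 5–9, mild 10–14, moderate 15–19,
severe 20–27); a six-band variant exists because published summaries of the
same instrument sometimes report six categories. Which administration (M1,
M2, M3) defines the label is configurable and defaults to baseline (M1),
since nothing in the protocol fixes it.

The cohort is split once at 3:1 (test size = ⌈n/4⌉, so 106 → 79/27), and a
random forest (1000 trees, maximum depth 100, impurity importances retained
for interpretability) is trained per label source. Class voting uses the
0.5 majority threshold. Metrics are per-class precision/recall/F1 and
accuracy; aggregates are reported **both macro- and support-weighted, with
the mode labelled**, because the two conventions genuinely disagree on
imbalanced test sets and an unlabelled "total" row is not reproducible.
Precision with zero predicted positives is reported as missing, never 0.

Participants are excluded before modelling when required questionnaire
waves are missing or a feature-required stream falls below coverage
thresholds (`exclusionPolicy()`: all three waves, ≥50% of days with a
screen event, ≥1 expression record — all parameterized). Under the default
`"drop"` policy a participant missing any feature group is removed;
`"impute"` substitutes training-set column means instead.

# The synthetic cohort generator

`generateCohort()` emulates the study conditions: 106 participants, 28
days, and a CESD-R-like 84:22 depressed/non-depressed imbalance (a PHQ-9
like 55:51 scenario is one argument away). The group defaults, chosen once
as plausible for a psychiatric-outpatient cohort and documented here:
depressed participants sleep longer (9.5 h vs 7 h, SD 0.75 — hypersomnia is
common in outpatient samples), use the phone more (6 h vs 3 h), are more
homebound (2 places visited 0.9/0.1 vs 4 places uniformly: entropies 0.33
vs 1.39 nats), accumulate more stationary-inclusive activity time (9 h vs
5.5 h), and have an expression embedding shifted by 0.5 per coordinate at
noise SD 0.5. Questionnaire totals are drawn around 16 (PHQ-9) and 28
(CESD-R) for the depressed group versus 4 and 5, so labels almost always
agree with the latent group. GPS is sampled at 12 fixes per day
(battery-realistic duty cycling) from places kilometres apart with ~20 m
jitter.

The generator is built for exact round-trips: each day's screen sessions
end at a bedtime placed so the nocturnal off interval equals the night's
sleep draw, an opening OFF event makes the first night recoverable, and
ground truth records **realized** (post-clipping) values. With zero noise,
extracted sleep, usage and activity equal the generative parameters
exactly, and entropy matches the visit distribution analytically. All
randomness flows from one root seed through per-participant, per-stream
sub-streams, so adding a stream type never perturbs existing draws.

`nullCohortSpec()` is the no-signal control: identical groups, PHQ-9 totals
drawn around 9.5 with SD 6 so labels straddle the cut-point independently
of the features. The statistically correct chance reference for a
classifier on such data is the independence expectation
p·q + (1−p)(1−q) (Cohen's chance agreement; ≈ the class prior here), and
the test suite checks held-out accuracy stays within binomial noise of it.

**What the generator does not emulate:** real human mobility (it hops
between fixed places), circadian irregularity, missing-data bursts, label
noise from questionnaire ambivalence, or any true link between facial
affect and mood. Passing tests therefore demonstrate that the pipeline
recovers what the generator planted — correctness of the machinery, not
clinical validity on real cohorts, whose group separations are far weaker
than these defaults.

# Numerical and degenerate-input choices

* Timestamps are ISO-8601 with explicit offset, stored internally as UTC
  plus the per-record local offset; sleep and day attribution use the local
  clock, interval arithmetic the absolute timeline.
* Duplicate consecutive same-state screen events collapse to the first
  occurrence (alternation is required downstream).
* An unterminated trailing OFF interval is closed at the window end and
  flagged; zero-length intervals are dropped.
* Empty streams make the corresponding feature group missing (a signal,
  not an exception); an all-noise GPS stream likewise.
* DBSCAN ties: a border fix reachable from several clusters joins the
  earliest-founded one; processing order is timestamp order.
* Malformed raw rows are skipped and counted; a table more than half
  malformed is rejected outright.

# Problem sizes

The test suite exercises the full study shape where it matters: parameter
recovery and end-to-end discrimination each run 20 independent seeds of the
106-participant, 28-day default cohort (and 20 null cohorts), while unit
tests use small cohorts (≤ 24 participants, ≤ 7 days) chosen to keep the
default suite comfortably within an ordinary desktop run.

# Known limitations

* The screen-off sleep proxy cannot see sleep with the phone in use, nor
  distinguish an ignored phone from a sleeping owner; the first study day
  has no recoverable previous night by construction.
* Count-based entropy conflates visit frequency with visit duration when
  sampling is not uniform in time.
* The single 3:1 split follows the study protocol; no cross-validation or
  hyperparameter search is attempted, so reported accuracies carry the
  variance of one split (mitigated in the test suite by averaging over
  seeds).
* The expression embedder is consumed, not learned; real-data performance
  depends entirely on the upstream embedding quality.
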