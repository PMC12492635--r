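---
title: "Detecting affective (a)synchrony scenes from multimodal recognizer streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting affective (a)synchrony scenes from multimodal recognizer streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affsync)
```

## The problem

In psychotherapy research, a mismatch between what a person *says* and what
their face and voice *show* — saying something positive while looking
dejected — is a clinically interesting signal. `affsync` operationalizes
this as **intrapersonal affective (a)synchrony**: per speech segment of a
target speaker, the verbal sentiment (from a text-sentiment ensemble over
the diarized transcript) is compared against two concurrent non-verbal
channels, the categorical facial/vocal emotion and the continuous valence.
The package consumes only the *outputs* of recognizer models — annotation
tiers and scored transcripts — never media or models themselves, so the
whole pipeline is testable on synthetic streams.

## The annotation model

Every stream is an *annotation tier*: the time-ordered output of one
annotator (human or machine) under one *scheme*, which is `discrete` (fixed
label set), `continuous` (numeric values in a closed range) or `free`
(text). All intervals are half-open `[start, end)` in seconds. This
convention is a deliberate choice: it makes binning onto a regular grid an
exact partition (a segment boundary at `t = 3.0` belongs to exactly one
bin), so no time is counted twice and "binning conserves labeled time"
holds to floating-point accuracy. Overlap is forbidden *within* a
discrete/free tier but unconstrained *across* tiers; continuous tiers may
be dense sample trains. `validate_tier()` reports violations as data rather
than raising, so a malformed file can be diagnosed in full. Segment
confidences are carried through I/O but ignored by every analysis stage.

Tiers are stored as semicolon-separated CSV (`start;end;payload;confidence`,
millisecond timestamps, quoted payloads so free text containing separators
round-trips) with a JSON sidecar holding session, role, annotator and
scheme. The semicolon and the explicit sidecar are this package's own
documented dialect — deliberately minimal and human-inspectable.

## The detection procedure

1. **Binning.** Each speech segment of the target role is divided into
   one-second grid intervals. A discrete model stream contributes its
   duration-weighted modal label per interval ("dominant" value); a
   continuous stream its time-weighted mean. Within-bin mode ties go to the
   label appearing earliest in the bin — a deterministic, content-neutral
   rule.
2. **Ensemble fusion.** Sentiment scores (three models, per segment) are
   averaged and thresholded at ±0.5: the decision rule downstream tests a
   numeric inequality, so a fused *number* is required; majority voting is
   reserved for class-valued channels. A `sentiment_fusion = "vote"` switch
   implements the alternative per-model-classify-then-vote reading, and
   `valence_fusion` likewise, since the fusion order for these ensembles is
   genuinely underdetermined; mean-then-threshold is the default because it
   uses all score information. Emotion labels fuse by majority vote with a
   conservative tie rule (ties containing *neutral* resolve to neutral,
   other ties to an `unclassified` sentinel) so that a tie can never
   manufacture an (a)synchrony claim.
3. **Per-interval classification.** Neutral-sentiment intervals are
   unclassifiable. Otherwise the emotion channel compares the fused
   emotion's polarity with the sentiment class (opposition → asynchrony,
   match → synchrony, neutral polarity → undecided) and the valence channel
   compares the low/high valence class analogously. The published rule is
   stated for positive sentiment; the mirrored rule for negative sentiment
   (negative words with a beaming face → asynchrony) is implemented because
   the symmetric reading is the only one consistent with a two-sided ±0.5
   threshold. The suite checks this symmetry exhaustively.
4. **Channel conflict.** When the emotion channel says synchrony and the
   valence channel asynchrony (or vice versa), the interval is *not* forced
   to a combined decision: both single-channel labels are recorded and the
   `both` channel is denied. Since scene selection consumes only `both`
   intervals, conflicts can never leak into a rating study.
5. **Scene filters.** A candidate scene is one speech segment; its coverage
   is the time in `both`-channel intervals carrying the segment's modal
   decision, divided by the full segment duration (the
   `coverage_denominator = "classified"` switch restricts the denominator
   to non-neutral time, answering an ambiguity in "70 % of the duration"
   the conservative way by default). Candidates shorter than 5 s or below
   70 % coverage are dropped, as are segments whose synchrony/asynchrony
   both-times tie exactly — an ambiguous scene must not enter a study.
6. **Selection.** Three scenes per decision class are drawn uniformly
   without replacement from a single seeded RNG in documented order
   (asynchrony class first, then synchrony, then a presentation shuffle),
   making selections bit-reproducible across platforms; the caller's RNG
   state is preserved. Classes with fewer candidates return everything plus
   a shortfall flag.

### Tunable parameters

| field | default | unit | role |
|---|---|---|---|
| `interval_length` | 1.0 | s | binning grid |
| `sentiment_threshold` | 0.5 | score | ± bound for decisive sentiment |
| `valence_midpoint` | 0.5 | value | low/high valence split |
| `min_scene_duration` | 5.0 | s | scene filter |
| `min_both_coverage` | 0.70 | fraction | scene filter |
| `n_select_per_class` | 3 | scenes | per-class selection |
| `rng_seed` | 1 | — | selection RNG |

All filter comparisons use `>=` with a `1e-9` slack so that exact boundary
cases (a 5.000 s segment, coverage of exactly 0.70) are kept rather than
lost to floating-point representation.

## Sliding-window scene search

`apply_rule()` is a generic engine: evaluate a predicate on every window
`[k·step, k·step + window)`, merge positive windows under
overlap/adjacency, and emit the merged spans as a machine tier. The shipped
predicate detects **smile mirroring**: true when a genuine smile onset in
one tier is answered within `max_lag` seconds by an onset in the other
(onsets created by window clipping are not counted as onsets), or when two
smiles overlap by at least `min_overlap` of the shorter smile. The defaults
— 4 s window, 1 s step, 3 s lag, 0.5 overlap — reflect typical
smile-response latencies in conversation and are exposed as ordinary
parameters, not empirical claims. The predicate is symmetric in the two
roles and monotone in `max_lag`, and both properties are property-tested
against a brute-force pairwise oracle.

## Agreement statistics

`cohens_kappa()` implements chance-corrected two-rater agreement from the
marginal label frequencies; `cronbachs_alpha()` implements
`k/(k−1)·(1 − Σ var_rater / var_total)` with unbiased (n−1) sample
variances — the two variance conventions differ, and the unbiased one is
declared rather than left implicit. Missing entries are removed listwise,
the standard convention for both statistics. Degenerate inputs are errors
with named causes (fewer than two complete items, zero total variance),
except the one well-defined corner: two raters constant on the same label
agree perfectly and get κ = 1. `align_tiers_to_matrix()` reuses the binning
stage so agreement can be computed directly on tier files.

## What the synthetic generator emulates — and what it does not

`generate_session()` emulates the *shapes* of a recognizer stack on a
dyadic session: alternating diarized speech segments with lognormal
durations (meanlog 1.5, sdlog 0.6 — median ≈ 4.5 s, deliberately straddling
the 5 s filter so both filter branches occur in random sessions), a
three-model ensemble per modality, dense 1 Hz emotion and valence streams,
and smile events with probabilistic mirroring. Planted scenes overwrite
background-neutral affect on exactly enough grid intervals to reach a
requested both-channel coverage; the achieved coverage is recorded
analytically (from interval overlap arithmetic, not by running the
pipeline), so the noise-free pipeline-equals-ground-truth check compares
two independent routes. Noise is applied *after* planting: Gaussian jitter
(sd 0.05 by default) on sentiment and valence, and per-model, per-interval
label flips that replace an emotion label with a uniformly random other one
and mirror the valence value about 0.5.

The generator does **not** emulate: correlated model errors (real ensembles
share failure modes; synthetic models err independently, which flatters
majority voting), drift or autocorrelation in valence, overlapping speech,
diarization errors, or emotion dynamics within an interval. Passing tests
therefore demonstrate the correctness of the *pipeline logic* under the
stated noise model — not recognizer-level performance on real recordings.

Gaps between segments are at least 1 s so that two speech segments of the
target role never share a grid interval; planted structure is thereby
local to its segment.

## Problem sizes and determinism

The test suite checks the voting rule against exhaustive enumeration (all
27 three-vote multisets), the congruence rule against an 18-case oracle,
filter exactness over 1,000 random sessions, noise-free recovery over 60
sessions and flip-noise (ε = 0.1) recovery over 200 sessions — sizes chosen
to exercise every branch while keeping the default run in tens of seconds.
The acceptance script regenerates everything from a single `--seed` and
verifies byte-level reproducibility of the detection outputs.

## Known limitations

* Sentiment is per speech segment (as diarized transcripts provide it), so
  within-segment sentiment shifts are invisible; only the non-verbal
  channels vary within a segment.
* The emotion-polarity map is a coarse, config-overridable simplification;
  contexts where surprise is valenced need a custom map.
* κ and α are the only agreement statistics; weighted κ or Krippendorff's
  α would be needed for ordinal schemes or many raters with missingness
  beyond listwise handling.
* The rule engine ships a single predicate (mirroring); it is a template
  for further predicates rather than a query language.
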