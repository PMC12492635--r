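# affsync

Scene detection for **intrapersonal affective (a)synchrony** in recorded
dyadic interactions (e.g. clinical interviews), plus the annotation-stream
plumbing around it: a typed tier model with flat-file I/O, sliding-window
rule search (smile mirroring), inter-rater agreement statistics, and a
synthetic session generator with planted ground truth.

The package is aimed at researchers in behavioral signal processing and
digital mental health who already run recognizer stacks (speech
transcription + diarization, text sentiment ensembles, facial/vocal emotion
and valence models, smile detectors) and need the *downstream* analysis:
turning heterogeneous per-model streams into interpretable, reproducible
scene annotations. No audio, video, or pretrained model is touched here —
only their output shapes.

## The method

For each speech segment of a target speaker, time is cut into one-second
intervals `[i, i+1)`. Within an interval, each model stream is aggregated to
its dominant value (duration-weighted mode for categorical streams,
time-weighted mean for continuous ones), and the model ensembles are fused:

* **sentiment** `s ∈ [−1, 1]`: mean of the ensemble scores, classified
  *positive* if `s > 0.5`, *negative* if `s < −0.5`, else *neutral*;
* **categorical emotion**: majority vote across models (ties resolve to
  neutral), mapped to a polarity (happiness → positive; sadness, anger,
  fear, disgust, contempt → negative; surprise, neutral → none);
* **valence** `v ∈ [0, 1]`: ensemble mean, class *high* iff `v > 0.5`.

An interval with decisive sentiment is **asynchronous** on a channel when
the non-verbal signal opposes the verbal sentiment (e.g. positive sentiment
with a negative emotion and/or valence below 0.5) and **synchronous** when
it matches; the *both* channel requires the emotion and valence channels to
agree. A speech segment becomes a **scene** when it is at least 5 s long and
carries a single (a)synchrony decision on the *both* channel for at least
70 % of its duration; finally 3 scenes per decision class are drawn with a
seeded RNG, in randomized presentation order. Every constant above is a
config field (`default_config()` / `read_config()`).

The same tier model feeds two side workflows: `apply_rule()` slides a
window over two smile tiers and merges windows where one interlocutor's
smile answers the other's (`mirroring_condition()`), and
`cohens_kappa()` / `cronbachs_alpha()` quantify inter-rater agreement on
aligned annotation tiers.

## Worked example

```r
library(affsync)

plan <- session_plan(
  n_segments = 10, rng_seed = 42,
  planted_scenes = data.frame(
    segment  = c(2, 5, 8),
    decision = c("asynchrony", "synchrony", "asynchrony"),
    coverage = c(0.9, 0.85, 1.0),
    duration = c(8, 7, 6)))
s <- generate_session(plan)

res <- detect_scenes(s$transcript, s$emotion_tiers, s$valence_tiers,
                     default_config(), session = s$session, role = "patient")
res$scenes[, c("segment_id", "duration", "both_coverage", "decision")]
#>   segment_id duration both_coverage   decision
#> 1          3        8     0.9058485 asynchrony
#> 2          9        7     0.8605384  synchrony
#> 3         15        6     1.0000000 asynchrony
```

Three speech segments of the simulated patient pass the filters — their
durations (8, 7, 6 s) are above 5 s and their *both*-channel coverages
(0.91, 0.86, 1.00) above 0.70 — and match the planted ground truth
(`s$ground_truth`) in position, decision and coverage. With only 1 + 2
qualifying candidates, `select_scenes()` returns all of them and flags the
shortfall against the 3 + 3 selection target.

A command-line wrapper over the same functions ships in `inst/cli/affsync`
(subcommands `detect`, `search`, `agreement`, `simulate`, `validate`; exit
codes 0 success / 2 input error / 1 internal error).

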