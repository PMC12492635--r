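# independent oracle for the congruence rule, written as a literal nested
# case analysis of the rule text (positive sentiment with negative emotion
# and/or low valence -> asynchrony; matching signals -> synchrony; the
# negative-sentiment case mirrored; neutral sentiment unclassifiable)
classify_oracle <- function(sent, pol, val) {
  if (sent == "neutral") {
    return(list(decision = "unclassified", channel = "none"))
  }
  e <- if (pol == "neutral") NA_character_ else if (sent == "positive") {
    if (pol == "negative") "asynchrony" else "synchrony"
  } else {
    if (pol == "positive") "asynchrony" else "synchrony"
  }
  v <- if (sent == "positive") {
    if (val == "low") "asynchrony" else "synchrony"
  } else {
    if (val == "high") "asynchrony" else "synchrony"
  }
  if (!is.na(e) && e == v) list(decision = e, channel = "both")
  else if (is.na(e)) list(decision = v, channel = "valence")
  else list(decision = NA_character_, channel = NA_character_)  # conflict
}

test_that("classify_interval matches the enumeration oracle on all 18 combinations", {
  grid <- expand.grid(sent = c("negative", "neutral", "positive"),
                      pol = c("positive", "negative", "neutral"),
                      val = c("low", "high"), stringsAsFactors = FALSE)
  expect_identical(nrow(grid), 18L)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- classify_interval(g$sent, g$pol, g$val)
    want <- classify_oracle(g$sent, g$pol, g$val)
    expect_identical(got$decision, want$decision,
                     info = paste(g$sent, g$pol, g$val))
    expect_identical(got$channel, want$channel,
                     info = paste(g$sent, g$pol, g$val))
  }
})

test_that("the quoted-rule cases classify as forced", {
  # positive sentiment + negative emotion + low valence -> asynchrony on both
  r <- classify_interval("positive", "negative", "low")
  expect_identical(r$decision, "asynchrony")
  expect_identical(r$channel, "both")
  # positive sentiment + positive emotion + high valence -> synchrony on both
  r <- classify_interval("positive", "positive", "high")
  expect_identical(r$decision, "synchrony")
  expect_identical(r$channel, "both")
  # sub-threshold sentiment is unclassifiable regardless of the nonverbal side
  r <- classify_interval("neutral", "negative", "low")
  expect_identical(r$decision, "unclassified")
  expect_identical(r$channel, "none")
  # mirror rule: negative sentiment + positive emotion + high valence
  r <- classify_interval("negative", "positive", "high")
  expect_identical(r$decision, "asynchrony")
  expect_identical(r$channel, "both")
})

test_that("the rule is symmetric under global affect negation", {
  flip_sent <- c(positive = "negative", negative = "positive",
                 neutral = "neutral")
  flip_pol <- c(positive = "negative", negative = "positive",
                neutral = "neutral")
  flip_val <- c(low = "high", high = "low")
  grid <- expand.grid(sent = names(flip_sent), pol = names(flip_pol),
                      val = names(flip_val), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    a <- classify_interval(g$sent, g$pol, g$val)
    b <- classify_interval(flip_sent[[g$sent]], flip_pol[[g$pol]],
                           flip_val[[g$val]])
    expect_identical(a$decision, b$decision)
    expect_identical(a$channel, b$channel)
  }
})

test_that("congruence_labels expands conflicts into two single-channel rows", {
  frame <- data.frame(
    interval = 0:2,
    sentiment_class = c("positive", "positive", "neutral"),
    emotion_polarity = c("positive", "negative", "negative"),
    valence_class = c("low", "low", "low")
  )
  classified <- classify_intervals(frame, default_config())
  labels <- congruence_labels(classified)
  # interval 0 conflicts: emotion synchrony vs valence asynchrony
  l0 <- labels[labels$interval == 0, ]
  expect_setequal(l0$channel, c("emotion", "valence"))
  expect_identical(l0$decision[l0$channel == "emotion"], "synchrony")
  expect_identical(l0$decision[l0$channel == "valence"], "asynchrony")
  expect_false("both" %in% l0$channel)
  # interval 1 agrees on both channels; interval 2 is unclassified
  expect_identical(labels$channel[labels$interval == 1], "both")
  expect_identical(labels$decision[labels$interval == 2], "unclassified")
})

test_that("build_scenes applies the duration and coverage filters", {
  # 6 s segment, 5 of 6 intervals asynchronous on both -> coverage 5/6, kept
  sc1 <- toy_scenes(c("A", "A", "A", "A", "A", "N"))
  expect_identical(nrow(sc1), 1L)
  expect_equal(sc1$both_coverage, 5 / 6, tolerance = 1e-9)
  expect_identical(sc1$decision, "asynchrony")
  expect_equal(sc1$duration, 6)

  # 4 s fully synchronous segment: dropped on duration
  sc2 <- toy_scenes(c("S", "S", "S", "S"))
  expect_identical(nrow(sc2), 0L)
  expect_identical(nrow(attr(sc2, "candidates")), 1L)
  expect_equal(attr(sc2, "candidates")$both_coverage, 1)

  # 10 s segment with 6 of 10 both-intervals: dropped on coverage
  sc3 <- toy_scenes(c(rep("A", 6), rep("N", 4)))
  expect_identical(nrow(sc3), 0L)
  expect_equal(attr(sc3, "candidates")$both_coverage, 0.6)

  # tied synchrony/asynchrony both-time: ambiguous, dropped
  sc4 <- toy_scenes(c("A", "A", "A", "S", "S", "S"))
  expect_identical(nrow(sc4), 0L)
  expect_true(is.na(attr(sc4, "candidates")$decision))
})

test_that("coverage can optionally be measured over classifiable time only", {
  # one 10 s segment: 6 s asynchronous on both, 2 s unclassified (neutral
  # sentiment), 2 s valence-channel only
  tr <- transcript("patient", 0, 10, "x",
                   sentiment_scores = data.frame(m1 = 0.8))
  classified <- data.frame(
    segment_id = 1L, interval = 0:9, overlap = 1,
    decision = c(rep("asynchrony", 6), rep("unclassified", 2),
                 rep("asynchrony", 2)),
    channel = c(rep("both", 6), rep("none", 2), rep("valence", 2))
  )
  full <- build_scenes(classified, tr, default_config())
  expect_identical(nrow(full), 0L)  # 6/10 = 0.6 < 0.7
  alt <- build_scenes(classified, tr,
                      default_config(coverage_denominator = "classified"))
  expect_identical(nrow(alt), 1L)  # 6/8 = 0.75 over classifiable time
  expect_equal(alt$both_coverage, 0.75)
})

test_that("scene selection is seeded, per-class, and shortfall-aware", {
  scenes <- data.frame(
    session = "s", role = "p", segment_id = 1:10,
    start = seq(0, 90, by = 10), end = seq(8, 98, by = 10),
    duration = 8, both_coverage = 0.9,
    decision = rep(c("synchrony", "asynchrony"), each = 5)
  )
  cfg <- default_config(rng_seed = 99L)
  sel1 <- select_scenes(scenes, cfg)
  expect_identical(nrow(sel1), 6L)
  expect_equal(sum(sel1$decision == "synchrony"), 3)
  expect_equal(sum(sel1$decision == "asynchrony"), 3)
  expect_equal(unname(attr(sel1, "shortfall")), c(0L, 0L))
  # determinism under a fixed seed, different draw under another
  sel2 <- select_scenes(scenes, cfg)
  expect_identical(sel1, sel2)
  sel3 <- select_scenes(scenes, default_config(rng_seed = 100L))
  expect_false(identical(sel1$segment_id, sel3$segment_id))

  # exhaustion: both asynchrony candidates returned, with a shortfall flag
  few <- scenes[scenes$decision == "asynchrony", ][1:2, ]
  expect_warning(self <- select_scenes(few, cfg), "shortfall")
  expect_identical(nrow(self), 2L)
  expect_equal(attr(self, "shortfall")[["asynchrony"]], 1L)
  expect_equal(attr(self, "shortfall")[["synchrony"]], 3L)

  # selection does not disturb the caller's RNG stream
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(select_scenes(scenes, cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("scenes export as a machine-annotated discrete tier", {
  sc1 <- toy_scenes(c(rep("A", 6)))
  tier <- scenes_to_tier(sc1)
  expect_identical(tier$annotator_type, "machine")
  expect_identical(nrow(validate_tier(tier)), 0L)
  expect_identical(tier$segments$payload, "asynchrony")
})
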