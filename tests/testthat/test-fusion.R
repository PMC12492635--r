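emo_scheme <- scheme("emotion", "discrete",
                     labels = names(default_emotion_polarity()))

test_that("bin_stream aggregates discrete tiers by duration-weighted mode", {
  t1 <- make_tier(data.frame(start = 0, end = 2, payload = "happiness"),
                  sc = emo_scheme)
  b <- bin_stream(t1, 1)
  expect_equal(b$interval, c(0L, 1L))
  expect_equal(b$value, c("happiness", "happiness"))
  expect_equal(b$time, c(1, 1))

  t2 <- make_tier(data.frame(start = c(0, 0.7), end = c(0.7, 1.0),
                             payload = c("sadness", "happiness")),
                  sc = emo_scheme)
  expect_equal(bin_stream(t2, 1)$value, "sadness")

  # empty bins are absent
  t3 <- make_tier(data.frame(start = 5.5, end = 6.5, payload = "anger"),
                  sc = emo_scheme)
  expect_equal(bin_stream(t3, 1)$interval, c(5L, 6L))

  expect_error(bin_stream(t1, 0), "positive")
})

test_that("bin_stream matches a numeric-integration oracle on continuous tiers", {
  val <- scheme("valence", "continuous", value_range = c(0, 1))
  t1 <- annotation_tier("s", "r", "m", "machine", val,
                        data.frame(start = c(0, 0.5), end = c(0.5, 1.0),
                                   payload = c(0.2, 0.8)))
  expect_equal(bin_stream(t1, 1)$value, 0.5)

  # oracle: dense Riemann sampling of the piecewise-constant signal
  set.seed(51)
  for (rep in 1:10) {
    n <- 8
    starts <- cumsum(runif(n, 0.1, 1.4))
    ends <- starts + runif(n, 0.1, 1.2)
    ends <- pmin(ends, c(starts[-1], Inf))
    v <- runif(n)
    tier <- annotation_tier("s", "r", "m", "machine", val,
                            data.frame(start = starts, end = ends, payload = v))
    b <- bin_stream(tier, 1)
    dt <- 0.0005
    pts <- seq(dt / 2, 12, by = dt)
    at <- function(p) {
      i <- which(starts <= p & p < ends)
      if (length(i)) v[i[1]] else NA_real_
    }
    sig <- vapply(pts, at, numeric(1))
    for (j in seq_len(nrow(b))) {
      in_bin <- sig[pts >= b$interval[j] & pts < b$interval[j] + 1]
      expect_equal(b$value[j], mean(in_bin, na.rm = TRUE), tolerance = 1e-2)
    }
  }
})

test_that("binning conserves labeled time", {
  set.seed(52)
  for (kind in c("discrete", "continuous")) {
    for (rep in 1:10) {
      tier <- random_tier(kind, n = 12)
      L <- sample(c(0.5, 1, 2), 1)
      b <- bin_stream(tier, L)
      expect_equal(sum(b$time),
                   sum(tier$segments$end - tier$segments$start),
                   tolerance = 1e-9)
    }
  }
})

test_that("majority_vote matches exhaustive counting on all 27 three-vote multisets", {
  classes <- c("positive", "negative", "neutral")
  grid <- expand.grid(a = classes, b = classes, c = classes,
                      stringsAsFactors = FALSE)
  # oracle: brute-force frequency count with the documented tie rule
  oracle <- function(votes) {
    best <- -1; tied <- character(0)
    for (cl in unique(votes)) {
      k <- sum(votes == cl)
      if (k > best) { best <- k; tied <- cl }
      else if (k == best) tied <- c(tied, cl)
    }
    if (length(tied) == 1) tied else if ("neutral" %in% tied) "neutral"
    else "unclassified"
  }
  for (i in seq_len(nrow(grid))) {
    votes <- unlist(grid[i, ])
    expect_identical(majority_vote(votes), oracle(votes))
  }
  expect_identical(majority_vote(c("positive", "positive", "negative")), "positive")
  expect_identical(majority_vote(c("positive", "negative", "neutral")), "neutral")
  expect_identical(majority_vote(c("happiness", "sadness")), "unclassified")
  expect_error(majority_vote(character(0)), "no votes")
})

test_that("fuse_intervals averages scores, votes labels, and maps polarity", {
  frame <- data.frame(
    sentiment.a = c(0.9, 0.6), sentiment.b = c(0.7, -0.6),
    sentiment.c = c(0.8, 0.0),
    emotion.a = c("sadness", "happiness"), emotion.b = c("sadness", "surprise"),
    emotion.c = c("happiness", "surprise"),
    valence.a = c(0.3, 0.9), valence.b = c(0.2, 0.8), valence.c = c(0.4, 0.7)
  )
  fused <- fuse_intervals(frame, default_config())
  expect_equal(fused$sentiment, c(0.8, 0.0))
  expect_equal(fused$sentiment_class, c("positive", "neutral"))
  expect_equal(fused$emotion, c("sadness", "surprise"))
  expect_equal(fused$emotion_polarity, c("negative", "neutral"))
  expect_equal(fused$valence, c(0.3, 0.8))
  expect_equal(fused$valence_class, c("low", "high"))

  unknown <- data.frame(sentiment.a = 0.9, emotion.a = "boredom",
                        valence.a = 0.5)
  expect_error(fuse_intervals(unknown, default_config()), "boredom")
})

test_that("fusion is invariant under model order and monotone in scores", {
  set.seed(53)
  cfg <- default_config()
  for (rep in 1:20) {
    frame <- data.frame(
      sentiment.a = runif(5, -1, 1), sentiment.b = runif(5, -1, 1),
      sentiment.c = runif(5, -1, 1),
      emotion.a = sample(emo_scheme$labels, 5, TRUE),
      emotion.b = sample(emo_scheme$labels, 5, TRUE),
      emotion.c = sample(emo_scheme$labels, 5, TRUE),
      valence.a = runif(5), valence.b = runif(5), valence.c = runif(5)
    )
    permuted <- frame[, c("sentiment.c", "sentiment.a", "sentiment.b",
                          "emotion.b", "emotion.c", "emotion.a",
                          "valence.c", "valence.b", "valence.a")]
    names(permuted) <- names(frame)
    f1 <- fuse_intervals(frame, cfg)
    f2 <- fuse_intervals(permuted, cfg)
    for (col in c("sentiment", "sentiment_class", "emotion",
                  "emotion_polarity", "valence", "valence_class")) {
      expect_equal(f1[[col]], f2[[col]])
    }
    # raising one model's score never moves the fused class toward negative
    bumped <- frame
    bumped$sentiment.b <- pmin(1, bumped$sentiment.b + runif(5, 0, 0.5))
    fb <- fuse_intervals(bumped, cfg)
    rank_of <- function(x) match(x, c("negative", "neutral", "positive"))
    expect_true(all(rank_of(fb$sentiment_class) >= rank_of(f1$sentiment_class)))
  }
})

test_that("vote-mode sentiment fusion classifies per model before voting", {
  cfg <- default_config(sentiment_fusion = "vote")
  frame <- data.frame(sentiment.a = 0.9, sentiment.b = 0.6, sentiment.c = -0.9,
                      emotion.a = "neutral", valence.a = 0.5)
  fused <- fuse_intervals(frame, cfg)
  expect_equal(fused$sentiment_class, "positive")  # 2 positive votes vs 1
  # mean mode would see (0.9 + 0.6 - 0.9) / 3 = 0.2 -> neutral
  expect_equal(fuse_intervals(frame, default_config())$sentiment_class, "neutral")
})

test_that("interval frames cover exactly the role's speech time", {
  s <- toy_session(c("A", "A", "N"))
  frame <- build_interval_frame(s$transcript, "patient", s$emotion_tiers,
                                s$valence_tiers, default_config())
  expect_equal(nrow(frame), 3L)
  expect_equal(sum(frame$overlap), 3)
  expect_error(
    build_interval_frame(s$transcript, "nobody", s$emotion_tiers,
                         s$valence_tiers, default_config()),
    "no segments")
})
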