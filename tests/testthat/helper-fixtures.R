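# Shared fixture builders: everything is generated in code at test time.

smile_scheme <- function() scheme("smile", "discrete", labels = c("smile", "none"))

make_tier <- function(segments, sc = smile_scheme(), role = "teacher",
                      annotator = "coder1", type = "human") {
  annotation_tier("s1", role, annotator, type, sc, segments)
}

# random tier of any scheme kind, for round-trip / slicing property tests
random_tier <- function(kind = c("discrete", "continuous", "free"), n = 10,
                        rate = 1) {
  kind <- match.arg(kind)
  sc <- switch(kind,
    discrete = scheme("emotion", "discrete",
                      labels = c("happiness", "sadness", "anger", "neutral")),
    continuous = scheme("valence", "continuous", value_range = c(0, 1)),
    free = scheme("transcript", "free")
  )
  if (kind == "continuous") {
    starts <- (seq_len(n) - 1) / rate
    seg <- data.frame(start = starts, end = starts + 1 / rate,
                      payload = round(runif(n), 4),
                      confidence = round(runif(n), 3))
  } else {
    dur <- runif(n, 0.2, 3)
    gap <- runif(n, 0, 2)
    starts <- cumsum(c(runif(1, 0, 1), (dur + gap)[-n]))
    payload <- if (kind == "discrete") {
      sample(sc$labels, n, replace = TRUE)
    } else {
      replicate(n, paste0("text ", paste(sample(letters, 5), collapse = ""),
                          "; with, separators"))
    }
    seg <- data.frame(start = starts, end = starts + dur, payload = payload,
                      confidence = ifelse(runif(n) < 0.3, NA, round(runif(n), 3)))
  }
  annotation_tier("s1", "teacher", "rater", "human", sc, seg)
}

# minimal single-role session with hand-chosen per-interval affect, for toy
# scene tests: `pattern` is a character vector, one code per 1 s interval of
# the single speech segment: "A" = asynchronous plant, "S" = synchronous
# plant, "N" = neutral nonverbal background
toy_session <- function(pattern, sentiment = 0.8, start = 0) {
  n <- length(pattern)
  tr <- transcript(speaker = "patient", start = start, end = start + n,
                   text = "toy",
                   sentiment_scores = data.frame(m1 = sentiment, m2 = sentiment,
                                                 m3 = sentiment))
  emo <- ifelse(pattern == "A", "sadness",
                ifelse(pattern == "S", "happiness", "neutral"))
  val <- ifelse(pattern == "A", 0.2, ifelse(pattern == "S", 0.8, 0.5))
  if (sentiment < 0) {  # mirror the nonverbal side for negative sentiment
    emo <- ifelse(pattern == "A", "happiness",
                  ifelse(pattern == "S", "sadness", "neutral"))
    val <- ifelse(pattern == "A", 0.8, ifelse(pattern == "S", 0.2, 0.5))
  }
  starts <- start + seq_len(n) - 1
  emotion_tiers <- lapply(1:3, function(m) {
    annotation_tier("s1", "patient", paste0("emo", m), "machine",
                    scheme("emotion", "discrete",
                           labels = names(default_emotion_polarity())),
                    data.frame(start = starts, end = starts + 1, payload = emo))
  })
  valence_tiers <- lapply(1:3, function(m) {
    annotation_tier("s1", "patient", paste0("val", m), "machine",
                    scheme("valence", "continuous", value_range = c(0, 1)),
                    data.frame(start = starts, end = starts + 1, payload = val))
  })
  list(transcript = tr, emotion_tiers = emotion_tiers,
       valence_tiers = valence_tiers)
}

toy_scenes <- function(pattern, cfg = default_config(), ...) {
  s <- toy_session(pattern, ...)
  frame <- build_interval_frame(s$transcript, "patient", s$emotion_tiers,
                                s$valence_tiers, cfg)
  classified <- classify_intervals(fuse_intervals(frame, cfg), cfg)
  build_scenes(classified, s$transcript, cfg, session = "s1", role = "patient")
}

# random session plan used by property-style pipeline tests
random_plan <- function(seed, n_segments = 6, eps = 0, n_planted = NULL) {
  set.seed(seed * 7 + 1)
  if (is.null(n_planted)) n_planted <- sample(0:3, 1)
  planted <- if (n_planted > 0) {
    data.frame(
      segment = sort(sample(n_segments, n_planted)),
      decision = sample(c("synchrony", "asynchrony"), n_planted, replace = TRUE),
      coverage = runif(n_planted, 0.4, 1),
      duration = runif(n_planted, 3, 10)
    )
  } else {
    NULL
  }
  session_plan(n_segments = n_segments, planted_scenes = planted,
               label_flip_prob = eps, rng_seed = seed)
}

run_pipeline <- function(s, cfg = default_config()) {
  # shortfall warnings are routine on sparse random sessions
  suppressWarnings(
    detect_scenes(s$transcript, s$emotion_tiers, s$valence_tiers, cfg,
                  session = s$session, role = s$roles[["target"]])
  )
}
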