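# Per-interval affective (a)synchrony classification and scene assembly.
#
# An interval is classifiable only when the fused verbal sentiment is
# decisively positive or negative (magnitude beyond the threshold). Two
# non-verbal channels are then compared against it: the categorical-emotion
# channel through its polarity, and the valence channel through its
# low/high class. Agreement on a channel is synchrony, opposition is
# asynchrony. When both channels decide identically the interval carries the
# "both" channel, which is what scene selection consumes; a channel conflict
# is recorded as two single-channel labels and can never reach selection.

decide_channel <- function(sentiment_class, signal_polarity) {
  # signal_polarity: "positive"/"negative"/"neutral"/NA relative scale
  out <- rep(NA_character_, length(sentiment_class))
  pos <- !is.na(sentiment_class) & sentiment_class == "positive"
  neg <- !is.na(sentiment_class) & sentiment_class == "negative"
  sp <- !is.na(signal_polarity)
  out[pos & sp & signal_polarity == "positive"] <- "synchrony"
  out[pos & sp & signal_polarity == "negative"] <- "asynchrony"
  out[neg & sp & signal_polarity == "negative"] <- "synchrony"
  out[neg & sp & signal_polarity == "positive"] <- "asynchrony"
  out
}

#' Classify affective (a)synchrony per interval
#'
#' Applies the congruence rule to every row of a fused interval frame.
#' Neutral-sentiment intervals are `unclassified` (channel `none`).
#' Otherwise the emotion channel is asynchronous iff the fused emotion's
#' polarity opposes the sentiment class (synchronous iff it matches,
#' undecided for neutral-polarity emotions such as surprise), and the valence
#' channel is asynchronous iff positive sentiment meets low valence or
#' negative sentiment meets high valence (synchronous otherwise). The
#' combined `channel` is `both` when both channels reach the same decision,
#' the single deciding channel when only one decides, and `NA` when the
#' channels conflict (the per-channel columns retain the two single-channel
#' labels).
#'
#' @param frame Output of [fuse_intervals()].
#' @param cfg An [default_config()] object.
#' @return `frame` with added columns `emotion_decision`, `valence_decision`
#'   (per-channel, `NA` when undecided), `decision` and `channel` (combined
#'   label).
#' @export
classify_intervals <- function(frame, cfg = default_config()) {
  stopifnot(all(c("sentiment_class", "emotion_polarity", "valence_class")
                %in% names(frame)))
  sc <- frame$sentiment_class
  e_dec <- decide_channel(sc, frame$emotion_polarity)
  v_pol <- ifelse(is.na(frame$valence_class), NA_character_,
                  ifelse(frame$valence_class == "high", "positive", "negative"))
  v_dec <- decide_channel(sc, v_pol)

  decision <- rep(NA_character_, nrow(frame))
  channel <- rep(NA_character_, nrow(frame))
  neutral <- is.na(sc) | sc == "neutral" | sc == "unclassified"
  decision[neutral] <- "unclassified"
  channel[neutral] <- "none"
  both_same <- !neutral & !is.na(e_dec) & !is.na(v_dec) & e_dec == v_dec
  decision[both_same] <- e_dec[both_same]
  channel[both_same] <- "both"
  only_v <- !neutral & is.na(e_dec) & !is.na(v_dec)
  decision[only_v] <- v_dec[only_v]
  channel[only_v] <- "valence"
  only_e <- !neutral & !is.na(e_dec) & is.na(v_dec)
  decision[only_e] <- e_dec[only_e]
  channel[only_e] <- "emotion"
  undecided <- !neutral & is.na(e_dec) & is.na(v_dec)
  decision[undecided] <- "unclassified"
  channel[undecided] <- "none"
  # conflicting channels: combined label left NA, per-channel columns kept

  frame$emotion_decision <- e_dec
  frame$valence_decision <- v_dec
  frame$decision <- decision
  frame$channel <- channel
  frame
}

#' Classify a single interval
#'
#' Scalar convenience wrapper around [classify_intervals()] for one fused
#' interval given directly as sentiment class, emotion polarity and valence
#' class.
#'
#' @param sentiment_class `"negative"`, `"neutral"` or `"positive"`.
#' @param emotion_polarity `"positive"`, `"negative"` or `"neutral"`.
#' @param valence_class `"low"` or `"high"`.
#' @param cfg An [default_config()] object.
#' @return A list with `decision`, `channel`, `emotion_decision`,
#'   `valence_decision`.
#' @export
#' @examples
#' classify_interval("positive", "negative", "low")  # asynchrony on both
classify_interval <- function(sentiment_class, emotion_polarity, valence_class,
                              cfg = default_config()) {
  frame <- data.frame(sentiment_class = sentiment_class,
                      emotion_polarity = emotion_polarity,
                      valence_class = valence_class)
  res <- classify_intervals(frame, cfg)
  list(decision = res$decision, channel = res$channel,
       emotion_decision = res$emotion_decision,
       valence_decision = res$valence_decision)
}

#' Long-format congruence labels
#'
#' Expands a classified interval frame into one row per emitted label:
#' both-channel intervals yield one `both` row, single-channel intervals one
#' row, conflicting intervals two rows (one per channel), unclassified
#' intervals one `none` row.
#'
#' @param classified Output of [classify_intervals()].
#' @return A data.frame with columns `interval`, `decision`, `channel`.
#' @export
congruence_labels <- function(classified) {
  iv <- if (!is.null(classified$interval)) classified$interval
        else seq_len(nrow(classified)) - 1L
  simple <- !is.na(classified$channel)
  out <- data.frame(interval = iv[simple],
                    decision = classified$decision[simple],
                    channel = classified$channel[simple])
  conflict <- which(!simple)
  if (length(conflict)) {
    out <- rbind(
      out,
      data.frame(interval = iv[conflict],
                 decision = classified$emotion_decision[conflict],
                 channel = "emotion"),
      data.frame(interval = iv[conflict],
                 decision = classified$valence_decision[conflict],
                 channel = "valence")
    )
  }
  out <- out[order(out$interval, out$channel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble candidate scenes from classified intervals
#'
#' One candidate is considered per speech segment of the target role. Its
#' both-channel coverage is the time spent in intervals carrying
#' `channel = "both"` with the segment's modal decision, divided by the
#' segment duration (or, with `coverage_denominator = "classified"`, by its
#' non-neutral time). A candidate becomes a scene iff its duration is at
#' least `cfg$min_scene_duration` seconds and its coverage at least
#' `cfg$min_both_coverage`; segments whose both-channel time ties between
#' synchrony and asynchrony are dropped as ambiguous.
#'
#' @param classified Output of [classify_intervals()] (must carry
#'   `segment_id` and `overlap` columns, i.e. built through
#'   [build_interval_frame()]).
#' @param tr The [transcript()] the frame was built from.
#' @param cfg An [default_config()] object.
#' @param session,role Identifiers stamped onto the scenes.
#' @return A data.frame of scenes: `session`, `role`, `segment_id`, `start`,
#'   `end`, `duration`, `both_coverage`, `decision`. The unfiltered
#'   candidates are attached as attribute `candidates`.
#' @export
build_scenes <- function(classified, tr, cfg = default_config(),
                         session = "session", role = NULL) {
  stopifnot(all(c("segment_id", "interval", "overlap", "decision", "channel")
                %in% names(classified)))
  if (!is.null(attr(classified, "interval_length")) &&
      abs(attr(classified, "interval_length") - cfg$interval_length) > 1e-12) {
    stop("interval grid mismatch: frame binned at ",
         attr(classified, "interval_length"), " s but config expects ",
         cfg$interval_length, " s", call. = FALSE)
  }
  seg_ids <- sort(unique(classified$segment_id))
  if (is.null(role)) role <- tr$speaker[seg_ids[1]]
  cand <- lapply(seg_ids, function(sid) {
    rows <- classified[classified$segment_id == sid, , drop = FALSE]
    seg <- tr[sid, ]
    duration <- seg$end - seg$start
    both <- !is.na(rows$channel) & rows$channel == "both"
    t_sync <- sum(rows$overlap[both & rows$decision == "synchrony"])
    t_async <- sum(rows$overlap[both & rows$decision == "asynchrony"])
    denom <- if (cfg$coverage_denominator == "full") {
      duration
    } else {
      sum(rows$overlap[!is.na(rows$decision) & rows$decision != "unclassified" |
                         is.na(rows$channel)])
    }
    if (t_sync == 0 && t_async == 0) {
      dec <- NA_character_; cov <- 0
    } else if (abs(t_sync - t_async) < 1e-9) {
      dec <- NA_character_; cov <- NA_real_  # ambiguous: tied decisions
    } else {
      dec <- if (t_sync > t_async) "synchrony" else "asynchrony"
      cov <- max(t_sync, t_async) / denom
    }
    data.frame(session = session, role = role, segment_id = sid,
               start = seg$start, end = seg$end, duration = duration,
               both_coverage = cov, decision = dec)
  })
  cand <- do.call(rbind, cand)
  rownames(cand) <- NULL
  keep <- !is.na(cand$decision) &
    cand$duration >= cfg$min_scene_duration - 1e-9 &
    !is.na(cand$both_coverage) &
    cand$both_coverage >= cfg$min_both_coverage - 1e-9
  scenes <- cand[keep, , drop = FALSE]
  rownames(scenes) <- NULL
  attr(scenes, "candidates") <- cand
  scenes
}

#' Randomly select scenes per decision class
#'
#' Draws `cfg$n_select_per_class` scenes uniformly without replacement from
#' each decision class (asynchrony drawn first, then synchrony) and returns
#' them in randomized presentation order. All randomness comes from
#' `cfg$rng_seed`, so the selection is reproducible; the caller's RNG state
#' is left untouched. If a class holds fewer candidates than requested, all
#' of its scenes are returned and the shortfall is recorded in the
#' `shortfall` attribute (and raised as a warning).
#'
#' @param scenes Output of [build_scenes()].
#' @param cfg An [default_config()] object.
#' @return A data.frame of selected scenes with attribute `shortfall`, a
#'   named integer vector of missing counts per class.
#' @export
select_scenes <- function(scenes, cfg = default_config()) {
  k <- cfg$n_select_per_class
  withr::with_seed(cfg$rng_seed, {
    pick_class <- function(cls) {
      idx <- which(!is.na(scenes$decision) & scenes$decision == cls)
      if (length(idx) <= k) {
        idx
      } else {
        idx[sample.int(length(idx), k)]
      }
    }
    a_idx <- pick_class("asynchrony")
    s_idx <- pick_class("synchrony")
    chosen <- c(a_idx, s_idx)
    out <- scenes[chosen, , drop = FALSE]
    if (nrow(out) > 1L) out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    shortfall <- c(asynchrony = max(0L, k - length(a_idx)),
                   synchrony = max(0L, k - length(s_idx)))
    attr(out, "shortfall") <- shortfall
    if (any(shortfall > 0L)) {
      warning("scene selection shortfall: ",
              paste(names(shortfall)[shortfall > 0L],
                    shortfall[shortfall > 0L], sep = " -", collapse = ", "),
              call. = FALSE)
    }
    out
  })
}

#' Export scenes as a discrete annotation tier
#'
#' @param scenes Output of [build_scenes()] or [select_scenes()].
#' @param session,role Identifiers for the tier (default: taken from scenes).
#' @param annotator Machine annotator identifier.
#' @return A discrete [annotation_tier()] with labels
#'   `synchrony`/`asynchrony`, flagged as machine-produced.
#' @export
scenes_to_tier <- function(scenes, session = NULL, role = NULL,
                           annotator = "affsync.detect") {
  if (is.null(session)) session <- if (nrow(scenes)) scenes$session[1] else "session"
  if (is.null(role)) role <- if (nrow(scenes)) scenes$role[1] else "role"
  sc <- scheme("affective_synchrony", "discrete",
               labels = c("synchrony", "asynchrony"))
  seg <- if (nrow(scenes)) {
    s <- scenes[order(scenes$start), , drop = FALSE]
    data.frame(start = s$start, end = s$end, payload = s$decision)
  } else {
    NULL
  }
  annotation_tier(session, role, annotator, "machine", sc, seg)
}
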