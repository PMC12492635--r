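# Interval binning and ensemble fusion.
#
# Heterogeneous recognizer streams (per-segment sentiment scores, dense
# categorical emotion tiers, dense continuous valence tiers) are projected
# onto a common grid of half-open intervals [i*L, (i+1)*L). Within a bin a
# discrete tier aggregates to its duration-weighted mode ("dominant" label)
# and a continuous tier to its time-weighted mean; across the model ensemble,
# class channels are combined by majority vote and numeric channels by
# averaging.

#' Bin one annotation tier onto a regular interval grid
#'
#' Interval `i` covers `[i * L, (i + 1) * L)`. Discrete (and free) tiers
#' aggregate to the duration-weighted modal label within each bin; ties go to
#' the label appearing earliest in the bin. Continuous tiers aggregate to the
#' time-weighted mean. Bins the tier does not touch are absent from the
#' result.
#'
#' @param tier An [annotation_tier()].
#' @param interval_length Bin length `L` in seconds (> 0).
#' @return A data.frame with columns `interval` (integer index), `value`
#'   (label or numeric mean) and `time` (seconds of the bin covered by the
#'   tier). Sorted by `interval`.
#' @export
#' @examples
#' sc <- scheme("emotion", "discrete", labels = c("happy", "sad"))
#' t1 <- annotation_tier("s", "r", "m", "machine", sc,
#'                       data.frame(start = 0, end = 2, payload = "happy"))
#' bin_stream(t1, 1)
bin_stream <- function(tier, interval_length = 1.0) {
  stopifnot(inherits(tier, "affsync_tier"))
  if (!is.numeric(interval_length) || length(interval_length) != 1L ||
      interval_length <= 0) {
    stop("interval_length must be a positive number", call. = FALSE)
  }
  L <- interval_length
  seg <- tier$segments
  continuous <- tier$scheme$kind == "continuous"
  if (nrow(seg) == 0L) {
    return(data.frame(interval = integer(0),
                      value = if (continuous) numeric(0) else character(0),
                      time = numeric(0)))
  }
  first <- floor(seg$start / L + 1e-12)
  last <- ceiling(seg$end / L - 1e-12) - 1
  nb <- pmax(last - first + 1, 0)
  sid <- rep(seq_len(nrow(seg)), nb)
  bin <- first[sid] + (sequence(nb) - 1)
  ovl <- pmin(seg$end[sid], (bin + 1) * L) - pmax(seg$start[sid], bin * L)
  keep <- ovl > 1e-12
  sid <- sid[keep]; bin <- bin[keep]; ovl <- ovl[keep]
  if (length(bin) == 0L) {
    return(data.frame(interval = integer(0),
                      value = if (continuous) numeric(0) else character(0),
                      time = numeric(0)))
  }
  if (continuous) {
    num <- rowsum(as.numeric(seg$payload[sid]) * ovl, bin)
    den <- rowsum(ovl, bin)
    out <- data.frame(interval = as.integer(rownames(den)),
                      value = as.numeric(num / den),
                      time = as.numeric(den))
  } else {
    lab <- as.character(seg$payload[sid])
    key <- paste(bin, lab, sep = "\r")
    dur <- rowsum(ovl, key)
    firstpos <- tapply(seq_along(key), key, min)
    parts <- strsplit(rownames(dur), "\r", fixed = TRUE)
    kb <- as.integer(vapply(parts, `[`, "", 1L))
    kl <- vapply(parts, `[`, "", 2L)
    # per bin: max duration, ties to the earliest-appearing label
    ord <- order(kb, -dur[, 1], firstpos[rownames(dur)])
    kb_o <- kb[ord]
    pick <- ord[!duplicated(kb_o)]
    tot <- rowsum(ovl, bin)
    out <- data.frame(interval = as.integer(rownames(tot)),
                      value = kl[pick][match(as.integer(rownames(tot)), kb[pick])],
                      time = as.numeric(tot))
  }
  out <- out[order(out$interval), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Majority vote over class labels
#'
#' Returns the strictly most frequent label. When several labels tie for the
#' maximum, the vote resolves to `"neutral"` if neutral is among the tied
#' labels and to the sentinel `"unclassified"` otherwise, so a tie never
#' manufactures an affective claim.
#'
#' @param votes Character vector of class labels (`NA`s are dropped).
#' @param neutral_label Label treated as the conservative tie-break target.
#' @return A single label (possibly `"unclassified"`).
#' @export
#' @examples
#' majority_vote(c("positive", "positive", "negative"))
#' majority_vote(c("positive", "negative", "neutral"))
majority_vote <- function(votes, neutral_label = "neutral") {
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0L) stop("majority_vote: no votes", call. = FALSE)
  counts <- table(votes)
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) == 1L) return(tied)
  if (neutral_label %in% tied) return(neutral_label)
  "unclassified"
}

classify_sentiment_score <- function(score, threshold) {
  ifelse(is.na(score), NA_character_,
         ifelse(score > threshold, "positive",
                ifelse(score < -threshold, "negative", "neutral")))
}

#' Build the per-interval frame for one role of a session
#'
#' Projects the speech segments of `role` and the per-model recognizer
#' streams onto the configured interval grid. One row is produced per
#' (speech segment, interval) pair for every interval overlapped by the
#' segment; recognizer columns hold the per-model aggregates of
#' [bin_stream()] at that interval, and sentiment columns repeat the
#' segment's per-model scores.
#'
#' @param tr A [transcript()].
#' @param role Speaker whose segments form the scenes.
#' @param emotion_tiers List of discrete emotion tiers, one per model.
#' @param valence_tiers List of continuous valence tiers, one per model.
#' @param cfg An [default_config()] object.
#' @return A data.frame (one row per segment x interval) with columns
#'   `segment_id`, `interval`, `int_start`, `int_end`, `overlap`,
#'   `sentiment.<model>`, `emotion.<model>`, `valence.<model>`; the grid
#'   length is attached as attribute `interval_length`.
#' @export
build_interval_frame <- function(tr, role, emotion_tiers, valence_tiers,
                                 cfg = default_config()) {
  stopifnot(inherits(tr, "affsync_transcript"))
  L <- cfg$interval_length
  seg_idx <- which(tr$speaker == role)
  segs <- tr[seg_idx, , drop = FALSE]
  segs$segment_id <- seg_idx
  if (nrow(segs) == 0L) {
    stop("transcript has no segments for role '", role, "'", call. = FALSE)
  }
  first <- floor(segs$start / L + 1e-12)
  last <- ceiling(segs$end / L - 1e-12) - 1
  nb <- pmax(last - first + 1, 0)
  idx <- rep(seq_len(nrow(segs)), nb)
  interval <- first[idx] + (sequence(nb) - 1)
  frame <- data.frame(
    segment_id = segs$segment_id[idx],
    interval = as.integer(interval),
    int_start = interval * L,
    int_end = (interval + 1) * L
  )
  frame$overlap <- pmin(segs$end[idx], frame$int_end) -
    pmax(segs$start[idx], frame$int_start)
  smodels <- sentiment_models(tr)
  for (m in smodels) {
    frame[[paste0("sentiment.", m)]] <- segs[[paste0("sentiment.", m)]][idx]
  }
  add_binned <- function(tiers, prefix) {
    for (i in seq_along(tiers)) {
      tier <- tiers[[i]]
      stopifnot(inherits(tier, "affsync_tier"))
      nm <- if (!is.null(names(tiers)) && nzchar(names(tiers)[i])) {
        names(tiers)[i]
      } else {
        tier$annotator
      }
      b <- bin_stream(tier, L)
      frame[[paste0(prefix, ".", nm)]] <<- b$value[match(frame$interval, b$interval)]
    }
  }
  add_binned(emotion_tiers, "emotion")
  add_binned(valence_tiers, "valence")
  attr(frame, "interval_length") <- L
  frame
}

#' Fuse per-model interval values into ensemble decisions
#'
#' Fills the fused channels of an interval frame. Sentiment: mean of the
#' model scores thresholded at `+/- cfg$sentiment_threshold` (or, with
#' `sentiment_fusion = "vote"`, per-model classification followed by majority
#' vote). Emotion: majority vote over model labels, then mapped to a polarity
#' through `cfg$emotion_polarity`. Valence: mean of model values split at
#' `cfg$valence_midpoint` into `low`/`high` (or per-model vote). The result
#' is invariant under reordering of the models.
#'
#' @param frame Output of [build_interval_frame()].
#' @param cfg An [default_config()] object.
#' @return `frame` with added columns `sentiment`, `sentiment_class`,
#'   `emotion`, `emotion_polarity`, `valence`, `valence_class`.
#' @export
fuse_intervals <- function(frame, cfg = default_config()) {
  scol <- grep("^sentiment\\.", names(frame), value = TRUE)
  ecol <- grep("^emotion\\.", names(frame), value = TRUE)
  vcol <- grep("^valence\\.", names(frame), value = TRUE)
  if (length(scol) == 0L) stop("no sentiment model columns in frame", call. = FALSE)
  n <- nrow(frame)

  smat <- as.matrix(frame[, scol, drop = FALSE])
  frame$sentiment <- rowMeans(smat, na.rm = TRUE)
  if (cfg$sentiment_fusion == "mean") {
    frame$sentiment_class <- classify_sentiment_score(frame$sentiment,
                                                      cfg$sentiment_threshold)
  } else {
    cls <- matrix(classify_sentiment_score(smat, cfg$sentiment_threshold),
                  nrow = n)
    frame$sentiment_class <- apply(cls, 1L, majority_vote)
  }

  if (length(ecol) > 0L) {
    emat <- as.matrix(frame[, ecol, drop = FALSE])
    frame$emotion <- apply(emat, 1L, function(v) {
      if (all(is.na(v))) NA_character_ else majority_vote(v)
    })
    pol <- unlist(cfg$emotion_polarity)
    known <- unique(frame$emotion[!is.na(frame$emotion) &
                                    frame$emotion != "unclassified"])
    unknown <- setdiff(known, names(pol))
    if (length(unknown)) {
      stop("emotion label(s) absent from polarity map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    frame$emotion_polarity <- ifelse(
      is.na(frame$emotion) | frame$emotion == "unclassified",
      "neutral", pol[frame$emotion])
  } else {
    frame$emotion <- NA_character_
    frame$emotion_polarity <- "neutral"
  }

  if (length(vcol) > 0L) {
    vmat <- matrix(as.numeric(as.matrix(frame[, vcol, drop = FALSE])), nrow = n)
    if (cfg$valence_fusion == "mean") {
      frame$valence <- rowMeans(vmat, na.rm = TRUE)
      frame$valence[is.nan(frame$valence)] <- NA_real_
      frame$valence_class <- ifelse(is.na(frame$valence), NA_character_,
                                    ifelse(frame$valence > cfg$valence_midpoint,
                                           "high", "low"))
    } else {
      frame$valence <- rowMeans(vmat, na.rm = TRUE)
      frame$valence[is.nan(frame$valence)] <- NA_real_
      cls <- matrix(ifelse(is.na(vmat), NA_character_,
                           ifelse(vmat > cfg$valence_midpoint, "high", "low")),
                    nrow = n)
      vc <- apply(cls, 1L, function(v) {
        if (all(is.na(v))) NA_character_ else majority_vote(v)
      })
      vc[vc == "unclassified"] <- NA_character_  # tied ensemble: channel undecided
      frame$valence_class <- vc
    }
  } else {
    frame$valence <- NA_real_
    frame$valence_class <- NA_character_
  }
  frame
}
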