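# Typed annotation model: schemes, segments, tiers, transcripts.
# All intervals are half-open [start, end) in seconds, so that binning onto a
# regular grid partitions time exactly.

#' Create an annotation scheme
#'
#' A scheme declares what an annotation tier may contain: `discrete` tiers
#' carry labels from a fixed set, `continuous` tiers carry numeric samples in
#' a closed range, and `free` tiers carry arbitrary text (e.g. transcription).
#'
#' @param name Scheme identifier (single string).
#' @param kind One of `"discrete"`, `"continuous"`, `"free"`.
#' @param labels Character vector of permitted labels (discrete only, >= 1).
#' @param value_range Numeric `c(lo, hi)` with `lo < hi` (continuous only).
#' @return An object of class `affsync_scheme`.
#' @export
#' @examples
#' scheme("smile", "discrete", labels = c("smile", "none"))
#' scheme("valence", "continuous", value_range = c(0, 1))
scheme <- function(name, kind = c("discrete", "continuous", "free"),
                   labels = NULL, value_range = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "discrete") {
    if (is.null(labels) || length(labels) < 1L) {
      stop("discrete scheme '", name, "' needs at least one label", call. = FALSE)
    }
    labels <- as.character(labels)
    value_range <- NULL
  } else if (kind == "continuous") {
    if (is.null(value_range) || length(value_range) != 2L ||
        !is.numeric(value_range) || !(value_range[1] < value_range[2])) {
      stop("continuous scheme '", name, "' needs value_range = c(lo, hi) with lo < hi",
           call. = FALSE)
    }
    value_range <- as.numeric(value_range)
    labels <- NULL
  } else {
    labels <- NULL
    value_range <- NULL
  }
  structure(
    list(name = name, kind = kind, labels = labels, value_range = value_range),
    class = "affsync_scheme"
  )
}

#' @export
print.affsync_scheme <- function(x, ...) {
  extra <- switch(x$kind,
    discrete = paste0(" {", paste(x$labels, collapse = ", "), "}"),
    continuous = sprintf(" [%g, %g]", x$value_range[1], x$value_range[2]),
    free = ""
  )
  cat(sprintf("<scheme %s: %s%s>\n", x$name, x$kind, extra))
  invisible(x)
}

#' Create an annotation tier
#'
#' A tier is the time-ordered output of one annotator (human or machine) under
#' one scheme for one session and role. Segments are half-open intervals
#' `[start, end)` in seconds. The constructor sorts segments by start; it does
#' not validate invariants (use [validate_tier()] so that invalid data can be
#' inspected rather than rejected).
#'
#' @param session,role Identifiers.
#' @param annotator Annotator identifier.
#' @param annotator_type `"human"` or `"machine"`.
#' @param scheme An [scheme()] object.
#' @param segments A data.frame with columns `start`, `end`, `payload` and
#'   optionally `confidence` (fractions in `[0, 1]`, `NA` allowed). Payload is
#'   character for discrete/free schemes, numeric for continuous ones.
#' @return An object of class `affsync_tier`: a list with the identifying
#'   fields and a `segments` data.frame.
#' @export
#' @examples
#' sc <- scheme("smile", "discrete", labels = "smile")
#' annotation_tier("s1", "teacher", "coder1", "human", sc,
#'                 data.frame(start = 0, end = 2.5, payload = "smile"))
annotation_tier <- function(session, role, annotator, annotator_type = c("human", "machine"),
                            scheme, segments = NULL) {
  annotator_type <- match.arg(annotator_type)
  stopifnot(inherits(scheme, "affsync_scheme"))
  if (is.null(segments) || nrow(segments) == 0L) {
    segments <- data.frame(
      start = numeric(0),
      end = numeric(0),
      payload = if (scheme$kind == "continuous") numeric(0) else character(0),
      confidence = numeric(0)
    )
  } else {
    stopifnot(all(c("start", "end", "payload") %in% names(segments)))
    if (is.null(segments$confidence)) segments$confidence <- NA_real_
    segments <- segments[, c("start", "end", "payload", "confidence")]
    segments$start <- as.numeric(segments$start)
    segments$end <- as.numeric(segments$end)
    if (scheme$kind == "continuous") {
      segments$payload <- as.numeric(segments$payload)
    } else {
      segments$payload <- as.character(segments$payload)
    }
    segments <- segments[order(segments$start, segments$end), , drop = FALSE]
    rownames(segments) <- NULL
  }
  structure(
    list(session = session, role = role, annotator = annotator,
         annotator_type = annotator_type, scheme = scheme, segments = segments),
    class = "affsync_tier"
  )
}

#' @export
print.affsync_tier <- function(x, ...) {
  cat(sprintf("<tier %s/%s scheme=%s annotator=%s (%s), %d segments>\n",
              x$session, x$role, x$scheme$name, x$annotator, x$annotator_type,
              nrow(x$segments)))
  if (nrow(x$segments) > 0) print(head(x$segments, 5))
  invisible(x)
}

#' Validate a tier against its scheme's invariants
#'
#' Checks every segment of a tier: `start >= 0`, `start < end`, payload
#' membership in the scheme's label set (discrete) or value range (continuous),
#' confidence in `[0, 1]` when present, segments sorted by start, and absence
#' of intra-tier overlap for discrete and free tiers (continuous tiers may be
#' dense sample trains and may touch but not properly overlap either; only
#' discrete/free overlap is flagged).
#'
#' Violations are data, not exceptions: the function never throws on
#' well-typed input, so that invalid files can be reported in full.
#'
#' @param tier An [annotation_tier()].
#' @return A data.frame with columns `segment` (1-based index, `NA` for
#'   tier-level problems) and `rule` (human-readable broken rule). Zero rows
#'   iff the tier is valid.
#' @export
#' @examples
#' sc <- scheme("smile", "discrete", labels = "smile")
#' bad <- annotation_tier("s", "r", "a", "human", sc,
#'                        data.frame(start = 5, end = 5, payload = "smile"))
#' validate_tier(bad)
validate_tier <- function(tier) {
  stopifnot(inherits(tier, "affsync_tier"))
  seg <- tier$segments
  sc <- tier$scheme
  violations <- list()
  add <- function(segment, rule) {
    violations[[length(violations) + 1L]] <<- data.frame(segment = segment, rule = rule)
  }
  n <- nrow(seg)
  if (n == 0L) {
    return(data.frame(segment = integer(0), rule = character(0)))
  }
  for (i in seq_len(n)) {
    if (is.na(seg$start[i]) || is.na(seg$end[i])) {
      add(i, "start/end must be numeric and non-missing")
      next
    }
    if (seg$start[i] < 0) add(i, "start >= 0")
    if (!(seg$start[i] < seg$end[i])) add(i, "start < end")
    if (sc$kind == "discrete" && !(seg$payload[i] %in% sc$labels)) {
      add(i, sprintf("label '%s' not in scheme labels", seg$payload[i]))
    }
    if (sc$kind == "continuous") {
      v <- suppressWarnings(as.numeric(seg$payload[i]))
      if (is.na(v)) {
        add(i, "value must be numeric")
      } else if (v < sc$value_range[1] || v > sc$value_range[2]) {
        add(i, sprintf("value %g out of range [%g, %g]",
                       v, sc$value_range[1], sc$value_range[2]))
      }
    }
    if (!is.na(seg$confidence[i]) &&
        (seg$confidence[i] < 0 || seg$confidence[i] > 1)) {
      add(i, "confidence must lie in [0, 1]")
    }
  }
  if (isTRUE(is.unsorted(seg$start, na.rm = TRUE))) {
    add(NA_integer_, "segments must be sorted by start")
  }
  finite <- which(!is.na(seg$start) & !is.na(seg$end))
  if (sc$kind != "continuous" && length(finite) > 1L) {
    # half-open intervals: touching segments (end == next start) do not overlap
    ord <- finite[order(seg$start[finite], seg$end[finite])]
    s <- seg$start[ord]; e <- seg$end[ord]
    ovl <- which(s[-1] < e[-length(ord)])
    for (i in ovl) add(ord[i + 1L], "segments must not overlap within a discrete/free tier")
  }
  out <- if (length(violations)) do.call(rbind, violations) else
    data.frame(segment = integer(0), rule = character(0))
  rownames(out) <- NULL
  out
}

#' Slice a tier to a half-open time window
#'
#' Returns the segments intersecting `[t0, t1)`, clipped to the window.
#' Payloads and all tier metadata are unchanged; an empty result is valid.
#'
#' @param tier An [annotation_tier()].
#' @param window Numeric `c(t0, t1)` with `t0 < t1`; `t1` may be `Inf`.
#' @return A new `affsync_tier` containing the clipped segments.
#' @export
#' @examples
#' sc <- scheme("smile", "discrete", labels = "smile")
#' tr <- annotation_tier("s", "r", "a", "human", sc,
#'                       data.frame(start = 0, end = 10, payload = "smile"))
#' slice_tier(tr, c(4, 6))$segments
slice_tier <- function(tier, window) {
  stopifnot(inherits(tier, "affsync_tier"),
            is.numeric(window), length(window) == 2L, window[1] < window[2])
  seg <- tier$segments
  keep <- seg$end > window[1] & seg$start < window[2]
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) > 0L) {
    seg$start <- pmax(seg$start, window[1])
    seg$end <- pmin(seg$end, window[2])
  }
  rownames(seg) <- NULL
  out <- tier
  out$segments <- seg
  out
}

#' Build a diarized transcript table
#'
#' A transcript is a data.frame of speech segments with per-segment speaker,
#' timing, text, and the sentiment score assigned by each model of the
#' sentiment ensemble (scores in `[-1, 1]`, negative to positive).
#'
#' @param speaker Character vector of role identifiers.
#' @param start,end Numeric vectors, seconds, `start < end` per segment.
#' @param text Character vector.
#' @param sentiment_scores A data.frame (one column per sentiment model) or a
#'   list of named numeric vectors, one element per segment.
#' @return A data.frame of class `affsync_transcript` with columns `speaker`,
#'   `start`, `end`, `text` and one `sentiment.<model>` column per model.
#' @export
#' @examples
#' transcript(speaker = "patient", start = 0, end = 6, text = "...",
#'            sentiment_scores = data.frame(m1 = 0.8, m2 = 0.7, m3 = 0.9))
transcript <- function(speaker, start, end, text, sentiment_scores) {
  if (is.list(sentiment_scores) && !is.data.frame(sentiment_scores)) {
    sentiment_scores <- as.data.frame(do.call(rbind, lapply(sentiment_scores, unlist)))
  }
  stopifnot(is.data.frame(sentiment_scores))
  n <- length(start)
  stopifnot(length(speaker) %in% c(1L, n), length(end) == n,
            length(text) %in% c(1L, n), nrow(sentiment_scores) == n)
  bad <- which(!(start < end))
  if (length(bad)) {
    stop("transcript segment ", bad[1], ": start < end violated", call. = FALSE)
  }
  rng <- range(as.matrix(sentiment_scores), na.rm = TRUE)
  if (rng[1] < -1 || rng[2] > 1) {
    stop("sentiment scores must lie in [-1, 1]", call. = FALSE)
  }
  out <- data.frame(speaker = speaker, start = as.numeric(start),
                    end = as.numeric(end), text = text)
  names(sentiment_scores) <- paste0("sentiment.", names(sentiment_scores))
  out <- cbind(out, sentiment_scores)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("affsync_transcript", "data.frame")
  out
}

#' Names of the sentiment models present in a transcript
#' @param tr A [transcript()].
#' @return Character vector of model names.
#' @export
sentiment_models <- function(tr) {
  sub("^sentiment\\.", "", grep("^sentiment\\.", names(tr), value = TRUE))
}
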