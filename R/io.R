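# Flat-file dialect for tiers and transcripts.
#
# A tier lives in two files: a semicolon-separated CSV `<stem>.csv` with
# header `start;end;payload;confidence` (UTF-8, timestamps at millisecond
# precision, free-text payloads double-quoted so prose with separators
# round-trips), and a JSON sidecar `<stem>.json` carrying session, role,
# annotator and the scheme. Transcripts are a JSON array of segment objects.

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

#' Write an annotation tier to disk
#'
#' Writes `<path>` (semicolon CSV, columns `start;end;payload;confidence`)
#' and the sidecar `<stem>.json` describing session, role, annotator and
#' scheme. Timestamps are serialized at millisecond precision, continuous
#' payloads at 1e-6; [read_tier()] inverts the pair exactly at that
#' resolution.
#'
#' @param tier An [annotation_tier()].
#' @param path Destination CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_tier <- function(tier, path) {
  stopifnot(inherits(tier, "affsync_tier"))
  seg <- tier$segments
  payload <- if (tier$scheme$kind == "continuous") {
    fmt_num(as.numeric(seg$payload), 6)
  } else {
    p <- as.character(seg$payload)
    # quote payloads so free text containing the separator survives
    paste0('"', gsub('"', '""', p), '"')
  }
  lines <- c(
    "start;end;payload;confidence",
    sprintf("%s;%s;%s;%s", fmt_num(seg$start, 3), fmt_num(seg$end, 3),
            payload, fmt_num(seg$confidence, 3))
  )
  writeLines(lines, path, useBytes = TRUE)
  meta <- list(
    session = tier$session, role = tier$role,
    annotator = tier$annotator, annotator_type = tier$annotator_type,
    scheme = list(name = tier$scheme$name, kind = tier$scheme$kind,
                  labels = tier$scheme$labels, value_range = tier$scheme$value_range)
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read an annotation tier from disk
#'
#' Reads the CSV written by [write_tier()] together with its JSON sidecar.
#' Structural problems (wrong field count, non-numeric timestamps,
#' `start >= end`, payload outside the scheme) are reported as errors naming
#' the offending file line.
#'
#' @param path Path to the tier CSV; the sidecar `<stem>.json` must exist.
#' @return An [annotation_tier()].
#' @export
read_tier <- function(path) {
  if (!file.exists(path)) stop("tier file not found: ", path, call. = FALSE)
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path)) {
    stop("tier sidecar not found: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("session", "role", "annotator", "annotator_type", "scheme")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("tier sidecar ", basename(meta_path), " lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sc <- scheme(meta$scheme$name, meta$scheme$kind,
               labels = meta$scheme$labels, value_range = meta$scheme$value_range)

  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || lines[1] != "start;end;payload;confidence") {
    stop("malformed tier header in ", basename(path),
         " (expected 'start;end;payload;confidence')", call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(annotation_tier(meta$session, meta$role, meta$annotator,
                           meta$annotator_type, sc))
  }
  nf <- count.fields(textConnection(body), sep = ";", quote = "\"",
                     blank.lines.skip = FALSE)
  bad <- which(is.na(nf) | nf != 4L)
  if (length(bad)) {
    stop("malformed row (expected 4 fields), line ", bad[1] + 1L,
         " of ", basename(path), call. = FALSE)
  }
  df <- read.table(text = body, sep = ";", quote = "\"",
                   col.names = c("start", "end", "payload", "confidence"),
                   colClasses = c("character", "character", "character", "character"),
                   stringsAsFactors = FALSE, encoding = "UTF-8")
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  conf <- suppressWarnings(as.numeric(ifelse(df$confidence == "", NA, df$confidence)))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L
    if (is.na(start[i]) || is.na(end[i])) {
      stop("non-numeric timestamp, line ", line, " of ", basename(path), call. = FALSE)
    }
    if (!(start[i] < end[i])) {
      stop("start < end, line ", line, " of ", basename(path), call. = FALSE)
    }
    if (start[i] < 0) {
      stop("start >= 0, line ", line, " of ", basename(path), call. = FALSE)
    }
  }
  payload <- df$payload
  if (sc$kind == "continuous") {
    payload <- suppressWarnings(as.numeric(payload))
    bad <- which(is.na(payload))
    if (length(bad)) {
      stop("non-numeric payload, line ", bad[1] + 1L, " of ", basename(path),
           call. = FALSE)
    }
    out_rng <- which(payload < sc$value_range[1] | payload > sc$value_range[2])
    if (length(out_rng)) {
      stop("value out of range, line ", out_rng[1] + 1L, " of ", basename(path),
           call. = FALSE)
    }
  } else if (sc$kind == "discrete") {
    bad <- which(!(payload %in% sc$labels))
    if (length(bad)) {
      stop("label '", payload[bad[1]], "' not in scheme '", sc$name,
           "', line ", bad[1] + 1L, " of ", basename(path), call. = FALSE)
    }
  }
  annotation_tier(meta$session, meta$role, meta$annotator, meta$annotator_type, sc,
                  data.frame(start = start, end = end, payload = payload,
                             confidence = conf))
}

#' Write a transcript to a JSON file
#'
#' Serializes a [transcript()] as a JSON array of objects with fields
#' `speaker`, `start`, `end`, `text` and a `sentiment_scores` map from model
#' name to score.
#'
#' @param tr A [transcript()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(tr, path) {
  models <- sentiment_models(tr)
  items <- lapply(seq_len(nrow(tr)), function(i) {
    scores <- as.list(setNames(
      as.numeric(tr[i, paste0("sentiment.", models)]), models))
    list(speaker = tr$speaker[i], start = tr$start[i], end = tr$end[i],
         text = tr$text[i], sentiment_scores = scores)
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transcript from a JSON file
#'
#' @param path Path to a JSON array of transcript segment objects as written
#'   by [write_transcript()].
#' @return A [transcript()].
#' @export
read_transcript <- function(path) {
  if (!file.exists(path)) stop("transcript file not found: ", path, call. = FALSE)
  items <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(items) == 0L) {
    stop("transcript is empty: ", path, call. = FALSE)
  }
  need <- c("speaker", "start", "end", "text", "sentiment_scores")
  for (i in seq_along(items)) {
    missing <- setdiff(need, names(items[[i]]))
    if (length(missing)) {
      stop("transcript segment ", i, " lacks field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  scores <- do.call(rbind, lapply(items, function(it) {
    as.data.frame(lapply(it$sentiment_scores, as.numeric),
                  check.names = FALSE)
  }))
  transcript(
    speaker = vapply(items, function(it) it$speaker, character(1)),
    start = vapply(items, function(it) as.numeric(it$start), numeric(1)),
    end = vapply(items, function(it) as.numeric(it$end), numeric(1)),
    text = vapply(items, function(it) it$text, character(1)),
    sentiment_scores = scores
  )
}
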