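# Pipeline configuration: every tunable of the detection procedure in one
# place, with defaults matching the published scene-selection protocol
# (1-second intervals, sentiment threshold +/-0.5, valence midpoint 0.5,
# >= 5 s scenes, >= 70% both-channel coverage, 3 scenes per class).

.config_defaults <- function() {
  list(
    interval_length = 1.0,
    sentiment_threshold = 0.5,
    valence_midpoint = 0.5,
    min_scene_duration = 5.0,
    min_both_coverage = 0.70,
    n_select_per_class = 3L,
    rng_seed = 1L,
    emotion_polarity = as.list(default_emotion_polarity()),
    sentiment_fusion = "mean",   # "mean": average scores then threshold; "vote": per-model class vote
    valence_fusion = "mean",     # "mean": average values then split; "vote": per-model class vote
    coverage_denominator = "full"  # "full": whole segment duration; "classified": non-neutral time only
  )
}

#' Default pipeline configuration
#'
#' Returns the configuration object controlling every stage of the
#' (a)synchrony detection pipeline. Fields and defaults:
#'
#' * `interval_length` (1.0 s): grid length for binning model streams.
#' * `sentiment_threshold` (0.5): magnitude beyond which fused sentiment
#'   counts as positive (> +0.5) or negative (< -0.5); otherwise neutral.
#' * `valence_midpoint` (0.5): fused valence above this is class `high`.
#' * `min_scene_duration` (5.0 s): minimum speech-segment duration of a scene.
#' * `min_both_coverage` (0.70): minimum fraction of the segment classified on
#'   the `both` channel with the modal decision.
#' * `n_select_per_class` (3): scenes drawn per decision class.
#' * `rng_seed` (1): seed for the scene-selection RNG.
#' * `emotion_polarity`: label -> polarity map, see
#'   [default_emotion_polarity()].
#' * `sentiment_fusion` (`"mean"`): combine model sentiment scores by
#'   averaging then thresholding, or (`"vote"`) by per-model classification
#'   followed by majority vote.
#' * `valence_fusion` (`"mean"`): likewise for valence.
#' * `coverage_denominator` (`"full"`): whether both-channel coverage is
#'   measured against the full segment duration or only its classifiable
#'   (non-neutral-sentiment) time.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `affsync_config`.
#' @export
#' @examples
#' cfg <- default_config(min_scene_duration = 4)
#' cfg$sentiment_threshold
default_config <- function(...) {
  overrides <- list(...)
  build_config(overrides, where = "default_config()")
}

build_config <- function(overrides, where = "config") {
  cfg <- .config_defaults()
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop(where, ": unknown key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg <- modifyList(cfg, overrides)
  }
  check_num <- function(key, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    v <- cfg[[key]]
    ok <- is.numeric(v) && length(v) == 1L && !is.na(v) &&
      (if (lo_open) v > lo else v >= lo) && (if (hi_open) v < hi else v <= hi)
    if (!ok) {
      stop(where, ": '", key, "' out of range (", lo, if (lo_open) " <" else " <=",
           " value ", if (hi_open) "< " else "<= ", hi, ")", call. = FALSE)
    }
  }
  check_num("interval_length", 0, Inf, lo_open = TRUE)
  check_num("sentiment_threshold", 0, 1, lo_open = TRUE)
  check_num("valence_midpoint", 0, 1)
  check_num("min_scene_duration", 0, Inf)
  check_num("min_both_coverage", 0, 1, lo_open = TRUE)
  if (!(is.numeric(cfg$n_select_per_class) && cfg$n_select_per_class >= 1)) {
    stop(where, ": 'n_select_per_class' must be >= 1", call. = FALSE)
  }
  cfg$n_select_per_class <- as.integer(cfg$n_select_per_class)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg$sentiment_fusion <- match.arg(cfg$sentiment_fusion, c("mean", "vote"))
  cfg$valence_fusion <- match.arg(cfg$valence_fusion, c("mean", "vote"))
  cfg$coverage_denominator <- match.arg(cfg$coverage_denominator, c("full", "classified"))
  pol <- unlist(cfg$emotion_polarity)
  if (!all(pol %in% .polarities)) {
    stop(where, ": 'emotion_polarity' values must be positive/negative/neutral",
         call. = FALSE)
  }
  cfg$emotion_polarity <- as.list(pol)
  structure(cfg, class = "affsync_config")
}

#' Read a pipeline configuration file
#'
#' Reads a YAML or JSON configuration. Missing keys take the defaults of
#' [default_config()]; unknown keys and out-of-range values are errors naming
#' the offending key. An empty file yields the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `affsync_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a mapping: ", path, call. = FALSE)
  build_config(raw, where = paste0("config '", basename(path), "'"))
}

#' @export
print.affsync_config <- function(x, ...) {
  cat("<affsync pipeline config>\n")
  for (k in setdiff(names(x), "emotion_polarity")) {
    cat(sprintf("  %-22s %s\n", k, as.character(x[[k]])))
  }
  pol <- unlist(x$emotion_polarity)
  cat("  emotion_polarity:      ",
      paste(names(pol), pol, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
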