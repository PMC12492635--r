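# End-to-end workflows. `detect_scenes()` chains fusion -> classification ->
# scene assembly -> seeded selection on in-memory objects; the `run_*`
# functions wrap the workflows for the command-line tool, reading and
# writing the flat-file dialect and emitting a run manifest.

#' Detect affective (a)synchrony scenes in one session
#'
#' Runs the full detection pipeline for one role of a session: builds the
#' interval frame over the speech segments, fuses the model ensembles,
#' classifies per-interval (a)synchrony, assembles candidate scenes under the
#' duration and coverage filters, and draws the seeded per-class selection.
#'
#' @param tr A [transcript()].
#' @param emotion_tiers,valence_tiers Lists of per-model tiers.
#' @param cfg An [default_config()] object.
#' @param session Session identifier.
#' @param role Target role (default: speaker of the first segment).
#' @return A list with `classified` (interval frame), `candidates`, `scenes`
#'   (filtered), `selected`, and `manifest` (per-stage counts).
#' @export
detect_scenes <- function(tr, emotion_tiers, valence_tiers,
                          cfg = default_config(),
                          session = "session", role = NULL) {
  if (is.null(role)) role <- tr$speaker[1]
  frame <- build_interval_frame(tr, role, emotion_tiers, valence_tiers, cfg)
  fused <- fuse_intervals(frame, cfg)
  classified <- classify_intervals(fused, cfg)
  scenes <- build_scenes(classified, tr, cfg, session = session, role = role)
  candidates <- attr(scenes, "candidates")
  selected <- select_scenes(scenes, cfg)
  counts_by <- function(x) {
    out <- c(synchrony = 0L, asynchrony = 0L, unclassified = 0L)
    t <- table(x)
    out[names(t)[names(t) %in% names(out)]] <-
      as.integer(t[names(t) %in% names(out)])
    out
  }
  manifest <- list(
    session = session, role = role, seed = cfg$rng_seed,
    n_segments = nrow(tr[tr$speaker == role, ]),
    n_intervals_fused = nrow(classified),
    interval_decisions = as.list(counts_by(classified$decision)),
    n_candidates = nrow(candidates),
    n_scenes = nrow(scenes),
    scene_decisions = as.list(counts_by(scenes$decision)),
    n_selected = nrow(selected),
    shortfall = as.list(attr(selected, "shortfall")),
    tool_version = as.character(utils::packageVersion("affsync"))
  )
  list(classified = classified, candidates = candidates, scenes = scenes,
       selected = selected, manifest = manifest)
}

scene_report <- function(res) {
  sel <- res$selected
  list(
    manifest = res$manifest,
    scenes = lapply(seq_len(nrow(sel)), function(i) {
      list(session = sel$session[i], role = sel$role[i],
           segment_id = sel$segment_id[i],
           start = sel$start[i], end = sel$end[i],
           duration = sel$duration[i],
           both_coverage = sel$both_coverage[i],
           decision = sel$decision[i])
    })
  )
}

#' Run scene detection on a session directory
#'
#' Reads a session laid out by [write_session()], runs [detect_scenes()],
#' and writes `scenes.csv` (+ sidecar; the selected scenes as a discrete
#' machine tier) and `report.json` (manifest plus per-scene coverage) into
#' `out_dir`.
#'
#' @param session_dir Session directory.
#' @param cfg An [default_config()] object.
#' @param out_dir Output directory (default: `session_dir`).
#' @return The [detect_scenes()] result, invisibly.
#' @export
run_detect <- function(session_dir, cfg = default_config(),
                       out_dir = session_dir) {
  s <- read_session(session_dir)
  role <- s$roles[["target"]]
  res <- detect_scenes(s$transcript, s$emotion_tiers, s$valence_tiers,
                       cfg, session = s$session, role = role)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tier(scenes_to_tier(res$selected, session = s$session, role = role),
             file.path(out_dir, "scenes.csv"))
  jsonlite::write_json(scene_report(res), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Run the smile-mirroring search on two tier files
#'
#' @param tier_path_a,tier_path_b Paths to the two smile tier CSVs.
#' @param rule A [window_rule()] (default: [smile_mirroring_rule()] over the
#'   two tiers' roles).
#' @param out_path Destination CSV for the detected tier.
#' @return The output [annotation_tier()], invisibly.
#' @export
run_search <- function(tier_path_a, tier_path_b, rule = NULL, out_path) {
  a <- read_tier(tier_path_a)
  b <- read_tier(tier_path_b)
  if (is.null(rule)) {
    rule <- smile_mirroring_rule(roles = c(a$role, b$role),
                                 scheme_name = a$scheme$name)
  }
  out <- apply_rule(rule, list(a, b))
  write_tier(out, out_path)
  invisible(out)
}

#' Run an agreement report on tier files
#'
#' @param tier_paths Character vector of tier CSV paths (>= 2).
#' @param interval_length Grid length in seconds.
#' @param out_path Optional destination for the JSON report.
#' @return The report list, invisibly.
#' @export
run_agreement <- function(tier_paths, interval_length = 1.0, out_path = NULL) {
  tiers <- lapply(tier_paths, read_tier)
  rep <- agreement_report(tiers, interval_length)
  if (!is.null(out_path)) {
    jsonlite::write_json(rep, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(rep)
}

#' Validate tier files and report violations
#'
#' @param tier_paths Character vector of tier CSV paths.
#' @return A data.frame of violations with a `file` column; zero rows iff
#'   all tiers are valid.
#' @export
run_validate <- function(tier_paths) {
  out <- lapply(tier_paths, function(p) {
    v <- validate_tier(read_tier(p))
    if (nrow(v)) cbind(file = basename(p), v) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out)) do.call(rbind, out) else
    data.frame(file = character(0), segment = integer(0), rule = character(0))
}
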