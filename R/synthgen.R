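# Synthetic session generator.
#
# Emulates the output shapes of a multimodal recognizer stack on a dyadic
# session -- a diarized transcript with a three-model sentiment ensemble,
# three dense categorical-emotion streams, three dense continuous valence
# streams and one binary smile tier per interlocutor -- with (a)synchrony
# structure planted at known segments so every downstream stage can be tested
# against ground truth without recordings or models.

#' Describe a synthetic session
#'
#' The plan fixes the structure of one simulated dyadic session. The target
#' role's speech segments alternate with the other role's; segment durations
#' are lognormal (default meanlog 1.5, sdlog 0.6 seconds, straddling the 5 s
#' scene filter so both filter branches occur), separated by uniform gaps of
#' at least one second (so no two speech segments of the target role share a
#' grid interval). Background affect is neutral: emotion label `"neutral"`,
#' valence 0.5, sentiment scores near zero. Planted scenes override this on
#' enough 1 s intervals of their segment to reach the requested both-channel
#' coverage: an asynchronous plant pairs decisive sentiment with
#' opposite-polarity emotion and opposite-side valence, a synchronous plant
#' with matching ones. Per-model noise (Gaussian jitter on scores and
#' valence, label flips on emotion labels and valence side) is applied after
#' planting, independently for each of the three models per modality.
#'
#' @param session Session identifier.
#' @param roles Named character vector `c(target = ..., other = ...)`; the
#'   target role's segments are scene candidates.
#' @param n_segments Speech segments of the target role.
#' @param n_other_segments Speech segments of the other role.
#' @param duration_meanlog,duration_sdlog Lognormal parameters of segment
#'   durations (seconds).
#' @param gap_range Uniform range of inter-segment gaps (seconds, min >= 1).
#' @param planted_scenes `NULL` or a data.frame with columns `segment`
#'   (1-based index among target segments), `decision` (`"synchrony"` /
#'   `"asynchrony"`), `coverage` (target both-channel coverage in `[0, 1]`)
#'   and optionally `duration` (seconds, overrides the lognormal draw) and
#'   `sentiment_sign` (+1 / -1, default random).
#' @param jitter_sd Gaussian noise sd applied per model to sentiment scores
#'   and valence values.
#' @param label_flip_prob Per interval and model, probability of replacing
#'   the emotion label with a random other label and of mirroring the
#'   valence value about 0.5 (in `[0, 1)`).
#' @param n_smiles Smile events of the target role.
#' @param p_mirror Probability that a smile is answered by the other role.
#' @param smile_duration_range,smile_max_lag Smile event duration range and
#'   maximum answer lag (seconds).
#' @param rng_seed Seed for all randomness of the generator.
#' @return A list of class `affsync_plan`.
#' @export
session_plan <- function(session = "synthetic-session",
                         roles = c(target = "patient", other = "therapist"),
                         n_segments = 10L,
                         n_other_segments = n_segments,
                         duration_meanlog = 1.5, duration_sdlog = 0.6,
                         gap_range = c(1, 3),
                         planted_scenes = NULL,
                         jitter_sd = 0.05,
                         label_flip_prob = 0,
                         n_smiles = 4L, p_mirror = 0.7,
                         smile_duration_range = c(1, 3), smile_max_lag = 2,
                         rng_seed = 1L) {
  stopifnot(length(roles) == 2L, n_segments >= 1L,
            duration_sdlog > 0, gap_range[1] >= 1, gap_range[1] <= gap_range[2],
            smile_duration_range[1] > 0)
  if (is.null(names(roles))) names(roles) <- c("target", "other")
  if (!(label_flip_prob >= 0 && label_flip_prob < 1)) {
    stop("label_flip_prob must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(planted_scenes)) {
    stopifnot(is.data.frame(planted_scenes),
              all(c("segment", "decision", "coverage") %in% names(planted_scenes)))
    if (any(planted_scenes$coverage > 1 | planted_scenes$coverage < 0)) {
      stop("infeasible plan: coverage targets must lie in [0, 1]", call. = FALSE)
    }
    stopifnot(all(planted_scenes$decision %in% c("synchrony", "asynchrony")),
              all(planted_scenes$segment >= 1),
              all(planted_scenes$segment <= n_segments),
              !anyDuplicated(planted_scenes$segment))
    if (!is.null(planted_scenes$duration) &&
        any(planted_scenes$duration <= 0, na.rm = TRUE)) {
      stop("planted durations must be positive", call. = FALSE)
    }
  }
  structure(
    list(session = session, roles = roles,
         n_segments = as.integer(n_segments),
         n_other_segments = as.integer(n_other_segments),
         duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
         gap_range = gap_range, planted_scenes = planted_scenes,
         jitter_sd = jitter_sd, label_flip_prob = label_flip_prob,
         n_smiles = as.integer(n_smiles), p_mirror = p_mirror,
         smile_duration_range = smile_duration_range,
         smile_max_lag = smile_max_lag,
         rng_seed = as.integer(rng_seed)),
    class = "affsync_plan"
  )
}

.negative_emotions <- c("sadness", "anger", "fear", "disgust", "contempt")
.emotion_labels <- names(default_emotion_polarity())

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic session from a plan
#'
#' Realizes the plan with its seed: the diarized transcript (three-model
#' sentiment scores per segment), three emotion tiers, three valence tiers,
#' one smile tier per role, and the ground truth listing each planted scene
#' with its achieved pre-noise coverage and whether it qualifies under the
#' default scene filters (duration >= 5 s, both-channel coverage >= 0.70).
#' Running the default pipeline on a noise-free realisation reproduces the
#' qualifying ground-truth scenes exactly.
#'
#' @param plan A [session_plan()].
#' @return A list with elements `session`, `roles`, `transcript`,
#'   `emotion_tiers` (3), `valence_tiers` (3), `sentiment_tiers` (3,
#'   per-segment scores as continuous tiers), `smile_tiers` (2, named by
#'   role), and `ground_truth` (data.frame).
#' @export
#' @examples
#' plan <- session_plan(n_segments = 4, rng_seed = 7,
#'   planted_scenes = data.frame(segment = 2, decision = "asynchrony",
#'                               coverage = 1, duration = 8))
#' s <- generate_session(plan)
#' s$ground_truth
generate_session <- function(plan) {
  stopifnot(inherits(plan, "affsync_plan"))
  withr::with_seed(plan$rng_seed, generate_session_impl(plan))
}

generate_session_impl <- function(plan) {
  target <- plan$roles[["target"]]
  other <- plan$roles[["other"]]
  n_t <- plan$n_segments
  n_o <- plan$n_other_segments

  dur_t <- rlnorm(n_t, plan$duration_meanlog, plan$duration_sdlog)
  planted <- plan$planted_scenes
  if (!is.null(planted)) {
    if (is.null(planted$duration)) planted$duration <- NA_real_
    has_d <- !is.na(planted$duration)
    dur_t[planted$segment[has_d]] <- planted$duration[has_d]
    if (is.null(planted$sentiment_sign)) planted$sentiment_sign <- NA_real_
    miss <- is.na(planted$sentiment_sign)
    planted$sentiment_sign[miss] <- sample(c(-1, 1), sum(miss), replace = TRUE)
  }
  dur_o <- rlnorm(n_o, plan$duration_meanlog, plan$duration_sdlog)

  # strictly alternating timeline, gaps >= 1 s keep target segments on
  # disjoint grid intervals
  rows <- list()
  t_cur <- runif(1, 0, 1)
  t_pos <- matrix(NA_real_, n_t, 2)
  for (i in seq_len(max(n_t, n_o))) {
    if (i <= n_t) {
      t_pos[i, ] <- c(t_cur, t_cur + dur_t[i])
      rows[[length(rows) + 1L]] <- data.frame(speaker = target,
                                              start = t_cur,
                                              end = t_cur + dur_t[i],
                                              tseg = i)
      t_cur <- t_cur + dur_t[i] + runif(1, plan$gap_range[1], plan$gap_range[2])
    }
    if (i <= n_o) {
      rows[[length(rows) + 1L]] <- data.frame(speaker = other,
                                              start = t_cur,
                                              end = t_cur + dur_o[i],
                                              tseg = NA_integer_)
      t_cur <- t_cur + dur_o[i] + runif(1, plan$gap_range[1], plan$gap_range[2])
    }
  }
  tl <- do.call(rbind, rows)
  t_end <- ceiling(max(tl$end)) + 1
  n_iv <- as.integer(t_end)

  # base (pre-noise) affect: neutral everywhere, overridden on planted intervals
  emo_base <- rep("neutral", n_iv)
  val_base <- rep(0.5, n_iv)
  sent_base <- runif(nrow(tl), -0.3, 0.3)

  gt <- NULL
  if (!is.null(planted)) {
    gt_rows <- lapply(seq_len(nrow(planted)), function(j) {
      p <- planted[j, ]
      s0 <- t_pos[p$segment, 1]; e0 <- t_pos[p$segment, 2]
      duration <- e0 - s0
      ivs <- seq.int(floor(s0), ceiling(e0) - 1)
      ovl <- pmin(e0, ivs + 1) - pmax(s0, ivs)
      ok <- ovl > 1e-12
      ivs <- ivs[ok]; ovl <- ovl[ok]
      cum <- cumsum(ovl)
      n_take <- if (p$coverage <= 0) 0L else
        which(cum >= p$coverage * duration - 1e-9)[1]
      take <- ivs[seq_len(n_take)]
      achieved <- if (n_take) cum[n_take] / duration else 0
      sign <- p$sentiment_sign
      # nonverbal polarity: opposite of sentiment for asynchrony, same for synchrony
      nonverbal_neg <- (p$decision == "asynchrony") == (sign > 0)
      emo_base[take + 1L] <<- if (nonverbal_neg) {
        sample(.negative_emotions, length(take), replace = TRUE)
      } else {
        rep("happiness", length(take))
      }
      val_base[take + 1L] <<- if (nonverbal_neg) {
        runif(length(take), 0.15, 0.35)
      } else {
        runif(length(take), 0.65, 0.85)
      }
      seg_row <- which(!is.na(tl$tseg) & tl$tseg == p$segment)
      sent_base[seg_row] <<- sign * 0.8
      data.frame(segment = p$segment, start = s0, end = e0, duration = duration,
                 decision = p$decision, sentiment_sign = sign,
                 target_coverage = p$coverage, achieved_coverage = achieved)
    })
    gt <- do.call(rbind, gt_rows)
    cfg0 <- .config_defaults()
    gt$qualifies <- gt$duration >= cfg0$min_scene_duration - 1e-9 &
      gt$achieved_coverage >= cfg0$min_both_coverage - 1e-9
  } else {
    gt <- data.frame(segment = integer(0), start = numeric(0), end = numeric(0),
                     duration = numeric(0), decision = character(0),
                     sentiment_sign = numeric(0), target_coverage = numeric(0),
                     achieved_coverage = numeric(0), qualifies = logical(0))
  }
  ord <- order(tl$start)
  tl <- tl[ord, , drop = FALSE]
  sent_base <- sent_base[ord]
  gt$segment_id <- match(gt$segment, tl$tseg)

  # three models per modality, independent noise applied after planting
  flip <- function(n) runif(n) < plan$label_flip_prob
  emotion_tiers <- lapply(1:3, function(m) {
    lab <- emo_base
    f <- which(flip(n_iv))
    if (length(f)) {
      lab[f] <- vapply(lab[f], function(cur) {
        sample(setdiff(.emotion_labels, cur), 1L)
      }, character(1))
    }
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    annotation_tier(plan$session, target, paste0("emotion-model-", m), "machine",
                    scheme("emotion", "discrete", labels = .emotion_labels),
                    data.frame(start = starts, end = ends, payload = r$values))
  })
  valence_tiers <- lapply(1:3, function(m) {
    v <- val_base
    f <- flip(n_iv)
    v[f] <- 1 - v[f]
    v <- clamp(v + rnorm(n_iv, 0, plan$jitter_sd), 0, 1)
    annotation_tier(plan$session, target, paste0("valence-model-", m), "machine",
                    scheme("valence", "continuous", value_range = c(0, 1)),
                    data.frame(start = seq_len(n_iv) - 1, end = seq_len(n_iv),
                               payload = v))
  })
  scores <- vapply(1:3, function(m) {
    clamp(sent_base + rnorm(nrow(tl), 0, plan$jitter_sd), -1, 1)
  }, numeric(nrow(tl)))
  colnames(scores) <- paste0("sentiment-model-", 1:3)
  tr <- transcript(speaker = tl$speaker, start = tl$start, end = tl$end,
                   text = sprintf("(synthetic utterance %d)", seq_len(nrow(tl))),
                   sentiment_scores = as.data.frame(scores))
  sentiment_tiers <- lapply(1:3, function(m) {
    annotation_tier(plan$session, target, colnames(scores)[m], "machine",
                    scheme("sentiment", "continuous", value_range = c(-1, 1)),
                    data.frame(start = tl$start, end = tl$end,
                               payload = scores[, m]))
  })

  smile_tiers <- generate_smiles(plan, t_end)

  list(session = plan$session, roles = plan$roles, transcript = tr,
       emotion_tiers = emotion_tiers, valence_tiers = valence_tiers,
       sentiment_tiers = sentiment_tiers, smile_tiers = smile_tiers,
       ground_truth = gt)
}

generate_smiles <- function(plan, t_end) {
  target <- plan$roles[["target"]]
  other <- plan$roles[["other"]]
  sc <- scheme("smile", "discrete", labels = "smile")
  mk <- function(role, seg) {
    annotation_tier(plan$session, role, paste0("smile-", role), "machine", sc, seg)
  }
  n <- plan$n_smiles
  if (n < 1L || t_end < 5) {
    out <- list(mk(target, NULL), mk(other, NULL))
    names(out) <- c(target, other)
    return(out)
  }
  a_start <- sort(runif(n, 0, max(1, t_end - 6)))
  a_dur <- runif(n, plan$smile_duration_range[1], plan$smile_duration_range[2])
  # enforce non-overlap within the tier
  for (i in seq_len(n)[-1]) {
    a_start[i] <- max(a_start[i], a_start[i - 1] + a_dur[i - 1] + 0.2)
  }
  mirrored <- runif(n) < plan$p_mirror
  b_start <- a_start[mirrored] + runif(sum(mirrored), 0, plan$smile_max_lag)
  b_dur <- runif(sum(mirrored), plan$smile_duration_range[1],
                 plan$smile_duration_range[2])
  if (length(b_start) > 1L) {
    for (i in seq_along(b_start)[-1]) {
      b_start[i] <- max(b_start[i], b_start[i - 1] + b_dur[i - 1] + 0.2)
    }
  }
  out <- list(
    mk(target, data.frame(start = a_start, end = a_start + a_dur,
                          payload = "smile")),
    mk(other, if (length(b_start)) {
      data.frame(start = b_start, end = b_start + b_dur, payload = "smile")
    } else NULL)
  )
  names(out) <- c(target, other)
  out
}

#' Generate a synthetic rating matrix
#'
#' Each rater column is `true_scores` plus independent Gaussian noise, the
#' standard parallel-measurements model under which Cronbach's alpha
#' approaches 1 as the noise vanishes.
#'
#' @param n_items Number of items (>= 2).
#' @param n_raters Number of raters (>= 2).
#' @param true_scores Numeric vector of length `n_items` (default: standard
#'   normal draws).
#' @param rater_noise_sd Noise standard deviation.
#' @param rng_seed Seed.
#' @return An items x raters numeric matrix.
#' @export
generate_rating_matrix <- function(n_items, n_raters = 3L, true_scores = NULL,
                                   rater_noise_sd = 0.1, rng_seed = 1L) {
  stopifnot(n_items >= 2L, n_raters >= 2L)
  withr::with_seed(as.integer(rng_seed), {
    if (is.null(true_scores)) true_scores <- rnorm(n_items)
    stopifnot(length(true_scores) == n_items)
    m <- vapply(seq_len(n_raters), function(j) {
      true_scores + rnorm(n_items, 0, rater_noise_sd)
    }, numeric(n_items))
    colnames(m) <- paste0("rater-", seq_len(n_raters))
    m
  })
}

#' Write a generated session to a directory
#'
#' Lays out the session in the flat-file dialect: `transcript.json`, nine
#' recognizer stream tiers (`sentiment-model-*.csv`, `emotion-model-*.csv`,
#' `valence-model-*.csv` with JSON sidecars), two smile tiers
#' (`smile-<role>.csv`), `ground_truth.json` and a `session.json` manifest
#' naming the roles.
#'
#' @param s Output of [generate_session()].
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(s, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcript(s$transcript, file.path(dir, "transcript.json"))
  for (i in 1:3) {
    write_tier(s$sentiment_tiers[[i]], file.path(dir, sprintf("sentiment-model-%d.csv", i)))
    write_tier(s$emotion_tiers[[i]], file.path(dir, sprintf("emotion-model-%d.csv", i)))
    write_tier(s$valence_tiers[[i]], file.path(dir, sprintf("valence-model-%d.csv", i)))
  }
  for (role in names(s$smile_tiers)) {
    write_tier(s$smile_tiers[[role]], file.path(dir, sprintf("smile-%s.csv", role)))
  }
  jsonlite::write_json(s$ground_truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(session = s$session, roles = as.list(s$roles)),
                       file.path(dir, "session.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Session directory.
#' @return A list with `session`, `roles`, `transcript`, `emotion_tiers`,
#'   `valence_tiers`, `smile_tiers` (ground truth, if present, under
#'   `ground_truth`).
#' @export
read_session <- function(dir) {
  manifest_path <- file.path(dir, "session.json")
  if (!file.exists(manifest_path)) {
    stop("session manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  tr <- read_transcript(file.path(dir, "transcript.json"))
  read_set <- function(pattern) {
    files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
    lapply(files, read_tier)
  }
  emotion_tiers <- read_set("^emotion-model-.*\\.csv$")
  valence_tiers <- read_set("^valence-model-.*\\.csv$")
  smile_files <- sort(list.files(dir, pattern = "^smile-.*\\.csv$", full.names = TRUE))
  smile_tiers <- lapply(smile_files, read_tier)
  names(smile_tiers) <- vapply(smile_tiers, `[[`, "", "role")
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  list(session = manifest$session, roles = unlist(manifest$roles),
       transcript = tr, emotion_tiers = emotion_tiers,
       valence_tiers = valence_tiers, smile_tiers = smile_tiers,
       ground_truth = gt)
}
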