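# Sliding-window rule engine over annotation tiers.
#
# A window rule slides a fixed-length window over a set of tiers in fixed
# steps, evaluates a predicate on the segments clipped to each window, and
# merges positive windows (closure under overlap/adjacency) into maximal
# machine-annotated segments. The shipped predicate detects smile mirroring
# in a dyad: one interlocutor's smile answered by the other's within a short
# lag, or two smiles overlapping substantially.

#' Define a sliding-window rule
#'
#' @param window_length Window length in seconds (> 0).
#' @param step Step between window starts in seconds (> 0).
#' @param tiers_required List of `c(role, scheme_name)` pairs the rule needs.
#' @param condition Predicate identifier; currently `"mirroring"`.
#' @param params Named list of predicate parameters. For `mirroring`:
#'   `max_lag` (seconds, must be `< window_length`) and `min_overlap`
#'   (fraction of the shorter smile).
#' @param output_label Label written on detected segments.
#' @return A list of class `affsync_rule`.
#' @export
#' @examples
#' smile_mirroring_rule(roles = c("teacher", "parent"))
window_rule <- function(window_length, step, tiers_required,
                        condition = "mirroring",
                        params = list(), output_label = condition) {
  stopifnot(window_length > 0, step > 0)
  condition <- match.arg(condition, c("mirroring"))
  if (condition == "mirroring") {
    params <- modifyList(list(max_lag = 3.0, min_overlap = 0.5), params)
    if (!(params$max_lag < window_length)) {
      stop("max_lag must be smaller than window_length", call. = FALSE)
    }
    if (length(tiers_required) != 2L) {
      stop("mirroring needs exactly two tiers (one per role)", call. = FALSE)
    }
  }
  structure(
    list(window_length = window_length, step = step,
         tiers_required = tiers_required, condition = condition,
         params = params, output_label = output_label),
    class = "affsync_rule"
  )
}

#' Default smile-mirroring rule
#'
#' A 4-second window advanced in 1-second steps, firing when one role's
#' smile onset is answered by the other's within 3 seconds or when their
#' smiles overlap by at least half of the shorter smile. The defaults track
#' typical smile-response latencies in dyadic conversation and are ordinary
#' parameters, adjustable per call or via the rule section of a config file.
#'
#' @param roles Character vector of the two role identifiers.
#' @param scheme_name Scheme name of the smile tiers.
#' @param window_length,step,max_lag,min_overlap Rule parameters (seconds /
#'   fraction).
#' @return A [window_rule()].
#' @export
smile_mirroring_rule <- function(roles, scheme_name = "smile",
                                 window_length = 4.0, step = 1.0,
                                 max_lag = 3.0, min_overlap = 0.5) {
  window_rule(window_length, step,
              tiers_required = list(c(roles[1], scheme_name),
                                    c(roles[2], scheme_name)),
              condition = "mirroring",
              params = list(max_lag = max_lag, min_overlap = min_overlap),
              output_label = "mirroring")
}

#' Smile-mirroring window predicate
#'
#' True iff, among the segments clipped to the current window, some smile
#' onset in one tier is answered within `max_lag` seconds by a smile onset in
#' the other (in either direction; onsets truncated by the window edge do not
#' count as onsets), or some pair of smiles overlaps by at least
#' `min_overlap` of the shorter smile. Symmetric in its two arguments and
#' monotone in `max_lag`.
#'
#' @param seg_a,seg_b Data.frames with `start`/`end` columns, clipped to the
#'   window; `true_onset` (logical) may mark starts that are genuine smile
#'   onsets rather than clip artefacts (defaults to all `TRUE`).
#' @param max_lag Maximum onset-to-onset lag in seconds.
#' @param min_overlap Minimum overlap as a fraction of the shorter smile.
#' @return Logical scalar.
#' @export
mirroring_condition <- function(seg_a, seg_b, max_lag = 3.0, min_overlap = 0.5) {
  if (nrow(seg_a) == 0L || nrow(seg_b) == 0L) return(FALSE)
  on_a <- seg_a$start[if (is.null(seg_a$true_onset)) TRUE else seg_a$true_onset]
  on_b <- seg_b$start[if (is.null(seg_b$true_onset)) TRUE else seg_b$true_onset]
  if (length(on_a) && length(on_b)) {
    lags <- abs(outer(on_a, on_b, `-`))
    if (any(lags <= max_lag + 1e-9)) return(TRUE)
  }
  for (i in seq_len(nrow(seg_a))) {
    ovl <- pmin(seg_a$end[i], seg_b$end) - pmax(seg_a$start[i], seg_b$start)
    shorter <- pmin(seg_a$end[i] - seg_a$start[i], seg_b$end - seg_b$start)
    if (any(ovl >= min_overlap * shorter - 1e-9 & ovl > 0)) return(TRUE)
  }
  FALSE
}

clip_with_onsets <- function(segments, t0, t1) {
  keep <- segments$end > t0 & segments$start < t1
  seg <- segments[keep, , drop = FALSE]
  if (nrow(seg)) {
    seg$true_onset <- seg$start >= t0
    seg$start <- pmax(seg$start, t0)
    seg$end <- pmin(seg$end, t1)
  } else {
    seg$true_onset <- logical(0)
  }
  seg
}

find_rule_tier <- function(tiers, role, scheme_name) {
  for (tier in tiers) {
    if (identical(tier$role, role) && identical(tier$scheme$name, scheme_name)) {
      return(tier)
    }
  }
  stop("required tier missing: role '", role, "', scheme '", scheme_name, "'",
       call. = FALSE)
}

#' Apply a sliding-window rule to a set of tiers
#'
#' Evaluates the rule's predicate on every window `[k * step,
#' k * step + window_length)` covering the tiers' time span, merges
#' overlapping or adjacent positive windows into maximal segments, and
#' returns them as a machine-annotated discrete tier labeled with the rule's
#' `output_label`.
#'
#' @param rule A [window_rule()].
#' @param tiers List of validated [annotation_tier()]s; must contain every
#'   `(role, scheme)` pair the rule requires.
#' @return A discrete [annotation_tier()] (possibly empty).
#' @export
apply_rule <- function(rule, tiers) {
  stopifnot(inherits(rule, "affsync_rule"))
  matched <- lapply(rule$tiers_required, function(rq) {
    find_rule_tier(tiers, rq[1], rq[2])
  })
  for (tier in matched) {
    v <- validate_tier(tier)
    if (nrow(v)) {
      stop("invalid tier (role '", tier$role, "'): ", v$rule[1], call. = FALSE)
    }
  }
  t_end <- max(0, vapply(matched, function(t) {
    if (nrow(t$segments)) max(t$segments$end) else 0
  }, numeric(1)))
  out_scheme <- scheme(rule$output_label, "discrete", labels = rule$output_label)
  session <- matched[[1]]$session
  empty <- annotation_tier(session, "dyad", paste0("affsync.", rule$condition),
                           "machine", out_scheme)
  if (t_end <= 0) return(empty)
  starts <- seq(0, max(0, t_end - rule$step), by = rule$step)
  hits <- vapply(starts, function(t0) {
    t1 <- t0 + rule$window_length
    clipped <- lapply(matched, function(tier) clip_with_onsets(tier$segments, t0, t1))
    if (rule$condition == "mirroring") {
      mirroring_condition(clipped[[1]], clipped[[2]],
                          max_lag = rule$params$max_lag,
                          min_overlap = rule$params$min_overlap)
    } else {
      FALSE
    }
  }, logical(1))
  if (!any(hits)) return(empty)
  # merge positive windows (closure under overlap/adjacency)
  w_start <- starts[hits]
  w_end <- pmin(w_start + rule$window_length, t_end)
  merged_start <- numeric(0); merged_end <- numeric(0)
  cur_s <- w_start[1]; cur_e <- w_end[1]
  for (i in seq_along(w_start)[-1]) {
    if (w_start[i] <= cur_e + 1e-9) {
      cur_e <- max(cur_e, w_end[i])
    } else {
      merged_start <- c(merged_start, cur_s); merged_end <- c(merged_end, cur_e)
      cur_s <- w_start[i]; cur_e <- w_end[i]
    }
  }
  merged_start <- c(merged_start, cur_s); merged_end <- c(merged_end, cur_e)
  annotation_tier(session, "dyad", paste0("affsync.", rule$condition), "machine",
                  out_scheme,
                  data.frame(start = merged_start, end = merged_end,
                             payload = rule$output_label))
}
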