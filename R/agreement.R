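# Inter-rater agreement over multi-annotator tiers: Cohen's kappa for two
# categorical raters, Cronbach's alpha for >= 2 numeric raters. Missing
# entries are handled by listwise (complete-case) deletion; variances use the
# unbiased (n - 1) estimator.

#' Align several tiers of one scheme into a rating matrix
#'
#' Bins each tier onto the common interval grid (via [bin_stream()]) and
#' stacks the binned values as columns, one per rater. Intervals no rater
#' labeled are dropped; intervals some raters missed carry `NA` there.
#'
#' @param tiers List of [annotation_tier()]s sharing session, role and
#'   scheme.
#' @param interval_length Grid length in seconds.
#' @return A matrix (items x raters) with interval indices as row names and
#'   annotator identifiers as column names; character for discrete/free
#'   schemes, numeric for continuous ones.
#' @export
align_tiers_to_matrix <- function(tiers, interval_length = 1.0) {
  stopifnot(length(tiers) >= 2L)
  kinds <- vapply(tiers, function(t) t$scheme$kind, character(1))
  names_ <- vapply(tiers, function(t) t$scheme$name, character(1))
  if (length(unique(kinds)) != 1L || length(unique(names_)) != 1L) {
    stop("all tiers must share one scheme (got: ",
         paste(unique(names_), collapse = ", "), ")", call. = FALSE)
  }
  binned <- lapply(tiers, bin_stream, interval_length = interval_length)
  all_iv <- sort(unique(unlist(lapply(binned, `[[`, "interval"))))
  cols <- lapply(binned, function(b) b$value[match(all_iv, b$interval)])
  m <- do.call(cbind, cols)
  rownames(m) <- all_iv
  colnames(m) <- make.unique(vapply(tiers, `[[`, "", "annotator"))
  m <- m[rowSums(!is.na(m)) > 0L, , drop = FALSE]
  m
}

#' Cohen's kappa for two categorical raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' observed agreement `p_o` and chance agreement `p_e` from the two raters'
#' marginal label frequencies. Incomplete items (any `NA`) are dropped.
#' When `p_e = 1` (both raters constant on the same label) the statistic is
#' 1 if they agree perfectly and undefined otherwise.
#'
#' @param m Items x 2 matrix (or data.frame) of labels.
#' @return A list with `kappa`, `p_o`, `p_e`, `n_items`, `n_dropped`.
#' @export
#' @examples
#' m <- cbind(r1 = c("a", "a", "b", "b"), r2 = c("a", "a", "b", "a"))
#' cohens_kappa(m)$kappa
cohens_kappa <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2L) stop("Cohen's kappa requires exactly 2 raters", call. = FALSE)
  cc <- complete.cases(m)
  n_dropped <- sum(!cc)
  m <- m[cc, , drop = FALSE]
  n <- nrow(m)
  if (n < 2L) stop("Cohen's kappa needs at least 2 complete items", call. = FALSE)
  labels <- sort(unique(c(m[, 1], m[, 2])))
  p_o <- mean(m[, 1] == m[, 2])
  f1 <- table(factor(m[, 1], levels = labels)) / n
  f2 <- table(factor(m[, 2], levels = labels)) / n
  p_e <- sum(as.numeric(f1) * as.numeric(f2))
  if (abs(1 - p_e) < 1e-15) {
    if (abs(1 - p_o) < 1e-15) {
      kappa <- 1
    } else {
      stop("Cohen's kappa undefined: chance agreement is 1 but observed is not",
           call. = FALSE)
    }
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  list(kappa = kappa, p_o = p_o, p_e = p_e, n_items = n, n_dropped = n_dropped)
}

#' Cronbach's alpha for numeric raters
#'
#' Internal consistency `alpha = k / (k - 1) * (1 - sum(var_j) / var_total)`
#' over `k` rater columns, where `var_j` are the per-rater variances and
#' `var_total` the variance of the item sums, all unbiased sample variances
#' over complete items. Invariant under adding a constant to any rater's
#' column.
#'
#' @param m Items x raters numeric matrix (or data.frame).
#' @return A list with `alpha`, `n_items`, `n_raters`, `n_dropped`.
#' @export
#' @examples
#' m <- cbind(r1 = c(1, 2, 3, 4), r2 = c(1.1, 2.2, 2.9, 4.2))
#' cronbachs_alpha(m)$alpha
cronbachs_alpha <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  k <- ncol(m)
  if (k < 2L) stop("Cronbach's alpha requires >= 2 raters", call. = FALSE)
  cc <- complete.cases(m)
  n_dropped <- sum(!cc)
  m <- m[cc, , drop = FALSE]
  n <- nrow(m)
  if (n < 2L) stop("Cronbach's alpha needs at least 2 complete items", call. = FALSE)
  var_total <- var(rowSums(m))
  if (var_total < 1e-15) {
    stop("Cronbach's alpha undefined: total score variance is zero", call. = FALSE)
  }
  var_raters <- sum(apply(m, 2L, var))
  alpha <- k / (k - 1) * (1 - var_raters / var_total)
  list(alpha = alpha, n_items = n, n_raters = k, n_dropped = n_dropped)
}

#' Agreement report over tier files
#'
#' Convenience wrapper: aligns tiers into a rating matrix and computes the
#' statistic appropriate to the scheme kind (kappa for two discrete raters,
#' alpha for numeric raters).
#'
#' @param tiers List of [annotation_tier()]s.
#' @param interval_length Grid length in seconds.
#' @return A list with `statistic` name, its `value`, `n_items`, `n_raters`,
#'   `n_dropped`.
#' @export
agreement_report <- function(tiers, interval_length = 1.0) {
  m <- align_tiers_to_matrix(tiers, interval_length)
  kind <- tiers[[1]]$scheme$kind
  if (kind == "continuous") {
    r <- cronbachs_alpha(m)
    list(statistic = "cronbachs_alpha", value = r$alpha, n_items = r$n_items,
         n_raters = r$n_raters, n_dropped = r$n_dropped)
  } else {
    r <- cohens_kappa(m)
    list(statistic = "cohens_kappa", value = r$kappa, n_items = r$n_items,
         n_raters = 2L, n_dropped = r$n_dropped)
  }
}
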