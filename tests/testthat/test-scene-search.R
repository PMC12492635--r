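smile_tier <- function(role, starts, ends) {
  annotation_tier("s1", role, paste0("smile-", role), "machine",
                  scheme("smile", "discrete", labels = "smile"),
                  if (length(starts)) {
                    data.frame(start = starts, end = ends, payload = "smile")
                  } else NULL)
}

# brute-force window predicate: loops over every onset pair and every
# segment pair of the clipped lists
mirror_oracle <- function(a, b, max_lag, min_overlap) {
  hit <- FALSE
  oa <- a$start[a$true_onset %||% rep(TRUE, nrow(a))]
  ob <- b$start[b$true_onset %||% rep(TRUE, nrow(b))]
  for (x in oa) for (y in ob) if (abs(x - y) <= max_lag + 1e-9) hit <- TRUE
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    ovl <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    shorter <- min(a$end[i] - a$start[i], b$end[j] - b$start[j])
    if (ovl > 0 && ovl >= min_overlap * shorter - 1e-9) hit <- TRUE
  }
  hit
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("mirroring_condition follows onset lag and overlap rules", {
  a <- data.frame(start = 10, end = 12)
  b <- data.frame(start = 11.5, end = 13)
  expect_true(mirroring_condition(a, b, max_lag = 3))
  b_far <- data.frame(start = 14, end = 20)
  expect_false(mirroring_condition(a, b_far, max_lag = 3, min_overlap = 0.5))
  # no onset within lag but substantial overlap of the shorter smile
  a2 <- data.frame(start = 0, end = 20)
  b2 <- data.frame(start = 9, end = 11)
  expect_true(mirroring_condition(a2, b2, max_lag = 3, min_overlap = 0.5))
  expect_false(mirroring_condition(a, data.frame(start = numeric(0),
                                                 end = numeric(0)), 3, 0.5))
})

test_that("mirroring_condition is symmetric and agrees with the pairwise oracle", {
  set.seed(61)
  for (rep in 1:500) {
    na <- sample(0:3, 1); nb <- sample(0:3, 1)
    mk <- function(n) {
      if (n == 0) return(data.frame(start = numeric(0), end = numeric(0)))
      s <- sort(runif(n, 0, 10))
      data.frame(start = s, end = s + runif(n, 0.2, 3))
    }
    a <- mk(na); b <- mk(nb)
    lag <- runif(1, 0.5, 4); mo <- runif(1, 0.2, 0.9)
    got <- mirroring_condition(a, b, lag, mo)
    expect_identical(got, mirror_oracle(a, b, lag, mo))
    expect_identical(got, mirroring_condition(b, a, lag, mo))
  }
})

test_that("apply_rule merges positive windows over the co-smile region", {
  tiers <- list(smile_tier("teacher", 10, 12), smile_tier("parent", 11, 13))
  rule <- smile_mirroring_rule(c("teacher", "parent"))
  out <- apply_rule(rule, tiers)
  expect_identical(out$annotator_type, "machine")
  expect_identical(nrow(out$segments), 1L)
  expect_identical(out$segments$payload, "mirroring")
  # the merged segment covers the co-smile region...
  expect_lte(out$segments$start, 10)
  expect_gte(out$segments$end, 13)

  # ...and agrees with a brute-force window enumeration oracle
  starts <- seq(0, 12, by = rule$step)
  hits <- vapply(starts, function(t0) {
    clip <- function(seg) {
      keep <- seg$end > t0 & seg$start < t0 + 4
      s <- seg[keep, , drop = FALSE]
      s$true_onset <- s$start >= t0
      s$start <- pmax(s$start, t0); s$end <- pmin(s$end, t0 + 4)
      s
    }
    mirror_oracle(clip(tiers[[1]]$segments), clip(tiers[[2]]$segments), 3, 0.5)
  }, logical(1))
  expect_equal(out$segments$start, min(starts[hits]))
  expect_equal(out$segments$end, min(max(starts[hits]) + 4, 13))
})

test_that("apply_rule handles absent co-smiling and identical tiers", {
  rule <- smile_mirroring_rule(c("teacher", "parent"))
  no_b <- list(smile_tier("teacher", c(2, 20), c(4, 22)),
               smile_tier("parent", numeric(0), numeric(0)))
  expect_identical(nrow(apply_rule(rule, no_b)$segments), 0L)

  same <- list(smile_tier("teacher", c(2, 20), c(4, 22)),
               smile_tier("parent", c(2, 20), c(4, 22)))
  out <- apply_rule(rule, same)
  covered <- sum(out$segments$end - out$segments$start)
  expect_gte(covered, 4)  # at least the total smile duration

  expect_error(apply_rule(rule, list(smile_tier("teacher", 1, 2))),
               "required tier missing")
  bad <- list(smile_tier("teacher", 3, 2), smile_tier("parent", 1, 2))
  expect_error(apply_rule(rule, bad), "invalid tier")
})

test_that("detections grow monotonically with max_lag and stay within window union", {
  set.seed(62)
  for (rep in 1:20) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    mk_spans <- function(n) {
      s <- sort(runif(n, 0, 30))
      e <- pmin(s + runif(n, 0.3, 2), c(s[-1] - 0.1, Inf))
      list(s = s, e = pmax(e, s + 0.05))
    }
    a <- mk_spans(na); b <- mk_spans(nb)
    tiers <- list(smile_tier("teacher", a$s, a$e),
                  smile_tier("parent", b$s, b$e))
    small <- apply_rule(smile_mirroring_rule(c("teacher", "parent"),
                                             max_lag = 1), tiers)
    large <- apply_rule(smile_mirroring_rule(c("teacher", "parent"),
                                             max_lag = 3.5), tiers)
    # every detection at the small lag is contained in one at the larger lag
    for (i in seq_len(nrow(small$segments))) {
      inside <- any(large$segments$start <= small$segments$start[i] + 1e-9 &
                      large$segments$end >= small$segments$end[i] - 1e-9)
      expect_true(inside)
    }
    t_end <- max(vapply(tiers, function(t) max(t$segments$end), numeric(1)))
    if (nrow(large$segments)) {
      expect_true(all(large$segments$end <= t_end + 4 + 1e-9))
      expect_true(all(large$segments$start >= 0))
    }
  }
})
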