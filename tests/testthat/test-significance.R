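# exact upper-tail oracle by direct summation of the binomial pmf
tail_oracle <- function(n, N, p) {
  if (p >= 1) return(1)
  sum(choose(N, n:N) * p^(n:N) * (1 - p)^(N - (n:N)))
}

test_that("fragment visibility sums marginals and normalises", {
  cc <- contact_counts(data.frame(frag_i = c(1, 1, 2), frag_j = c(2, 3, 3),
                                  count = c(8, 1, 1)))
  vis <- fragment_visibility(cc)
  expect_equal(vis$end_count, c(9, 9, 2))
  expect_equal(vis$visibility, c(0.45, 0.45, 0.10))
  expect_equal(attr(cc, "N"), 10)
  # single pair: both ends at 0.5
  one <- fragment_visibility(contact_counts(
    data.frame(frag_i = 1, frag_j = 2, count = 1)))
  expect_equal(one$visibility, c(0.5, 0.5))
  # sum of end counts is 2N on random tables
  set.seed(601)
  for (k in 1:10) {
    df <- data.frame(frag_i = sample(10, 20, TRUE),
                     frag_j = sample(11:20, 20, TRUE),
                     count = sample(5, 20, TRUE))
    cc2 <- contact_counts(df)
    v <- fragment_visibility(cc2)
    expect_equal(sum(v$end_count), 2 * attr(cc2, "N"))
    expect_equal(sum(v$visibility), 1, tolerance = 1e-12)
  }
})

test_that("contact_counts canonicalises and validates", {
  cc <- contact_counts(data.frame(frag_i = c(2, 1), frag_j = c(1, 2),
                                  count = c(3, 4)))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$count, 7)
  expect_true(all(cc$frag_i < cc$frag_j))
  expect_error(contact_counts(data.frame(frag_i = 1, frag_j = 1, count = 1)),
               "self-pair")
  expect_error(contact_counts(data.frame(frag_i = 1, frag_j = 2, count = 0)),
               "positive")
})

test_that("binomial caller reproduces the exact tail on the worked example", {
  cc <- contact_counts(data.frame(frag_i = c(1, 1, 2), frag_j = c(2, 3, 3),
                                  count = c(8, 1, 1)))
  res <- binomial_interaction_test(cc)
  ab <- res[res$frag_i == 1 & res$frag_j == 2, ]
  expect_equal(ab$expected_p, 2 * 0.45 * 0.45)
  expect_equal(ab$pvalue, tail_oracle(8, 10, 0.405))
  # count == N: the upper tail collapses to p^N (<= p)
  full <- binomial_interaction_test(contact_counts(
    data.frame(frag_i = 1, frag_j = 2, count = 3)))
  expect_equal(full$expected_p, 0.5)
  expect_equal(full$pvalue, 0.5^3)
  expect_lte(full$pvalue, full$expected_p)
})

test_that("caller matches exact enumeration on all 3-fragment tables", {
  for (nab in 0:6) for (nac in 0:6) for (nbc in 0:6) {
    N <- nab + nac + nbc
    if (N < 1 || N > 12) next
    df <- data.frame(frag_i = c(1, 1, 2), frag_j = c(2, 3, 3),
                     count = c(nab, nac, nbc))
    df <- df[df$count > 0, ]
    cc <- contact_counts(df)
    ends <- c(`1` = 0, `2` = 0, `3` = 0)
    for (r in seq_len(nrow(df))) {
      ends[as.character(df$frag_i[r])] <-
        ends[as.character(df$frag_i[r])] + df$count[r]
      ends[as.character(df$frag_j[r])] <-
        ends[as.character(df$frag_j[r])] + df$count[r]
    }
    r_or <- ends / (2 * N)
    res <- suppressWarnings(binomial_interaction_test(cc))
    for (r in seq_len(nrow(df))) {
      p_or <- 2 * r_or[as.character(df$frag_i[r])] *
        r_or[as.character(df$frag_j[r])]
      row <- res[res$frag_i == df$frag_i[r] & res$frag_j == df$frag_j[r], ]
      expect_equal(row$pvalue, tail_oracle(df$count[r], N, p_or),
                   tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  # q >= p, monotone in p, permutation-invariant
  set.seed(602)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cumulative significance curve matches the worked example", {
  q <- c(0.04, 0.04, 0.03, 1e-3, 1e-6)
  cv <- cumulative_significance_curve(q)
  expect_equal(cv$levels, c(1, 2, 3, 6))
  expect_equal(cv$cum_counts, c(5, 3, 2, 1))
  expect_equal(cv$slopes, c(-2, -1, -1 / 3))
  # C(v1) equals the input count; C positive and non-increasing
  expect_equal(cv$cum_counts[1], length(q))
  expect_true(all(diff(cv$cum_counts) <= 0))
  expect_true(all(cv$slopes <= 0))
  # all equal q: single level, no slopes
  cv1 <- cumulative_significance_curve(c(0.01, 0.01))
  expect_equal(length(cv1$levels), 1L)
  expect_equal(length(cv1$slopes), 0L)
  # q = 1 maps to level 0
  expect_equal(cumulative_significance_curve(1)$levels, 0)
  # invalid inputs
  expect_error(cumulative_significance_curve(numeric()), "no significant")
  expect_error(cumulative_significance_curve(c(0.1, 0)), "positive")
  # tiny q floored before the log
  expect_equal(cumulative_significance_curve(1e-320)$levels, 300)
})

test_that("rounding of significance levels is half away from zero", {
  expect_equal(round_half_away(c(1.4, 1.5, 2.5, -1.5)), c(1, 2, 3, -2))
  # 0.04 -> 1.40 -> 1 ; 0.03 -> 1.52 -> 2
  expect_equal(cumulative_significance_curve(c(0.04))$levels, 1)
  expect_equal(cumulative_significance_curve(c(0.03))$levels, 2)
})

test_that("elbow threshold follows the slope rule", {
  cv <- cumulative_significance_curve(c(0.04, 0.04, 0.03, 1e-3, 1e-6))
  # |slopes| = {2, 1, 1/3}: only the first strictly exceeds 1
  expect_equal(lf_threshold(cv), 2)
  # slope exactly 1 does not count as "above 1"
  flat <- structure(list(levels = c(1, 2), cum_counts = c(2, 1),
                         slopes = -1, call_levels = c(1, 2)),
                    class = "lf_curve")
  expect_equal(lf_threshold(flat), 1)
  # steep throughout -> highest level under both rules
  steep <- structure(list(levels = 1:4, cum_counts = c(11, 6, 3, 1),
                          slopes = c(-5, -3, -2), call_levels = rep(1, 11)),
                     class = "lf_curve")
  expect_equal(lf_threshold(steep), 4)
  expect_equal(lf_threshold(steep, "first-at-or-below"), 4)
  # single level: fallback keeps everything
  one <- cumulative_significance_curve(c(0.01, 0.01))
  expect_equal(lf_threshold(one), one$levels[1])
})

test_that("both elbow rules are deterministic on a fuzz corpus", {
  set.seed(603)
  for (k in 1:50) {
    q <- 10^-runif(sample(1:40, 1), 0, 8)
    cv <- cumulative_significance_curve(q)
    t1a <- lf_threshold(cv, "last-above")
    t1b <- lf_threshold(cv, "last-above")
    t2 <- lf_threshold(cv, "first-at-or-below")
    expect_identical(t1a, t1b)
    expect_true(t1a %in% cv$levels)
    expect_true(t2 %in% cv$levels)
    # under both rules the threshold never exceeds the top level
    expect_lte(t1a, max(cv$levels))
  }
})

test_that("local filtering retains the worked-example subset per bait", {
  cs <- call_set(data.frame(bait_id = 2L, oe_id = c(11L, 12L, 13L, 14L, 15L),
                            metric_value = c(0.04, 0.04, 0.03, 1e-3, 1e-6)),
                 "qvalue")
  lf <- local_filter(cs)
  expect_equal(lf$thresholds$threshold, 2)
  expect_equal(sort(lf$calls$calls$metric_value), sort(c(0.03, 1e-3, 1e-6)))
  # single-interaction bait is retained via the fallback
  one <- call_set(data.frame(bait_id = 3L, oe_id = 9L, metric_value = 0.04),
                  "qvalue")
  expect_equal(nrow(local_filter(one)$calls$calls), 1L)
  # score input is rejected
  sc <- call_set(data.frame(bait_id = 2L, oe_id = 1L, metric_value = 5),
                 "score")
  expect_error(local_filter(sc), "q-value")
})

test_that("local filtering treats baits independently of order", {
  df <- data.frame(bait_id = rep(c(4L, 9L), each = 5),
                   oe_id = c(11:15, 21:25),
                   metric_value = rep(c(0.04, 0.04, 0.03, 1e-3, 1e-6), 2))
  a <- local_filter(call_set(df, "qvalue"))
  b <- local_filter(call_set(df[sample(nrow(df)), ], "qvalue"))
  key <- function(x) {
    k <- paste(x$calls$calls$bait_id, x$calls$calls$oe_id)
    sort(k)
  }
  expect_equal(key(a), key(b))
  expect_equal(a$thresholds, b$thresholds)
  # output is a subset of input, and every retained level >= every
  # discarded level within a bait
  expect_true(all(paste(a$calls$calls$bait_id, a$calls$calls$oe_id) %in%
                    paste(df$bait_id, df$oe_id)))
  for (b_id in unique(df$bait_id)) {
    inb <- df[df$bait_id == b_id, ]
    kept <- a$calls$calls[a$calls$calls$bait_id == b_id, ]
    lv <- round_half_away(-log10(inb$metric_value))
    kv <- round_half_away(-log10(kept$metric_value))
    disc <- lv[!paste(b_id, inb$oe_id) %in% paste(b_id, kept$oe_id)]
    if (length(disc) && length(kv)) expect_true(min(kv) >= max(disc))
  }
})
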