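#' Cumulative significance curve of one bait
#'
#' For one bait's globally significant interactions, significance values
#' `-log10(q)` are rounded (half away from zero, to `digits` decimal
#' places, default integer levels) and for each distinct rounded level
#' the number of interactions with equal or higher significance is
#' counted. The finite-difference slope of this cumulative curve is the
#' basis of the local-filter elbow.
#'
#' @param q Numeric vector of q-values in (0, 1]; must be non-empty.
#' @param min_q Floor applied to tiny q-values before the log
#'   (default 1e-300); q <= 0 is an error.
#' @param digits Rounding granularity for the levels (default 0, i.e.
#'   integer levels).
#' @return An object of class `lf_curve`: list with `levels` (distinct
#'   rounded levels, increasing), `cum_counts` (interactions at or above
#'   each level) and `slopes` (finite differences between consecutive
#'   levels; length `length(levels) - 1`, all <= 0).
#' @examples
#' cumulative_significance_curve(c(0.04, 0.04, 0.03, 1e-3, 1e-6))
#' @export
cumulative_significance_curve <- function(q, min_q = 1e-300, digits = 0L) {
  if (length(q) == 0L) cb_stop("bait has no significant interactions")
  if (any(q <= 0)) cb_stop("q-values must be positive")
  if (any(q > 1)) cb_stop("q-values must be <= 1")
  lv <- round_half_away(-log10(pmax(q, min_q)), digits)
  levels <- sort(unique(lv))
  cum_counts <- vapply(levels, function(v) sum(lv >= v), numeric(1))
  slopes <- if (length(levels) > 1L) {
    diff(cum_counts) / diff(levels)
  } else {
    numeric()
  }
  structure(list(levels = levels, cum_counts = cum_counts,
                 slopes = slopes, call_levels = lv),
            class = "lf_curve")
}

#' @export
print.lf_curve <- function(x, ...) {
  cat("<lf_curve>", length(x$call_levels), "calls over",
      length(x$levels), "levels\n")
  print(data.frame(level = x$levels, cum_count = x$cum_counts,
                   slope = c(x$slopes, NA)))
  invisible(x)
}

#' Local-filter threshold from a cumulative significance curve
#'
#' The per-bait threshold is set where the cumulative curve stops being
#' steep. With the default `"last-above"` rule the threshold is the
#' level just above the last segment whose absolute slope strictly
#' exceeds 1; with `"first-at-or-below"` it is the lower level of the
#' first segment whose absolute slope is <= 1. When no segment is steep
#' (including single-level curves) the threshold falls back to the
#' lowest level and every interaction is retained; when every segment is
#' steep both rules give the highest level.
#'
#' @param curve An [cumulative_significance_curve()] result.
#' @param rule Elbow rule, `"last-above"` (default) or
#'   `"first-at-or-below"`.
#' @return The threshold level (on the rounded -log10 q scale).
#' @export
lf_threshold <- function(curve, rule = c("last-above",
                                         "first-at-or-below")) {
  rule <- match.arg(rule)
  stopifnot(inherits(curve, "lf_curve"))
  v <- curve$levels
  s <- abs(curve$slopes)
  if (length(s) == 0L) return(v[1L])
  if (rule == "last-above") {
    steep <- which(s > 1)
    if (length(steep) == 0L) return(v[1L])
    v[max(steep) + 1L]
  } else {
    flat <- which(s <= 1)
    if (length(flat) == 0L) return(v[length(v)])
    v[min(flat)]
  }
}

#' Per-bait local filtering of globally significant interactions
#'
#' For each bait independently, builds the cumulative significance
#' curve of its q-values, derives the elbow threshold via
#' [lf_threshold()], and retains the calls whose rounded -log10(q)
#' level is at or above the threshold. Input calls are expected to be
#' globally significant already; the output is always a subset of the
#' input.
#'
#' @param cs A `call_set` with q-value metric.
#' @param rule Elbow rule passed to [lf_threshold()].
#' @param min_q,digits Passed to [cumulative_significance_curve()].
#' @return List with `calls` (the filtered `call_set`) and `thresholds`
#'   (data.frame `bait_id`, `threshold`, `n_input`, `n_retained`).
#' @export
local_filter <- function(cs, rule = c("last-above", "first-at-or-below"),
                         min_q = 1e-300, digits = 0L) {
  rule <- match.arg(rule)
  stopifnot(inherits(cs, "call_set"))
  if (cs$metric_kind != "qvalue") {
    cb_stop("local filtering is defined only for q-value call sets")
  }
  calls <- cs$calls
  keep <- logical(nrow(calls))
  baits <- sort(unique(calls$bait_id))
  thr <- data.frame(bait_id = baits, threshold = NA_real_,
                    n_input = NA_integer_, n_retained = NA_integer_)
  for (k in seq_along(baits)) {
    idx <- which(calls$bait_id == baits[k])
    curve <- cumulative_significance_curve(calls$metric_value[idx],
                                           min_q = min_q, digits = digits)
    t_k <- lf_threshold(curve, rule)
    keep_k <- curve$call_levels >= t_k
    keep[idx] <- keep_k
    thr$threshold[k] <- t_k
    thr$n_input[k] <- length(idx)
    thr$n_retained[k] <- sum(keep_k)
  }
  list(calls = call_set(calls[keep, , drop = FALSE], cs$metric_kind,
                        cs$tool, cs$replicate),
       thresholds = thr)
}
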