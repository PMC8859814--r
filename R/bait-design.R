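#' Capture bait design rules
#'
#' Constraints a 120-mer capture probe must satisfy: GC content within
#' [gc_min, gc_max], at most `max_consecutive_n` consecutive Ns, and the
#' probe anchored within `max_terminus_distance` bases of a restriction
#' fragment terminus (probes target both fragment ends).
#'
#' @param probe_length Probe length in bases (default 120).
#' @param gc_min,gc_max GC-fraction bounds (defaults 0.25 and 0.65).
#' @param max_terminus_distance Maximum distance in bases between the
#'   probe and the fragment terminus (default 330).
#' @param max_consecutive_n Maximum run of Ns allowed in a probe
#'   (default 2).
#' @return An object of class `bait_design_rules`.
#' @export
bait_design_rules <- function(probe_length = 120L, gc_min = 0.25,
                              gc_max = 0.65, max_terminus_distance = 330L,
                              max_consecutive_n = 2L) {
  if (!(gc_min >= 0 && gc_min < gc_max && gc_max <= 1)) {
    cb_stop("need 0 <= gc_min < gc_max <= 1")
  }
  if (probe_length <= 0L) cb_stop("probe_length must be positive")
  structure(list(probe_length = as.integer(probe_length),
                 gc_min = gc_min, gc_max = gc_max,
                 max_terminus_distance = as.integer(max_terminus_distance),
                 max_consecutive_n = as.integer(max_consecutive_n)),
            class = "bait_design_rules")
}

#' Bait-probe eligibility of a fragment
#'
#' Searches both fragment termini for a probe window satisfying the
#' design rules. A candidate window's start (left end) or end (right
#' end) must lie within `max_terminus_distance` of the respective
#' terminus; among passing windows the one closest to the terminus wins.
#' The fragment is eligible iff at least one end admits a probe.
#' Fragments shorter than the probe are ineligible, not an error.
#'
#' @param seq The fragment's DNA sequence (character, A/C/G/T/N).
#' @param rules A [bait_design_rules()] object.
#' @return List with `eligible` (logical) and `probes`, a data.frame of
#'   chosen windows (columns `side`, `start`, `end`, 1-based within the
#'   fragment; zero rows when ineligible).
#' @export
bait_eligible <- function(seq, rules = bait_design_rules()) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  pl <- rules$probe_length
  empty <- data.frame(side = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (n < pl) return(list(eligible = FALSE, probes = empty))
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (any(!ch %in% c("A", "C", "G", "T", "N"))) {
    cb_stop("sequence contains characters other than A/C/G/T/N")
  }
  gc_cum <- c(0L, cumsum(ch %in% c("G", "C")))
  # positions where a disallowed N-run (length max_consecutive_n + 1)
  # begins; a window fails iff it fully contains one such run
  runlen <- rules$max_consecutive_n + 1L
  is_n <- ch == "N"
  if (n >= runlen) {
    win <- stats::filter(as.integer(is_n), rep(1L, runlen), sides = 1)
    bad_start <- which(!is.na(win) & win == runlen) - runlen + 1L
  } else {
    bad_start <- integer()
  }
  bad_cum <- c(0L, cumsum(tabulate(bad_start, nbins = n)))

  window_ok <- function(a) {
    b <- a + pl - 1L
    gc <- (gc_cum[b + 1L] - gc_cum[a]) / pl
    if (gc < rules$gc_min || gc > rules$gc_max) return(FALSE)
    hi <- b - runlen + 1L
    if (hi >= a && (bad_cum[hi + 1L] - bad_cum[a]) > 0L) return(FALSE)
    TRUE
  }

  probes <- empty
  # left terminus: scan starts outward from the fragment start
  left_starts <- seq_len(min(rules$max_terminus_distance + 1L, n - pl + 1L))
  for (a in left_starts) {
    if (window_ok(a)) {
      probes <- rbind(probes, data.frame(side = "left", start = a,
                                         end = a + pl - 1L))
      break
    }
  }
  # right terminus: scan ends inward from the fragment end
  right_ends <- seq(n, by = -1L,
                    length.out = min(rules$max_terminus_distance + 1L,
                                     n - pl + 1L))
  for (b in right_ends) {
    if (window_ok(b - pl + 1L)) {
      probes <- rbind(probes, data.frame(side = "right", start = b - pl + 1L,
                                         end = b))
      break
    }
  }
  list(eligible = nrow(probes) > 0L, probes = probes)
}
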