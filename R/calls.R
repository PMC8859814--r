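#' Significance metric specification
#'
#' Interaction callers report either a q-value (passes when the value is
#' below the cutoff) or a score (passes when the value is at or above
#' the cutoff). A metric spec pairs the kind with a cutoff.
#'
#' @param kind "qvalue" or "score".
#' @param cutoff Cutoff; q-value cutoffs must lie in (0, 1], score
#'   cutoffs must be >= 0.
#' @return An object of class `metric_spec`.
#' @export
metric_spec <- function(kind = c("qvalue", "score"), cutoff) {
  kind <- match.arg(kind)
  if (kind == "qvalue" && !(cutoff > 0 && cutoff <= 1)) {
    cb_stop("q-value cutoff must lie in (0, 1]")
  }
  if (kind == "score" && cutoff < 0) cb_stop("score cutoff must be >= 0")
  structure(list(kind = kind, cutoff = cutoff), class = "metric_spec")
}

metric_passes <- function(values, spec) {
  if (spec$kind == "qvalue") values < spec$cutoff else values >= spec$cutoff
}

#' Per-replicate interaction call set
#'
#' A call set holds one caller's significant bait/other-end interactions
#' for one replicate, keyed by fragment pair. `class` is "bait-bait"
#' when both ends are baited, "bait-other" otherwise, or NA before
#' [classify_calls()] has run.
#'
#' @param calls data.frame with columns `bait_id`, `oe_id`,
#'   `metric_value` and optionally `class`.
#' @param metric_kind "qvalue" or "score".
#' @param tool,replicate Labels for the caller and replicate.
#' @return An object of class `call_set`.
#' @export
call_set <- function(calls, metric_kind = c("qvalue", "score"),
                     tool = "tool", replicate = "rep1") {
  metric_kind <- match.arg(metric_kind)
  req <- c("bait_id", "oe_id", "metric_value")
  if (!all(req %in% names(calls))) {
    cb_stop("calls needs columns ", paste(req, collapse = ", "))
  }
  if (!"class" %in% names(calls)) {
    calls$class <- rep(NA_character_, nrow(calls))
  }
  calls <- calls[, c(req, "class")]
  calls$bait_id <- as.integer(calls$bait_id)
  calls$oe_id <- as.integer(calls$oe_id)
  if (any(calls$bait_id == calls$oe_id)) {
    cb_stop("self-interaction: bait_id equals oe_id")
  }
  if (metric_kind == "qvalue" &&
      any(calls$metric_value < 0 | calls$metric_value > 1)) {
    cb_stop("q-values must lie in [0, 1]")
  }
  if (anyDuplicated(pair_key(calls$bait_id, calls$oe_id))) {
    cb_stop("duplicate (bait_id, oe_id) pair in call set")
  }
  rownames(calls) <- NULL
  structure(list(calls = calls, metric_kind = metric_kind,
                 tool = tool, replicate = replicate),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat("<call_set>", x$tool, "/", x$replicate, ":", nrow(x$calls),
      "calls,", x$metric_kind, "metric\n")
  invisible(x)
}

#' Read interaction calls from a generic caller-agnostic TSV
#'
#' The generic call table has a header row and eight columns:
#' `bait_chrom`, `bait_start`, `bait_end`, `oe_chrom`, `oe_start`,
#' `oe_end`, `metric_kind`, `metric_value` (1-based inclusive
#' coordinates). Each interval must exactly match a fragment of `map`;
#' the bait interval must be baited. Duplicate pairs are collapsed
#' keeping the most significant value (minimum q-value or maximum
#' score).
#'
#' @param path File path.
#' @param map The backing `fragment_map`.
#' @param baits The `bait_map`.
#' @param tool,replicate Labels recorded on the call set.
#' @return A `call_set` (classes unset; see [classify_calls()]).
#' @export
read_calls <- function(path, map, baits, tool = "tool",
                       replicate = "rep1") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("bait_chrom", "bait_start", "bait_end", "oe_chrom",
           "oe_start", "oe_end", "metric_kind", "metric_value")
  if (!all(req %in% names(df))) {
    cb_stop("call table ", path, " must have header columns ",
            paste(req, collapse = ", "))
  }
  kinds <- unique(df$metric_kind)
  if (length(kinds) != 1L) {
    cb_stop("mixed metric kinds in one call table: ",
            paste(kinds, collapse = ", "))
  }
  fr <- map$fragments
  frag_key <- paste(fr$chrom, fr$start, fr$end)
  bait_idx <- match(paste(df$bait_chrom, df$bait_start, df$bait_end),
                    frag_key)
  oe_idx <- match(paste(df$oe_chrom, df$oe_start, df$oe_end), frag_key)
  bad <- which(is.na(bait_idx) | is.na(oe_idx))
  if (length(bad)) {
    cb_stop("row ", bad[1L], " of ", path,
            ": interval matches no fragment in the map")
  }
  bait_id <- fr$frag_id[bait_idx]
  oe_id <- fr$frag_id[oe_idx]
  not_bait <- which(!bait_id %in% baits$frag_id)
  if (length(not_bait)) {
    cb_stop("row ", not_bait[1L], " of ", path,
            ": bait fragment ", bait_id[not_bait[1L]], " is not baited")
  }
  calls <- data.frame(bait_id = bait_id, oe_id = oe_id,
                      metric_value = df$metric_value)
  calls <- collapse_duplicate_pairs(calls, kinds)
  call_set(calls, kinds, tool, replicate)
}

# keep the most significant record per (bait_id, oe_id)
collapse_duplicate_pairs <- function(calls, metric_kind) {
  key <- pair_key(calls$bait_id, calls$oe_id)
  best <- if (metric_kind == "qvalue") {
    tapply(calls$metric_value, key, min)
  } else {
    tapply(calls$metric_value, key, max)
  }
  first <- !duplicated(key)
  out <- calls[first, , drop = FALSE]
  out$metric_value <- as.numeric(best[key[first]])
  rownames(out) <- NULL
  out
}

#' Write a call set to the generic TSV format
#' @param cs A `call_set`.
#' @param map The backing `fragment_map`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calls <- function(cs, map, path) {
  stopifnot(inherits(cs, "call_set"))
  fr <- map$fragments
  bi <- match(cs$calls$bait_id, fr$frag_id)
  oi <- match(cs$calls$oe_id, fr$frag_id)
  if (anyNA(bi) || anyNA(oi)) cb_stop("call fragment ids not in map")
  out <- data.frame(bait_chrom = fr$chrom[bi], bait_start = fr$start[bi],
                    bait_end = fr$end[bi], oe_chrom = fr$chrom[oi],
                    oe_start = fr$start[oi], oe_end = fr$end[oi],
                    metric_kind = cs$metric_kind,
                    metric_value = cs$calls$metric_value)
  ord <- order(out$bait_chrom, out$bait_start, out$oe_chrom, out$oe_start)
  write_tsv_plain(out[ord, ], path, header = TRUE)
  invisible(path)
}

#' Classify calls as bait-bait or bait-other
#'
#' An interaction is bait-bait when its other end is itself baited;
#' bait-bait pairs are stored unordered (bait_id < oe_id) and mirrored
#' duplicates are collapsed keeping the most significant value, so each
#' captured pair is counted once. Idempotent and order-independent.
#'
#' @param cs A `call_set`.
#' @param baits The `bait_map`.
#' @return The call set with `class` filled.
#' @export
classify_calls <- function(cs, baits) {
  stopifnot(inherits(cs, "call_set"))
  calls <- cs$calls
  bb <- calls$oe_id %in% baits$frag_id
  calls$class <- ifelse(bb, "bait-bait", "bait-other")
  # canonical unordered orientation for bait-bait pairs
  swap <- bb & calls$bait_id > calls$oe_id
  tmp <- calls$bait_id[swap]
  calls$bait_id[swap] <- calls$oe_id[swap]
  calls$oe_id[swap] <- tmp
  calls <- collapse_duplicate_pairs_keep_class(calls, cs$metric_kind)
  call_set(calls, cs$metric_kind, cs$tool, cs$replicate)
}

collapse_duplicate_pairs_keep_class <- function(calls, metric_kind) {
  cls <- calls$class
  out <- collapse_duplicate_pairs(calls[, c("bait_id", "oe_id",
                                            "metric_value")], metric_kind)
  key <- pair_key(calls$bait_id, calls$oe_id)
  out$class <- cls[!duplicated(key)]
  out
}

#' Threshold a call set
#'
#' Retains exactly the calls passing the metric spec (q < cutoff or
#' score >= cutoff). Stricter cutoffs always yield subsets of looser
#' ones.
#'
#' @param cs A `call_set`.
#' @param spec A [metric_spec()]; its kind must match the call set's.
#' @return The filtered `call_set`.
#' @export
apply_threshold <- function(cs, spec) {
  stopifnot(inherits(cs, "call_set"), inherits(spec, "metric_spec"))
  if (cs$metric_kind != spec$kind) {
    cb_stop("metric kind mismatch: call set has ", cs$metric_kind,
            ", spec is ", spec$kind)
  }
  keep <- metric_passes(cs$calls$metric_value, spec)
  call_set(cs$calls[keep, , drop = FALSE], cs$metric_kind,
           cs$tool, cs$replicate)
}

#' Fraction of baits with at least one interaction
#'
#' A bait counts as interacting when it appears as the bait of any call
#' or as the partner of a bait-bait call.
#'
#' @param cs A `call_set`.
#' @param baits The `bait_map`.
#' @return Fraction in [0, 1].
#' @export
fraction_baits_with_interaction <- function(cs, baits) {
  if (nrow(baits) == 0L) cb_stop("empty bait map")
  involved <- union(cs$calls$bait_id,
                    intersect(cs$calls$oe_id, baits$frag_id))
  length(intersect(involved, baits$frag_id)) / nrow(baits)
}

#' Proportion of bait-bait calls in a classified call set
#' @param cs A classified `call_set`.
#' @return Fraction of calls with class "bait-bait".
#' @export
bait_bait_proportion <- function(cs) {
  if (anyNA(cs$calls$class)) cb_stop("call set is not classified")
  if (nrow(cs$calls) == 0L) return(NA_real_)
  mean(cs$calls$class == "bait-bait")
}
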