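#' Replicate support table
#'
#' Overlaps the other ends of each bait across replicates. At `pad = 0`
#' two interactions match iff they share the exact (bait, other-end)
#' fragment pair. At `pad > 0`, the other-end fragments of bait-other
#' calls are extended by `pad` bases on both sides (clipped at the
#' chromosome bounds) and other ends of the same bait whose extended
#' intervals overlap by at least 1 bp are linked; support propagates by
#' single linkage, so an other-end is supported by every replicate that
#' contains a matching other-end in its cluster. Bait identity must
#' match exactly at every pad (baits are fixed by the capture design),
#' and bait-bait pairs, when included, are matched exactly on both ends.
#'
#' @param call_sets List of >= 2 classified `call_set`s from one tool.
#' @param pad Extension in bases per side (0, 2500 and 20000 are the
#'   conventional values).
#' @param map The shared `fragment_map`.
#' @param include_bait_bait Include bait-bait pairs (default TRUE).
#' @return An object of class `support_table`: data.frame with columns
#'   `bait_id`, `oe_id`, `class`, `n_support` and a list column
#'   `replicates`, one row per unique (bait, other-end) pair in the
#'   union across replicates.
#' @export
support_table <- function(call_sets, pad = 0L, map,
                          include_bait_bait = TRUE) {
  if (length(call_sets) < 2L) {
    cb_stop("need at least two replicates")
  }
  tools <- unique(vapply(call_sets, function(x) x$tool, character(1)))
  if (length(tools) != 1L) {
    cb_stop("call sets come from different tools: ",
            paste(tools, collapse = ", "))
  }
  reps <- vapply(call_sets, function(x) x$replicate, character(1))
  if (anyDuplicated(reps)) cb_stop("duplicate replicate labels")
  rows <- do.call(rbind, lapply(call_sets, function(x) {
    if (anyNA(x$calls$class)) cb_stop("call sets must be classified")
    cbind(x$calls[, c("bait_id", "oe_id", "class")],
          replicate = x$replicate)
  }))
  if (!include_bait_bait) rows <- rows[rows$class != "bait-bait", ]
  if (nrow(rows) == 0L) cb_stop("no interactions to overlap")

  # union of unique (bait, oe) pairs; support = replicates in the pair's
  # single-linkage cluster (exact pair identity when pad == 0)
  key <- pair_key(rows$bait_id, rows$oe_id)
  un <- rows[!duplicated(key), c("bait_id", "oe_id", "class")]
  un_key <- key[!duplicated(key)]

  if (pad == 0L) {
    supp <- lapply(split(rows$replicate, key), unique)
    supp <- supp[un_key]
  } else {
    fr <- map$fragments
    cluster <- rep(NA_integer_, nrow(un))
    bo <- un$class == "bait-other"
    sel <- which(bo)
    if (length(sel)) {
      idx <- match(un$oe_id[sel], fr$frag_id)
      lens <- map$chrom_lengths[fr$chrom[idx]]
      # bait identity folded into the seqname: one global reduce() then
      # performs the per-bait single-linkage clustering
      space <- paste(un$bait_id[sel], fr$chrom[idx], sep = "|")
      gr <- GenomicRanges::GRanges(
        space,
        IRanges::IRanges(pmax(1L, fr$start[idx] - pad),
                         pmin(as.integer(lens), fr$end[idx] + pad)))
      red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
      hit <- GenomicRanges::findOverlaps(gr, red, minoverlap = 1L)
      cluster[sel] <- S4Vectors::subjectHits(hit)
    }
    # bait-bait pairs: exact identity, each its own cluster
    bb <- which(!bo)
    cluster[bb] <- max(0L, cluster, na.rm = TRUE) + seq_along(bb)
    # replicate support per cluster via the per-row cluster assignment
    row_cluster <- cluster[match(key, un_key)]
    clus_reps <- lapply(split(rows$replicate, row_cluster), unique)
    supp <- clus_reps[as.character(cluster)]
  }
  un$n_support <- lengths(supp)
  un$replicates <- I(unname(supp))
  rownames(un) <- NULL
  attr(un, "pad") <- pad
  attr(un, "replicate_labels") <- reps
  class(un) <- c("support_table", "data.frame")
  un
}

#' Reproducibility fraction from a support table
#'
#' Fraction of unique (bait, other-end) pairs in the union across
#' replicates that are supported by at least `min_support` replicates.
#' Two denominators are reported: the union of unique pairs (the
#' default, symmetric in the replicates) and the mean over replicates
#' of each replicate's own supported fraction.
#'
#' @param support A [support_table()].
#' @param min_support Minimum number of supporting replicates
#'   (default 2, the "at least two replicates" rule).
#' @return List with `fraction` (union denominator),
#'   `per_replicate_mean`, and `per_bait` (data.frame `bait_id`, `n`,
#'   `n_supported`, `fraction`).
#' @export
reproducibility_fraction <- function(support, min_support = 2L) {
  stopifnot(inherits(support, "support_table"))
  if (nrow(support) == 0L) cb_stop("empty union of interactions")
  ok <- support$n_support >= min_support
  per_bait <- stats::aggregate(
    list(n = rep(1L, nrow(support)), n_supported = as.integer(ok)),
    by = list(bait_id = support$bait_id), FUN = sum)
  per_bait$fraction <- per_bait$n_supported / per_bait$n
  reps <- attr(support, "replicate_labels")
  per_rep <- vapply(reps, function(r) {
    inr <- vapply(support$replicates, function(s) r %in% s, logical(1))
    if (!any(inr)) return(NA_real_)
    mean(ok[inr])
  }, numeric(1))
  list(fraction = mean(ok),
       per_replicate_mean = mean(per_rep, na.rm = TRUE),
       per_bait = per_bait)
}

#' Joint mean-threshold rescue across replicates
#'
#' A pair present in the full (unthresholded) result tables of at least
#' `min_replicates` replicates passes jointly when the mean of its
#' metric over some `min_replicates` of those replicates satisfies the
#' spec - equivalently, when the mean of its `min_replicates` most
#' significant values passes. This reading guarantees that a pair
#' individually significant in `min_replicates` replicates always
#' passes jointly (the mean preserves the bound), while still rescuing
#' pairs that sit just past the cutoff in one replicate. The
#' comparison statistic is the relative increase of the union of
#' individually significant pairs when joint passes are added:
#' `(|joint-pass U indiv-union| - |indiv-union|) / |indiv-union|`,
#' which is always >= 0.
#'
#' @param tables Named list (by replicate) of data.frames with columns
#'   `bait_id`, `oe_id`, `metric_value`, covering all tested pairs.
#' @param spec A [metric_spec()].
#' @param min_replicates Minimum replicates a candidate pair must appear
#'   in (default 2).
#' @return List with `pass` (data.frame of jointly passing pairs with
#'   `mean_metric` and `n_replicates`), `n_joint`, `n_indiv_union`,
#'   `increase`.
#' @export
joint_mean_pass <- function(tables, spec, min_replicates = 2L) {
  stopifnot(inherits(spec, "metric_spec"))
  if (length(tables) < 2L) cb_stop("need at least two replicate tables")
  rows <- do.call(rbind, lapply(tables, function(df) {
    df[, c("bait_id", "oe_id", "metric_value")]
  }))
  key <- pair_key(rows$bait_id, rows$oe_id)
  n_rep <- tapply(rows$metric_value, key, length)
  # mean of the min_replicates most significant values per pair
  best_mean <- function(v) {
    v <- if (spec$kind == "qvalue") sort(v) else sort(v, decreasing = TRUE)
    mean(v[seq_len(min(length(v), min_replicates))])
  }
  mean_v <- tapply(rows$metric_value, key, best_mean)
  first <- !duplicated(key)
  cand <- data.frame(bait_id = rows$bait_id[first],
                     oe_id = rows$oe_id[first],
                     mean_metric = as.numeric(mean_v[key[first]]),
                     n_replicates = as.integer(n_rep[key[first]]))
  cand <- cand[cand$n_replicates >= min_replicates, , drop = FALSE]
  pass <- cand[metric_passes(cand$mean_metric, spec), , drop = FALSE]
  rownames(pass) <- NULL
  indiv <- unique(key[metric_passes(rows$metric_value, spec)])
  pass_key <- pair_key(pass$bait_id, pass$oe_id)
  n_union <- length(union(pass_key, indiv))
  list(pass = pass, n_joint = nrow(pass), n_indiv_union = length(indiv),
       increase = if (length(indiv)) {
         (n_union - length(indiv)) / length(indiv)
       } else {
         NA_real_
       })
}

#' Read a chromatin peak track (BED / narrowPeak)
#'
#' Imports a 0-based half-open BED-family file to 1-based inclusive
#' internal coordinates. For narrowPeak, column 9 is interpreted as
#' -log10(q) (ENCODE convention) and only peaks with q below `q_cutoff`
#' are retained; BED files without a q column are kept in full with a
#' warning.
#'
#' @param path File path.
#' @param format "auto" (by extension), "narrowPeak" or "bed".
#' @param q_cutoff Peak significance cutoff (default 0.05).
#' @param label Feature label attached to all peaks (e.g. "DHS",
#'   "H3K27ac"); defaults to the file name.
#' @return A [GenomicRanges::GRanges] with metadata columns `q` (NA when
#'   absent) and `label`.
#' @export
read_peaks <- function(path, format = c("auto", "narrowPeak", "bed"),
                       q_cutoff = 0.05, label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.narrowPeak$", path, ignore.case = TRUE)) {
      "narrowPeak"
    } else {
      "bed"
    }
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  if (format == "narrowPeak") {
    extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
    gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
    q <- 10^(-gr$qValue)
    S4Vectors::mcols(gr) <- NULL
    gr$q <- q
    gr <- gr[gr$q < q_cutoff]
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    S4Vectors::mcols(gr) <- NULL
    gr$q <- NA_real_
    warning("no q-values in ", basename(path), "; keeping all peaks")
  }
  gr$label <- label
  gr
}

#' Functional overlap of interaction other-ends with peak tracks
#'
#' Computes, per feature label and overall, the proportion of unique
#' non-baited other-end fragments of bait-other calls whose interval,
#' extended by `pad` on both sides and clipped at the chromosome
#' bounds, overlaps at least one peak by >= 1 bp. Bait-bait pairs are
#' excluded: their ends are promoters by design.
#'
#' @param cs A classified `call_set`.
#' @param peaks A `GRanges` with a `label` metadata column (as returned
#'   by [read_peaks()]), or a list of such objects.
#' @param pad Extension in bases per side.
#' @param map The backing `fragment_map`.
#' @return List with `fraction` (overlap with any peak of any feature),
#'   `per_feature` (data.frame `label`, `n_overlap`, `n_total`,
#'   `fraction`) and `n_fragments`.
#' @export
functional_overlap_fraction <- function(cs, peaks, pad = 0L, map) {
  stopifnot(inherits(cs, "call_set"))
  if (nrow(cs$calls) == 0L) cb_stop("empty call set")
  if (anyNA(cs$calls$class)) cb_stop("call set is not classified")
  if (is.list(peaks) && !inherits(peaks, "GRanges")) {
    peaks <- do.call(c, unname(peaks))
  }
  oe <- unique(cs$calls$oe_id[cs$calls$class == "bait-other"])
  if (length(oe) == 0L) cb_stop("no bait-other calls")
  fr <- map$fragments
  idx <- match(oe, fr$frag_id)
  lens <- map$chrom_lengths[fr$chrom[idx]]
  gr <- GenomicRanges::GRanges(
    fr$chrom[idx],
    IRanges::IRanges(pmax(1L, fr$start[idx] - pad),
                     pmin(as.integer(lens), fr$end[idx] + pad)))
  labels <- unique(peaks$label)
  per_feature <- do.call(rbind, lapply(labels, function(lb) {
    hits <- GenomicRanges::countOverlaps(gr, peaks[peaks$label == lb],
                                         minoverlap = 1L) > 0
    data.frame(label = lb, n_overlap = sum(hits), n_total = length(gr),
               fraction = mean(hits))
  }))
  any_hit <- GenomicRanges::countOverlaps(gr, peaks, minoverlap = 1L) > 0
  list(fraction = mean(any_hit), per_feature = per_feature,
       n_fragments = length(gr))
}
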