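#' Restriction fragment map
#'
#' A fragment map is the shared coordinate system for every stage of the
#' toolkit: an ordered set of restriction fragments tiling each chromosome
#' with 1-based inclusive coordinates. Fragments on one chromosome are
#' contiguous (each start is the previous end + 1), the first fragment
#' starts at 1 and the last ends at the chromosome length, and `frag_id`s
#' increase strictly in chromosome-then-coordinate order.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`,
#'   `frag_id` (integer coordinates, 1-based inclusive).
#' @param chrom_lengths Named integer vector of chromosome lengths; if
#'   missing, inferred from the last fragment end per chromosome.
#' @return An object of class `fragment_map` with elements `fragments`
#'   and `chrom_lengths`.
#' @export
fragment_map <- function(fragments, chrom_lengths = NULL) {
  req <- c("chrom", "start", "end", "frag_id")
  if (!all(req %in% names(fragments))) {
    cb_stop("fragments needs columns ", paste(req, collapse = ", "))
  }
  fragments <- fragments[, req]
  if (any(fragments$start != as.integer(fragments$start)) ||
      any(fragments$end != as.integer(fragments$end))) {
    cb_stop("fragment coordinates must be integers")
  }
  fragments$start <- as.integer(fragments$start)
  fragments$end <- as.integer(fragments$end)
  fragments$frag_id <- as.integer(fragments$frag_id)
  fragments$chrom <- as.character(fragments$chrom)
  fragments <- fragments[order(fragments$frag_id), , drop = FALSE]
  rownames(fragments) <- NULL
  if (anyDuplicated(fragments$frag_id)) cb_stop("duplicate frag_id")
  if (any(fragments$start < 1L)) cb_stop("fragment start < 1")
  if (any(fragments$end < fragments$start)) cb_stop("fragment end < start")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(fragments$end, fragments$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  }
  obj <- structure(list(fragments = fragments,
                        chrom_lengths = chrom_lengths),
                   class = "fragment_map")
  validate_fragment_map(obj)
  obj
}

# Contiguity / ordering invariants; error names the first offending gap.
validate_fragment_map <- function(map) {
  fr <- map$fragments
  for (chrom in unique(fr$chrom)) {
    f <- fr[fr$chrom == chrom, , drop = FALSE]
    if (is.unsorted(f$start, strictly = TRUE)) {
      cb_stop("fragments on ", chrom, " not in increasing coordinate order")
    }
    if (f$start[1] != 1L) {
      cb_stop("first fragment on ", chrom, " starts at ", f$start[1],
              ", expected 1")
    }
    if (nrow(f) > 1L) {
      gap <- which(f$start[-1L] != f$end[-nrow(f)] + 1L)
      if (length(gap)) {
        cb_stop("non-contiguous fragments on ", chrom, ": fragment ",
                f$frag_id[gap[1L]], " ends at ", f$end[gap[1L]],
                " but the next starts at ", f$start[gap[1L] + 1L])
      }
    }
    len <- map$chrom_lengths[[chrom]]
    if (!is.null(len) && f$end[nrow(f)] != len) {
      cb_stop("last fragment on ", chrom, " ends at ", f$end[nrow(f)],
              " but chromosome length is ", len)
    }
  }
  invisible(map)
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("<fragment_map>", nrow(x$fragments), "fragments on",
      length(x$chrom_lengths), "chromosome(s)\n")
  invisible(x)
}

#' Digest one sequence in silico
#'
#' Scans every position of `seq` for the enzyme's recognition sequence
#' (overlapping matches included; N never matches) and cuts at
#' recognition start + `cut_offset`, returning the resulting fragments
#' with 1-based inclusive coordinates.
#'
#' @param seq DNA sequence: a character string or [Biostrings::DNAString].
#'   Only A/C/G/T/N are accepted.
#' @param chrom Chromosome name for the output fragments.
#' @param enzyme An [restriction_enzyme()] object.
#' @param first_id frag_id of the first fragment (ids are sequential).
#' @return data.frame with columns `chrom`, `start`, `end`, `frag_id`.
#' @examples
#' digest_sequence("GGGAAGCTTCCCGATCAAA", "chr1", hindiii())
#' @export
digest_sequence <- function(seq, chrom, enzyme, first_id = 1L) {
  if (inherits(seq, "DNAString")) {
    dna <- seq
  } else {
    seq <- toupper(as.character(seq))
    if (!nzchar(seq)) cb_stop("empty sequence")
    if (grepl("[^ACGTN]", seq)) {
      cb_stop("sequence contains characters other than A/C/G/T/N")
    }
    dna <- Biostrings::DNAString(seq)
  }
  L <- length(dna)
  if (L == 0L) cb_stop("empty sequence")
  # matchPattern reports overlapping matches; fixed = TRUE keeps N inert
  m <- Biostrings::matchPattern(enzyme$recognition, dna, fixed = TRUE)
  cuts <- Biostrings::start(m) + enzyme$cut_offset
  cuts <- sort(unique(cuts[cuts > 1L & cuts <= L]))
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, L)
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(ends),
             frag_id = seq_along(starts) + as.integer(first_id) - 1L,
             stringsAsFactors = FALSE)
}

#' Digest a genome in silico
#'
#' Applies [digest_sequence()] to every record of a FASTA file (or an
#' in-memory [Biostrings::DNAStringSet]) and assembles a [fragment_map()]
#' with genome-wide sequential frag_ids in record order.
#'
#' @param fasta Path to a FASTA file, or a `DNAStringSet`.
#' @param enzyme An [restriction_enzyme()] object.
#' @return A `fragment_map`.
#' @export
digest_genome <- function(fasta, enzyme) {
  if (inherits(fasta, "DNAStringSet")) {
    seqs <- fasta
  } else {
    if (!file.exists(fasta)) {
      cb_stop("FASTA not found: ", fasta, class = "chicbench_config_error")
    }
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  }
  if (anyDuplicated(names(seqs))) {
    cb_stop("duplicate chromosome names in FASTA")
  }
  frs <- vector("list", length(seqs))
  nxt <- 1L
  for (k in seq_along(seqs)) {
    frs[[k]] <- digest_sequence(seqs[[k]], names(seqs)[k], enzyme,
                                first_id = nxt)
    nxt <- nxt + nrow(frs[[k]])
  }
  fragment_map(do.call(rbind, frs),
               stats::setNames(Biostrings::width(seqs), names(seqs)))
}

#' Read / write a CHiCAGO-style rmap
#'
#' The rmap is a headerless 4-column TSV (chrom, start, end, frag_id)
#' with 1-based inclusive coordinates. `zero_based = TRUE` imports a
#' 0-based digest profile (mHiC-style) by shifting starts up by one at
#' the boundary; internal coordinates are always 1-based.
#'
#' @param path File path.
#' @param zero_based If TRUE, input starts are 0-based and are converted.
#' @return `read_rmap`: a `fragment_map`; `write_rmap`: the path,
#'   invisibly.
#' @export
read_rmap <- function(path, zero_based = FALSE) {
  df <- read_tsv_plain(path, c("chrom", "start", "end", "frag_id"))
  if (!is.numeric(df$start) || !is.numeric(df$end) ||
      any(df$start != floor(df$start)) || any(df$end != floor(df$end))) {
    cb_stop("rmap coordinates must be integers: ", path)
  }
  if (zero_based) df$start <- df$start + 1L
  fragment_map(df)
}

#' @rdname read_rmap
#' @param map A `fragment_map`.
#' @export
write_rmap <- function(map, path) {
  stopifnot(inherits(map, "fragment_map"))
  write_tsv_plain(map$fragments, path)
  invisible(path)
}

#' Bait map: the captured subset of fragments
#'
#' A bait map designates a subset of fragments as capture baits, with a
#' free-text annotation (gene names) per bait. Every baited frag_id must
#' exist in the backing fragment map with identical coordinates.
#'
#' @param frag_ids Integer vector of baited fragment ids.
#' @param annotations Character vector of per-bait annotations (recycled
#'   if length 1).
#' @param map The backing `fragment_map`.
#' @return An object of class `bait_map`: data.frame with columns
#'   `chrom`, `start`, `end`, `frag_id`, `annotation`.
#' @export
bait_map <- function(frag_ids, annotations = "", map) {
  frag_ids <- as.integer(frag_ids)
  if (anyDuplicated(frag_ids)) cb_stop("duplicate baited frag_id")
  idx <- match(frag_ids, map$fragments$frag_id)
  if (anyNA(idx)) {
    cb_stop("baited frag_id not in fragment map: ",
            paste(frag_ids[is.na(idx)], collapse = ", "))
  }
  out <- map$fragments[idx, , drop = FALSE]
  out$annotation <- rep_len(as.character(annotations), nrow(out))
  out <- out[order(out$frag_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bait_map", "data.frame")
  out
}

#' Read / write a CHiCAGO-style baitmap
#'
#' Headerless 5-column TSV (chrom, start, end, frag_id, annotation),
#' 1-based inclusive. Coordinates are checked against the fragment map
#' row with the same frag_id and a mismatch is an error.
#'
#' @param path File path.
#' @param map The backing `fragment_map`.
#' @return `read_baitmap`: a `bait_map`; `write_baitmap`: the path,
#'   invisibly.
#' @export
read_baitmap <- function(path, map) {
  df <- read_tsv_plain(path, c("chrom", "start", "end", "frag_id",
                               "annotation"),
                       colClasses = c("character", "integer", "integer",
                                      "integer", "character"))
  idx <- match(df$frag_id, map$fragments$frag_id)
  if (anyNA(idx)) {
    cb_stop("baitmap frag_id not in fragment map: ",
            paste(df$frag_id[is.na(idx)], collapse = ", "))
  }
  ref <- map$fragments[idx, ]
  bad <- which(ref$chrom != df$chrom | ref$start != df$start |
                 ref$end != df$end)
  if (length(bad)) {
    cb_stop("baitmap row ", bad[1L], " (frag_id ", df$frag_id[bad[1L]],
            ") has coordinates that do not match the fragment map")
  }
  bait_map(df$frag_id, df$annotation, map)
}

#' @rdname read_baitmap
#' @param baits A `bait_map`.
#' @export
write_baitmap <- function(baits, path) {
  stopifnot(inherits(baits, "bait_map"))
  write_tsv_plain(as.data.frame(baits), path)
  invisible(path)
}
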