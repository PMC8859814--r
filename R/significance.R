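#' Fragment-pair contact counts
#'
#' Read-pair counts per unordered fragment pair, the input to the
#' global-background binomial caller. Pairs are canonicalised to
#' `frag_i < frag_j`; duplicate records are summed; all counts must be
#' positive integers.
#'
#' @param pairs data.frame with columns `frag_i`, `frag_j`, `count`.
#' @return An object of class `contact_counts` (data.frame with
#'   attribute `N`, the total pair count).
#' @export
contact_counts <- function(pairs) {
  req <- c("frag_i", "frag_j", "count")
  if (!all(req %in% names(pairs))) {
    cb_stop("pairs needs columns ", paste(req, collapse = ", "))
  }
  if (nrow(pairs) == 0L) cb_stop("empty contact table")
  if (any(pairs$frag_i == pairs$frag_j)) {
    cb_stop("self-pair in contact table")
  }
  if (any(pairs$count < 1 | pairs$count != floor(pairs$count))) {
    cb_stop("counts must be positive integers")
  }
  i <- pmin(pairs$frag_i, pairs$frag_j)
  j <- pmax(pairs$frag_i, pairs$frag_j)
  agg <- stats::aggregate(list(count = pairs$count),
                          by = list(frag_i = i, frag_j = j), FUN = sum)
  agg <- agg[order(agg$frag_i, agg$frag_j), ]
  rownames(agg) <- NULL
  structure(agg, N = sum(agg$count), class = c("contact_counts",
                                               "data.frame"))
}

#' Read / write a contact-count TSV (frag_i, frag_j, count, with header)
#' @param path File path.
#' @return `read_contacts`: a `contact_counts`; `write_contacts`: the
#'   path, invisibly.
#' @export
read_contacts <- function(path) {
  contact_counts(utils::read.table(path, sep = "\t", header = TRUE))
}

#' @rdname read_contacts
#' @param counts A `contact_counts`.
#' @export
write_contacts <- function(counts, path) {
  write_tsv_plain(as.data.frame(counts), path, header = TRUE)
  invisible(path)
}

#' Fragment visibility from contact counts
#'
#' A fragment's visibility is its total read-end count
#' `c_i = sum_j n_ij`; the relative visibility is `r_i = c_i / (2N)`
#' where `N` is the total pair count, so the `r_i` sum to 1. Visibility
#' is the basis of the random-ligation background correction.
#'
#' @param counts A [contact_counts()] object.
#' @return data.frame with columns `frag_id`, `end_count`, `visibility`,
#'   ordered by `frag_id`.
#' @export
fragment_visibility <- function(counts) {
  stopifnot(inherits(counts, "contact_counts"))
  ids <- sort(unique(c(counts$frag_i, counts$frag_j)))
  ends <- stats::setNames(numeric(length(ids)), ids)
  ti <- tapply(counts$count, counts$frag_i, sum)
  tj <- tapply(counts$count, counts$frag_j, sum)
  ends[names(ti)] <- ends[names(ti)] + ti
  ends[names(tj)] <- ends[names(tj)] + tj
  N <- attr(counts, "N")
  data.frame(frag_id = ids, end_count = as.numeric(ends),
             visibility = as.numeric(ends) / (2 * N))
}

#' Global-background binomial interaction test
#'
#' Random-ligation null model: under random ligation, fragment ends pair
#' proportionally to their visibility, so an unordered pair (i, j) has
#' expected probability `p_ij = 2 r_i r_j` per read pair. Each observed
#' pair is tested with the upper binomial tail
#' `P(X >= n_ij), X ~ Binomial(N, p_ij)` and q-values are obtained by
#' Benjamini-Hochberg over all tested pairs. Pairs with zero counts are
#' never tested. Output rows are sorted by q-value, then p-value, then
#' pair id, so results are deterministic.
#'
#' @param counts A [contact_counts()] object.
#' @return data.frame with columns `frag_i`, `frag_j`, `count`,
#'   `expected_p`, `pvalue`, `qvalue`.
#' @export
binomial_interaction_test <- function(counts) {
  stopifnot(inherits(counts, "contact_counts"))
  vis <- fragment_visibility(counts)
  r <- stats::setNames(vis$visibility, vis$frag_id)
  N <- attr(counts, "N")
  p_exp <- 2 * r[as.character(counts$frag_i)] *
    r[as.character(counts$frag_j)]
  p_exp <- as.numeric(p_exp)
  degenerate <- p_exp >= 1
  if (any(degenerate)) {
    warning("expected probability >= 1 for ", sum(degenerate),
            " pair(s) (degenerate contact table); p-value set to 1")
    p_exp[degenerate] <- 1
  }
  pval <- stats::pbinom(counts$count - 1L, N, p_exp, lower.tail = FALSE)
  pval[degenerate] <- 1
  out <- data.frame(frag_i = counts$frag_i, frag_j = counts$frag_j,
                    count = counts$count, expected_p = p_exp,
                    pvalue = pval, qvalue = bh_adjust(pval))
  out <- out[order(out$qvalue, out$pvalue, out$frag_i, out$frag_j), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validating wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    cb_stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
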