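# Shared fixtures, all built in code.

# 2-chromosome toy map: chr1 = 3 fragments over 300 bp, chr2 = 3 over 450
toy_map <- function() {
  fragment_map(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(1L, 101L, 201L, 1L, 151L, 301L),
    end = c(100L, 200L, 300L, 150L, 300L, 450L),
    frag_id = 1:6))
}

toy_baits <- function(map = toy_map()) bait_map(c(2L, 5L), "g", map)

# random DNA string, seeded by the caller
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent digestion oracle: vectorised position-by-position scan,
# no pattern-matching machinery shared with the implementation
oracle_cut_starts <- function(seq, enzyme) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  pat <- strsplit(enzyme$recognition, "")[[1L]]
  k <- length(pat)
  n <- length(ch)
  if (n < k) return(integer())
  hit <- rep(TRUE, n - k + 1L)
  for (off in seq_len(k)) {
    hit <- hit & ch[seq.int(off, n - k + off)] == pat[off]
  }
  starts <- which(hit) + enzyme$cut_offset
  sort(unique(starts[starts > 1L & starts <= n]))
}

# small end-to-end simulation, cached for the whole test session
.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- simulation_config(
      seed = 11,
      genome = list(n_chroms = 1L, chrom_length = 400000L),
      baits = list(n_baits = 30L),
      loops = list(n_true = 150L, noise_per_replicate = 100L,
                   max_dist = 100000L),
      counts = list(n_pairs = 20000L, n_frags = 80L, n_planted = 5L))
    .fixture_cache$small <- suppressWarnings(simulate_chic(cfg))
  }
  .fixture_cache$small
}

# full-scale study conditions (defaults of simulation_config)
study_sim <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <-
      suppressWarnings(simulate_chic(simulation_config(seed = 7)))
  }
  .fixture_cache$study
}

# random classified call set over a map, for property tests
rand_call_set <- function(map, baits, n, metric_kind = "qvalue",
                          replicate = "rep1", tool = "rand") {
  fr <- map$fragments
  b <- sample(baits$frag_id, n, replace = TRUE)
  oe <- sample(setdiff(fr$frag_id, NULL), n, replace = TRUE)
  ok <- oe != b
  b <- b[ok]; oe <- oe[ok]
  key <- paste(pmin(b, oe), pmax(b, oe))
  keep <- !duplicated(key)
  b <- b[keep]; oe <- oe[keep]
  v <- if (metric_kind == "qvalue") runif(length(b)) else runif(length(b), 0, 30)
  classify_calls(call_set(data.frame(bait_id = b, oe_id = oe,
                                     metric_value = v),
                          metric_kind, tool, replicate), baits)
}
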