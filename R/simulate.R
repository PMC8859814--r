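#' Simulation configuration
#'
#' Defaults describe a small but structurally realistic promoter
#' capture Hi-C study: a 6 Mb four-chromosome genome digested by
#' HindIII (~4 kb fragments), 150 baits drawn from design-eligible
#' fragments, three replicates in which each of 2,000 planted true
#' loops is detected independently with probability 0.6 alongside
#' 2,000 replicate-specific noise calls, a 200,000-pair contact table
#' with log-normal visibility bias and 20 pairs enriched 50-fold, and
#' DHS-like peaks covering 40% of true-loop other-ends over a 5%
#' per-fragment background.
#'
#' @param seed Integer master seed; every simulate_* stage derives its
#'   own stream from it, so all outputs are pure functions of the
#'   configuration.
#' @param genome,baits,loops,counts,peaks Named lists overriding the
#'   defaults printed by `str(simulation_config())`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, genome = list(), baits = list(),
                              loops = list(), counts = list(),
                              peaks = list()) {
  def <- list(
    seed = as.integer(seed),
    genome = list(n_chroms = 4L, chrom_length = 1500000L,
                  enzyme = "HindIII", mean_fragment_length = 4000L),
    baits = list(n_baits = 150L, rules = bait_design_rules()),
    loops = list(n_true = 2000L, detection_prob = 0.6,
                 n_replicates = 3L, noise_per_replicate = 2000L,
                 decay = 1.0, min_dist = 5000L, max_dist = 300000L,
                 q_true_shift = 2, q_true_rate = 0.5,
                 q_noise_min = 0.01, cutoff = 0.05),
    counts = list(n_pairs = 200000L, visibility_sdlog = 0.5,
                  fold = 50, n_planted = 20L, n_frags = 300L),
    peaks = list(p_func = 0.4, background = 0.05, peak_length = 500L,
                 features = "DHS", decoy_frac = 0.2, q_cutoff = 0.05))
  def$genome <- utils::modifyList(def$genome, genome)
  def$baits <- utils::modifyList(def$baits, baits)
  def$loops <- utils::modifyList(def$loops, loops)
  def$counts <- utils::modifyList(def$counts, counts)
  def$peaks <- utils::modifyList(def$peaks, peaks)
  lp <- def$loops
  if (lp$decay <= 0) cb_stop("distance-decay exponent must be positive")
  if (lp$n_replicates < 2L) cb_stop("need at least two replicates")
  if (!(lp$detection_prob >= 0 && lp$detection_prob <= 1)) {
    cb_stop("detection_prob must lie in [0, 1]")
  }
  if (def$counts$fold < 1) cb_stop("enrichment fold must be >= 1")
  structure(def, class = "simulation_config")
}

# mutate one background base inside each accidental recognition match
# until the only matches left are the planted ones
scrub_sites <- function(ch, recognition, keep_starts) {
  len <- nchar(recognition)
  planted <- rep(FALSE, length(ch))
  for (s in keep_starts) planted[s:(s + len - 1L)] <- TRUE
  bases <- c("A", "C", "G", "T")
  for (iter in 1:50) {
    m <- Biostrings::matchPattern(
      recognition, Biostrings::DNAString(paste(ch, collapse = "")))
    acc <- setdiff(Biostrings::start(m), keep_starts)
    if (length(acc) == 0L) return(ch)
    for (s in acc) {
      cand <- (s:(s + len - 1L))[!planted[s:(s + len - 1L)]]
      if (length(cand) == 0L) next
      p <- cand[1L]
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
  }
  cb_stop("failed to scrub accidental recognition sites")
}

#' Simulate a genome with plantable restriction sites
#'
#' Generates uniform-random A/C/G/T chromosomes, plants enzyme
#' recognition sites at geometric-spaced intervals so the mean fragment
#' length matches the target, and removes accidental occurrences of the
#' recognition sequence from the background, so the planted cut list is
#' the complete digestion truth.
#'
#' @param config A [simulation_config()].
#' @return List with `seqs` ([Biostrings::DNAStringSet]), `sites`
#'   (data.frame `chrom`, `site_start`, `cut_pos` of planted sites) and
#'   `enzyme`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$genome
  enz <- get_enzyme(g$enzyme)
  len <- nchar(enz$recognition)
  if (g$chrom_length < len + 2L) {
    cb_stop("chrom_length too small to place one recognition site")
  }
  set.seed(config$seed)
  seqs <- character(g$n_chroms)
  sites <- list()
  for (k in seq_len(g$n_chroms)) {
    L <- g$chrom_length
    # geometric gaps => exponential-like fragment sizes around the mean
    gaps <- stats::rgeom(ceiling(L / max(g$mean_fragment_length, 1)) + 50L,
                         1 / g$mean_fragment_length)
    starts <- cumsum(gaps + len) - len + 1L
    starts <- starts[starts >= 2L & starts + len - 1L <= L - 1L]
    ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (s in starts) {
      ch[s:(s + len - 1L)] <- strsplit(enz$recognition, "")[[1L]]
    }
    ch <- scrub_sites(ch, enz$recognition, starts)
    seqs[k] <- paste(ch, collapse = "")
    sites[[k]] <- data.frame(chrom = paste0("chr", k),
                             site_start = starts,
                             cut_pos = starts + enz$cut_offset)
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- paste0("chr", seq_len(g$n_chroms))
  list(seqs = dna, sites = do.call(rbind, sites), enzyme = enz)
}

#' Simulate a bait map from design-eligible fragments
#'
#' Samples `n_baits` fragments uniformly from those whose sequence
#' passes [bait_eligible()] under the configured design rules.
#' Promoter identity is abstracted away: the downstream metrics depend
#' only on bait / non-bait status.
#'
#' @param map A `fragment_map` (from digesting the simulated genome).
#' @param genome The [simulate_genome()] result (for fragment
#'   sequences).
#' @param config A [simulation_config()].
#' @return A `bait_map`.
#' @export
simulate_baitmap <- function(map, genome, config) {
  stopifnot(inherits(config, "simulation_config"))
  chseq <- stats::setNames(as.character(genome$seqs), names(genome$seqs))
  fr <- map$fragments
  ok <- vapply(seq_len(nrow(fr)), function(i) {
    s <- substring(chseq[[fr$chrom[i]]], fr$start[i], fr$end[i])
    bait_eligible(s, config$baits$rules)$eligible
  }, logical(1))
  eligible <- fr$frag_id[ok]
  if (length(eligible) < config$baits$n_baits) {
    cb_stop("only ", length(eligible),
            " fragments are bait-eligible; need ", config$baits$n_baits)
  }
  set.seed(config$seed + 1L)
  chosen <- sort(sample(eligible, config$baits$n_baits))
  bait_map(chosen, paste0("GENE", chosen), map)
}

# draw (bait, other-end) pairs: bait uniform over baits, other end at a
# signed power-law distance snapped to the containing fragment;
# bait-bait pairs are canonicalised to bait_id < oe_id
sample_loop_pairs <- function(n, map, baits, config, exclude_keys = character()) {
  lp <- config$loops
  fr <- map$fragments
  mids <- (fr$start + fr$end) / 2
  bait_ids <- baits$frag_id
  out <- data.frame(bait_id = integer(), oe_id = integer())
  seen <- exclude_keys
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 100L)
    b <- sample(bait_ids, m, replace = TRUE)
    bi <- match(b, fr$frag_id)
    u <- stats::runif(m)
    a <- lp$decay
    d <- if (abs(a - 1) < 1e-9) {
      exp(log(lp$min_dist) + u * (log(lp$max_dist) - log(lp$min_dist)))
    } else {
      (lp$min_dist^(1 - a) +
         u * (lp$max_dist^(1 - a) - lp$min_dist^(1 - a)))^(1 / (1 - a))
    }
    target <- round(mids[bi] + sample(c(-1, 1), m, replace = TRUE) * d)
    oe <- rep(NA_integer_, m)
    for (chrom in unique(fr$chrom[bi])) {
      sel <- which(fr$chrom[bi] == chrom)
      f <- fr[fr$chrom == chrom, ]
      pos <- findInterval(target[sel], f$start)
      valid <- pos >= 1L & target[sel] >= 1L &
        target[sel] <= map$chrom_lengths[[chrom]]
      oe[sel[valid]] <- f$frag_id[pos[valid]]
    }
    keep <- !is.na(oe) & oe != b
    b <- b[keep]; oe <- oe[keep]
    bb <- oe %in% bait_ids
    lo <- ifelse(bb, pmin(b, oe), b)
    hi <- ifelse(bb, pmax(b, oe), oe)
    key <- pair_key(lo, hi)
    fresh <- !key %in% seen & !duplicated(key)
    out <- rbind(out, data.frame(bait_id = lo[fresh], oe_id = hi[fresh]))
    seen <- c(seen, key[fresh])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate replicate call sets with known ground truth
#'
#' Plants `n_true` unique loops (bait uniform, other end at a signed
#' power-law distance). Each loop enters each replicate independently
#' with probability `detection_prob`, with a q-value drawn from a
#' shifted-exponential tail model (`-log10 q = shift + Exp(rate)`).
#' Noise calls, unique across all replicates and disjoint from the
#' planted loops, get q-values uniform just under the significance
#' cutoff. The functional flag is assigned per unique true-loop
#' other-end fragment with probability `p_func`, so the functional
#' overlap of the true-loop subset follows a single binomial law.
#'
#' @param map A `fragment_map`.
#' @param baits A `bait_map`.
#' @param config A [simulation_config()].
#' @return List with `call_sets` (list of classified `call_set`s, one
#'   per replicate) and `truth` (list `loops`, `noise`,
#'   `functional_frags`).
#' @export
simulate_replicate_callsets <- function(map, baits, config) {
  stopifnot(inherits(config, "simulation_config"))
  lp <- config$loops
  set.seed(config$seed + 2L)
  loops <- sample_loop_pairs(lp$n_true, map, baits, config)
  loops$loop_id <- seq_len(nrow(loops))
  # one functional draw per unique other-end fragment
  oe_frags <- unique(loops$oe_id)
  func_frag <- oe_frags[stats::runif(length(oe_frags)) <
                          config$peaks$p_func]
  loops$functional <- loops$oe_id %in% func_frag
  R <- lp$n_replicates
  present <- matrix(stats::runif(nrow(loops) * R) < lp$detection_prob,
                    nrow = nrow(loops))
  colnames(present) <- paste0("rep", seq_len(R))
  loop_keys <- pair_key(loops$bait_id, loops$oe_id)
  noise <- sample_loop_pairs(R * lp$noise_per_replicate, map, baits,
                             config, exclude_keys = loop_keys)
  noise$replicate <- rep(paste0("rep", seq_len(R)),
                         each = lp$noise_per_replicate)
  call_sets <- vector("list", R)
  for (r in seq_len(R)) {
    tr <- loops[present[, r], c("bait_id", "oe_id"), drop = FALSE]
    tr$metric_value <- 10^-(lp$q_true_shift +
                              stats::rexp(nrow(tr), lp$q_true_rate))
    nz <- noise[noise$replicate == paste0("rep", r),
                c("bait_id", "oe_id"), drop = FALSE]
    nz$metric_value <- stats::runif(nrow(nz), lp$q_noise_min, lp$cutoff)
    cs <- call_set(rbind(tr, nz), "qvalue", tool = "internal",
                   replicate = paste0("rep", r))
    call_sets[[r]] <- classify_calls(cs, baits)
  }
  list(call_sets = call_sets,
       truth = list(loops = cbind(loops, present),
                    noise = noise, functional_frags = func_frag))
}

#' Simulate a contact-count table with planted enrichment
#'
#' Samples `n_pairs` read pairs from the random-ligation null
#' `p_ij = 2 r_i r_j`, with per-fragment relative visibility `r` drawn
#' from a log-normal bias model, then up-weights `n_planted` bait-other
#' pairs by `fold` and renormalises. With `fold = 1` the output is an
#' exact draw from the null. The table covers the first `n_frags`
#' fragments of the map (a contiguous capture window): a desk-scale
#' read budget over a focused region gives per-pair coverage
#' comparable to a real capture experiment, rather than a vanishingly
#' sparse genome-wide table.
#'
#' @param map A `fragment_map`.
#' @param baits A `bait_map`.
#' @param config A [simulation_config()].
#' @return List with `counts` (a [contact_counts()]) and `truth`
#'   (data.frame of planted pairs; zero rows when `fold = 1`).
#' @export
simulate_contact_counts <- function(map, baits, config) {
  stopifnot(inherits(config, "simulation_config"))
  cc <- config$counts
  set.seed(config$seed + 3L)
  ids <- map$fragments$frag_id
  if (!is.null(cc$n_frags) && cc$n_frags < length(ids)) {
    ids <- ids[seq_len(cc$n_frags)]
  }
  nf <- length(ids)
  bias <- stats::rlnorm(nf, 0, cc$visibility_sdlog)
  r <- bias / sum(bias)
  N <- cc$n_pairs
  window_baits <- intersect(baits$frag_id, ids)
  if (cc$fold > 1 && cc$n_planted > 0L && length(window_baits) == 0L) {
    cb_stop("no baited fragment inside the contact window")
  }
  if (cc$fold > 1 && cc$n_planted > 0L) {
    pb <- sample(window_baits, cc$n_planted, replace = TRUE)
    po <- sample(ids, cc$n_planted, replace = TRUE)
    redo <- which(po == pb |
                    duplicated(pair_key(pmin(pb, po), pmax(pb, po))))
    while (length(redo)) {
      po[redo] <- sample(ids, length(redo), replace = TRUE)
      redo <- which(po == pb |
                      duplicated(pair_key(pmin(pb, po), pmax(pb, po))))
    }
    pi_ <- pmin(pb, po); pj <- pmax(pb, po)
    p_pl <- 2 * r[match(pi_, ids)] * r[match(pj, ids)]
    Z <- 1 + (cc$fold - 1) * sum(p_pl)
    n_pl <- stats::rbinom(1L, N, cc$fold * sum(p_pl) / Z)
    pl_draw <- sample(length(p_pl), n_pl, replace = TRUE, prob = p_pl)
    planted_key <- pair_key(pi_, pj)
    truth <- data.frame(frag_i = pi_, frag_j = pj, fold = cc$fold)
  } else {
    n_pl <- 0L
    pl_draw <- integer()
    planted_key <- character()
    truth <- data.frame(frag_i = integer(), frag_j = integer(),
                        fold = numeric())
  }
  n_base <- N - n_pl
  e1 <- sample(ids, n_base, replace = TRUE, prob = r)
  e2 <- sample(ids, n_base, replace = TRUE, prob = r)
  repeat {
    bad <- which(e1 == e2 |
                   pair_key(pmin(e1, e2), pmax(e1, e2)) %in% planted_key)
    if (length(bad) == 0L) break
    e1[bad] <- sample(ids, length(bad), replace = TRUE, prob = r)
    e2[bad] <- sample(ids, length(bad), replace = TRUE, prob = r)
  }
  i <- c(pmin(e1, e2), if (n_pl) truth$frag_i[pl_draw])
  j <- c(pmax(e1, e2), if (n_pl) truth$frag_j[pl_draw])
  o <- order(i, j)
  i <- i[o]; j <- j[o]
  new <- c(TRUE, i[-1L] != i[-length(i)] | j[-1L] != j[-length(j)])
  gid <- cumsum(new)
  cnt <- as.integer(rowsum(rep(1L, length(i)), gid))
  counts <- data.frame(frag_i = i[new], frag_j = j[new], count = cnt)
  list(counts = contact_counts(counts), truth = truth)
}

#' Simulate chromatin peak tracks
#'
#' Places one significant peak inside every functional true-loop
#' other-end fragment, a significant background peak inside each other
#' fragment independently with probability `background`, and a
#' configured fraction of extra decoy peaks with q >= 0.05 to exercise
#' the peak significance filter. `background` is therefore the
#' probability that a non-functional fragment carries a peak, matching
#' the closed-form expected overlap `p_func + (1 - p_func) * background`
#' for the true-loop subset.
#'
#' @param map A `fragment_map`.
#' @param truth The `truth` element of [simulate_replicate_callsets()].
#' @param config A [simulation_config()].
#' @return Named list of [GenomicRanges::GRanges], one per feature
#'   label, with metadata columns `q` and `label`.
#' @export
simulate_peaks <- function(map, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  pk <- config$peaks
  set.seed(config$seed + 4L)
  fr <- map$fragments
  func <- truth$functional_frags
  out <- list()
  for (feature in pk$features) {
    bg_cand <- fr$frag_id[!fr$frag_id %in% func]
    bg <- bg_cand[stats::runif(length(bg_cand)) < pk$background]
    frag_ids <- c(func, bg)
    idx <- match(frag_ids, fr$frag_id)
    flen <- fr$end[idx] - fr$start[idx] + 1L
    plen <- pmin(pk$peak_length, flen)
    if (any(plen < pk$peak_length)) {
      warning(sum(plen < pk$peak_length),
              " peak(s) clipped to fragment length")
    }
    off <- floor(stats::runif(length(idx)) * (flen - plen + 1L))
    start <- fr$start[idx] + as.integer(off)
    gr_sig <- GenomicRanges::GRanges(
      fr$chrom[idx], IRanges::IRanges(start, start + plen - 1L))
    gr_sig$q <- stats::runif(length(gr_sig), 1e-6, pk$q_cutoff * 0.98)
    n_decoy <- round(pk$decoy_frac * length(gr_sig))
    d_idx <- sample(nrow(fr), n_decoy, replace = TRUE)
    d_len <- pmin(pk$peak_length, fr$end[d_idx] - fr$start[d_idx] + 1L)
    d_off <- floor(stats::runif(n_decoy) *
                     (fr$end[d_idx] - fr$start[d_idx] + 1L - d_len + 1L))
    d_start <- fr$start[d_idx] + as.integer(d_off)
    gr_dec <- GenomicRanges::GRanges(
      fr$chrom[d_idx], IRanges::IRanges(d_start, d_start + d_len - 1L))
    # decoys start 5% above the cutoff so text round-trips of -log10(q)
    # cannot leak them past the significance filter
    gr_dec$q <- stats::runif(n_decoy, pk$q_cutoff * 1.05, 0.9)
    gr <- c(gr_sig, gr_dec)
    gr$label <- rep(feature, length(gr))
    out[[feature]] <- sort(gr)
  }
  out
}

#' Run the whole generator
#'
#' Convenience wrapper producing every input the pipeline consumes:
#' genome, fragment map, bait map, replicate call sets, contact counts
#' and peak tracks, all deterministic given the configuration.
#'
#' @param config A [simulation_config()].
#' @return List with elements `genome`, `map`, `baits`, `replicates`,
#'   `contacts`, `peaks`, `config`.
#' @export
simulate_chic <- function(config = simulation_config()) {
  genome <- simulate_genome(config)
  map <- digest_genome(genome$seqs, genome$enzyme)
  baits <- simulate_baitmap(map, genome, config)
  replicates <- simulate_replicate_callsets(map, baits, config)
  contacts <- simulate_contact_counts(map, baits, config)
  peaks <- simulate_peaks(map, replicates$truth, config)
  list(genome = genome, map = map, baits = baits,
       replicates = replicates, contacts = contacts, peaks = peaks,
       config = config)
}

#' Write a simulated bundle to disk
#'
#' Emits genome.fa, map.rmap, map.baitmap, one generic call TSV per
#' replicate, counts.tsv, one narrowPeak file per feature and the
#' ground-truth tables, in the formats the package readers accept.
#'
#' @param sim A [simulate_chic()] result.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome$seqs,
                              file.path(outdir, "genome.fa"))
  write_rmap(sim$map, file.path(outdir, "map.rmap"))
  write_baitmap(sim$baits, file.path(outdir, "map.baitmap"))
  for (cs in sim$replicates$call_sets) {
    write_calls(cs, sim$map,
                file.path(outdir, paste0("calls_", cs$replicate, ".tsv")))
  }
  write_contacts(sim$contacts$counts, file.path(outdir, "counts.tsv"))
  for (feature in names(sim$peaks)) {
    gr <- sim$peaks[[feature]]
    np <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     name = paste0(feature, "_", seq_along(gr)),
                     score = 0L, strand = ".", signalValue = 1,
                     pValue = -1, qValue = -log10(gr$q), peak = -1L)
    write_tsv_plain(np, file.path(outdir, paste0(feature, ".narrowPeak")))
  }
  write_tsv_plain(sim$replicates$truth$loops,
                  file.path(outdir, "ground_truth_loops.tsv"),
                  header = TRUE)
  write_tsv_plain(sim$replicates$truth$noise,
                  file.path(outdir, "ground_truth_noise.tsv"),
                  header = TRUE)
  write_tsv_plain(sim$contacts$truth,
                  file.path(outdir, "ground_truth_planted.tsv"),
                  header = TRUE)
  invisible(outdir)
}

#' Closed-form expected reproducibility of the generator
#'
#' Under the generative model (each true loop in each of R replicates
#' independently with probability d; noise unique to one replicate),
#' a true loop in the union has support >= 2 with probability
#' `(1 - (1-d)^R - R d (1-d)^(R-1)) / (1 - (1-d)^R)`; mixture-weighting
#' with the noise gives the expected union fraction.
#'
#' @param n_replicates,detection_prob Generator parameters R and d.
#' @param n_true,n_noise_total Planted loop count and the total number
#'   of noise calls across replicates.
#' @return Expected reproducibility fraction (union denominator).
#' @export
reproducibility_expectation <- function(n_replicates, detection_prob,
                                        n_true, n_noise_total) {
  R <- n_replicates; d <- detection_prob
  p1 <- 1 - (1 - d)^R
  p2 <- p1 - R * d * (1 - d)^(R - 1)
  (n_true * p2) / (n_true * p1 + n_noise_total)
}

#' Monte-Carlo interval for the generator's reproducibility fraction
#'
#' Simulates the per-loop replicate-presence process `n_sim` times and
#' returns the central `conf` interval of the reproducibility fraction.
#'
#' @inheritParams reproducibility_expectation
#' @param n_sim Number of Monte-Carlo draws (default 2000).
#' @param conf Central interval mass (default 0.99).
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return Length-2 numeric vector (lower, upper).
#' @export
reproducibility_interval <- function(n_replicates, detection_prob,
                                     n_true, n_noise_total,
                                     n_sim = 2000L, conf = 0.99,
                                     seed = 1L) {
  set.seed(seed)
  frac <- vapply(seq_len(n_sim), function(k) {
    x <- stats::rbinom(n_true, n_replicates, detection_prob)
    sum(x >= 2L) / (sum(x >= 1L) + n_noise_total)
  }, numeric(1))
  stats::quantile(frac, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                  names = FALSE)
}
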