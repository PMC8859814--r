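# map with widely spaced fragments for interval arithmetic checks:
# chr1 split at 2000 and 3000 among others
wide_map <- function() {
  fragment_map(data.frame(
    chrom = "chr1",
    start = c(1L, 1001L, 2001L, 3001L, 9001L, 30001L, 60001L),
    end = c(1000L, 2000L, 3000L, 9000L, 30000L, 60000L, 100000L),
    frag_id = 1:7))
}

mk_cs <- function(bait, oes, rep, baits, q = 0.01) {
  classify_calls(call_set(data.frame(bait_id = bait, oe_id = oes,
                                     metric_value = q),
                          "qvalue", tool = "t", replicate = rep), baits)
}

test_that("exact support counts replicates sharing a fragment pair", {
  map <- wide_map()
  baits <- bait_map(1L, "g", map)
  css <- list(mk_cs(1L, c(4L, 5L), "rep1", baits),
              mk_cs(1L, c(4L, 6L), "rep2", baits),
              mk_cs(1L, 7L, "rep3", baits))
  st <- support_table(css, pad = 0L, map = map)
  expect_equal(nrow(st), 4L)       # union {4, 5, 6, 7}
  expect_equal(st$n_support[st$oe_id == 4L], 2L)
  expect_equal(sum(st$n_support >= 2L), 1L)
  rf <- reproducibility_fraction(st)
  expect_equal(rf$fraction, 0.25)
  expect_equal(rf$per_bait$fraction, 0.25)
})

test_that("padding links nearby other-ends across replicates", {
  map <- wide_map()
  baits <- bait_map(1L, "g", map)
  # other ends [1001,2000] and [2001,3000] vs gapped [9001,30000]
  css <- list(mk_cs(1L, 2L, "rep1", baits), mk_cs(1L, 3L, "rep2", baits))
  st0 <- support_table(css, pad = 0L, map = map)
  expect_true(all(st0$n_support == 1L))
  st1 <- support_table(css, pad = 2500L, map = map)
  expect_true(all(st1$n_support == 2L))
  expect_equal(reproducibility_fraction(st1)$fraction, 1)
  # adjacent fragments overlap at any positive pad; distant ones do not
  far <- list(mk_cs(1L, 2L, "rep1", baits), mk_cs(1L, 7L, "rep2", baits))
  expect_true(all(support_table(far, pad = 2500L, map = map)$n_support == 1L))
  # identical replicates are fully supported
  same <- list(mk_cs(1L, c(4L, 5L), "rep1", baits),
               mk_cs(1L, c(4L, 5L), "rep2", baits))
  expect_equal(reproducibility_fraction(
    support_table(same, pad = 0L, map = map))$fraction, 1)
  # fully disjoint replicates have zero reproducibility
  disj <- list(mk_cs(1L, 2L, "rep1", baits), mk_cs(1L, 5L, "rep2", baits))
  expect_equal(reproducibility_fraction(
    support_table(disj, pad = 0L, map = map))$fraction, 0)
})

test_that("support requires matching baits and >= 2 replicates", {
  map <- wide_map()
  baits <- bait_map(c(1L, 2L), "g", map)
  # same other-end region, different baits: never linked
  css <- list(mk_cs(1L, 5L, "rep1", baits), mk_cs(2L, 5L, "rep2", baits))
  st <- support_table(css, pad = 20000L, map = map)
  expect_true(all(st$n_support == 1L))
  expect_error(support_table(css[1], pad = 0L, map = map), "two replicates")
  # replicate order does not matter
  css3 <- list(mk_cs(1L, c(4L, 5L), "rep1", baits),
               mk_cs(1L, c(4L, 6L), "rep2", baits),
               mk_cs(1L, 7L, "rep3", baits))
  a <- support_table(css3, pad = 2500L, map = map)
  b <- support_table(rev(css3), pad = 2500L, map = map)
  ka <- order(a$bait_id, a$oe_id)
  kb <- order(b$bait_id, b$oe_id)
  expect_equal(a$n_support[ka], b$n_support[kb])
})

test_that("joint mean threshold rescues near-threshold pairs", {
  tabs <- list(
    rep1 = data.frame(bait_id = c(1L, 1L, 1L), oe_id = c(4L, 5L, 6L),
                      metric_value = c(0.06, 0.01, 0.5)),
    rep2 = data.frame(bait_id = c(1L, 1L), oe_id = c(4L, 5L),
                      metric_value = c(0.02, 0.02)))
  jm <- joint_mean_pass(tabs, metric_spec("qvalue", 0.05))
  # (1,4): mean(0.06, 0.02) = 0.04 passes though rep1 alone does not
  expect_true("4" %in% as.character(jm$pass$oe_id))
  # (1,5) significant in both -> always jointly passing (mean convexity)
  expect_true("5" %in% as.character(jm$pass$oe_id))
  # (1,6) present in one replicate only -> never a candidate
  expect_false("6" %in% as.character(jm$pass$oe_id))
  expect_gte(jm$increase, 0)
  expect_equal(jm$n_indiv_union, 2L)   # (1,4) via rep2, (1,5)
  expect_equal(jm$increase, 0)         # joint set adds nothing here
  expect_error(joint_mean_pass(tabs[1], metric_spec("qvalue", 0.05)),
               "two replicate")
})

test_that("pairs significant in >= 2 replicates always pass jointly", {
  set.seed(701)
  for (k in 1:20) {
    tabs <- lapply(1:3, function(r) {
      data.frame(bait_id = 1L, oe_id = sample(10:40, 25),
                 metric_value = runif(25))
    })
    names(tabs) <- paste0("rep", 1:3)
    spec <- metric_spec("qvalue", 0.05)
    jm <- joint_mean_pass(tabs, spec)
    expect_gte(jm$increase, 0)
    # oracle: individually significant in >= 2 replicates
    rows <- do.call(rbind, tabs)
    sig <- rows[rows$metric_value < 0.05, ]
    twice <- names(which(table(paste(sig$bait_id, sig$oe_id)) >= 2))
    expect_true(all(twice %in% paste(jm$pass$bait_id, jm$pass$oe_id)))
  }
})

test_that("peak reader applies the q filter and converts coordinates", {
  np <- data.frame(chrom = "chr1", start = c(0L, 500L), end = c(100L, 600L),
                   name = c("p1", "p2"), score = 0L, strand = ".",
                   signal = 1, p = -1, q = -log10(c(0.04, 0.2)), peak = -1L)
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write.table(np, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  pk <- read_peaks(path, label = "DHS")
  expect_equal(length(pk), 1L)                  # q = 0.2 filtered out
  expect_equal(GenomicRanges::start(pk), 1L)    # [0,100) -> [1,100]
  expect_equal(GenomicRanges::end(pk), 100L)
  expect_equal(pk$label, "DHS")
  # BED3 without q: kept in full with a warning
  bed <- data.frame(chrom = "chr1", start = c(0L, 500L), end = c(100L, 600L))
  bpath <- withr::local_tempfile(fileext = ".bed")
  write.table(bed, bpath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_warning(pk2 <- read_peaks(bpath), "keeping all")
  expect_equal(length(pk2), 2L)
  expect_true(all(is.na(pk2$q)))
})

test_that("functional overlap counts unique other-end fragments", {
  map <- wide_map()
  baits <- bait_map(1L, "g", map)
  cs <- mk_cs(1L, c(2L, 3L, 5L, 7L), "rep1", baits)
  # peaks inside fragments 2 and 5 only
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1500L, 10000L),
                                                   c(1600L, 10100L)))
  peaks$q <- 0.01
  peaks$label <- "DHS"
  fo <- functional_overlap_fraction(cs, peaks, pad = 0L, map = map)
  expect_equal(fo$fraction, 0.5)
  expect_equal(fo$n_fragments, 4L)
  expect_equal(fo$per_feature$n_overlap, 2L)
  # no peaks anywhere near -> 0
  far_peaks <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10))
  far_peaks$q <- 0.01
  far_peaks$label <- "DHS"
  expect_equal(suppressWarnings(
    functional_overlap_fraction(cs, far_peaks, 0L, map))$fraction, 0)
  # monotone in pad
  f0 <- functional_overlap_fraction(cs, peaks, 0L, map)$fraction
  f1 <- functional_overlap_fraction(cs, peaks, 2500L, map)$fraction
  f2 <- functional_overlap_fraction(cs, peaks, 20000L, map)$fraction
  expect_lte(f0, f1)
  expect_lte(f1, f2)
  # bait-bait calls are excluded from the denominator
  bb_baits <- bait_map(c(1L, 2L), "g", map)
  cs_bb <- mk_cs(1L, c(2L, 5L), "rep1", bb_baits)
  fo_bb <- functional_overlap_fraction(cs_bb, peaks, 0L, map)
  expect_equal(fo_bb$n_fragments, 1L)   # only fragment 5 is a true other end
})

test_that("reproducibility and overlap are monotone in pad on random data", {
  map <- wide_map()
  baits <- bait_map(c(1L, 3L), "g", map)
  set.seed(702)
  pads <- c(0L, 2500L, 20000L)
  for (k in 1:30) {
    css <- lapply(1:3, function(r) {
      rand_call_set(map, baits, 8, replicate = paste0("rep", r), tool = "t")
    })
    fr <- vapply(pads, function(p) {
      reproducibility_fraction(support_table(css, p, map))$fraction
    }, numeric(1))
    expect_true(all(diff(fr) >= 0))
    peaks <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(sample(90000L, 3), width = 300L))
    peaks$q <- 0.01
    peaks$label <- "DHS"
    ov <- vapply(pads, function(p) {
      functional_overlap_fraction(css[[1]], peaks, p, map)$fraction
    }, numeric(1))
    expect_true(all(diff(ov) >= 0))
  }
})
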