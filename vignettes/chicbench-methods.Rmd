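---
title: "Methods: models, filters and synthetic data in chicbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, filters and synthetic data in chicbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chicbench evaluates Capture Hi-C (CHi-C) interaction callers at
restriction-fragment resolution. A CHi-C experiment enriches ligation
products that involve a predefined set of "bait" fragments (here,
promoters); a caller then decides which bait/other-end fragment pairs
interact more often than a background model predicts. Because different
callers use very different backgrounds, the package scores them on
common, caller-agnostic ground: replicate reproducibility, threshold
behaviour, and overlap of interacting fragments with regulatory
chromatin. Everything runs on synthetic data with known ground truth,
so each metric can be checked against a closed-form expectation.

## Coordinate system and in-silico digestion

All stages share one coordinate system: the restriction fragment map
(rmap), a 1-based inclusive tiling of each chromosome into fragments
between consecutive enzyme cut sites. Inputs in 0-based conventions
(mHiC-style digest profiles, BED) are converted at the boundary and
never afterwards; a single internal convention prevents off-by-one
drift.

`digest_sequence()` scans every position for the recognition sequence
(overlapping matches included, so a new site may begin inside the
previous match) and cuts at recognition start + offset: HindIII
(A^AGCTT) has offset 1, MboI (^GATC) offset 0. `N` never matches a
site: unknown sequence cannot assert one. Both fragments flanking a cut
keep their genomic coordinates; overhang fill-in is not modelled,
matching how digest profiles list genomic fragments.

Bait-probe eligibility follows the capture design constraints: a
120-mer probe with GC in [0.25, 0.65], at most two consecutive Ns, and
anchored within 330 bp of a fragment terminus, with probes sought at
both fragment ends. The design source does not say which window wins
when several near a terminus qualify; we take the window closest to the
terminus, scanning outward, which is deterministic and favours probes
that capture the ligation junction. Fragments shorter than the probe
are ineligible rather than an error - real digests contain tiny
fragments.

## The global-background binomial caller

The package's own caller implements the classic random-ligation
background: if fragment ends ligate at random, the chance that one
sequenced pair joins fragments $i$ and $j$ is

$$p_{ij} = 2\,r_i\,r_j,\qquad r_i = \frac{c_i}{2N},$$

where $c_i$ is fragment $i$'s total read-end count ("visibility"), and
$N$ the total pair count. Each observed pair is scored with the upper
binomial tail $P(X \ge n_{ij})$, $X \sim \mathrm{Binomial}(N, p_{ij})$,
and Benjamini-Hochberg q-values are computed over all tested pairs.
Output order (q, then p, then pair id) is deterministic. The
mixed additive/multiplicative background that some callers use for
bait-bait pairs with a random-ligation control library is out of scope;
bait-bait calls from external callers are consumed, classified and
counted, never re-scored.

One calibration subtlety is worth recording. Only observed pairs
(count >= 1) are tested. Conditioning on being observed inflates the
p-value distribution by $1/(1-e^{-\lambda})$ at per-pair depth
$\lambda$, so at shallow depth ($\lambda \ll 1$) the tested p-values
are *not* super-uniform even though each fixed pair's p-value is. The
calibration analysis therefore runs at deep per-pair coverage (a
100-fragment contact window at $N = 10^5$, $\lambda \approx 20$),
where the conditioning term is negligible; there the one-sided
Kolmogorov-Smirnov check against anti-conservatism passes comfortably.

## Per-bait local filtering (LF)

A global background keeps every non-artefactual contact, which for
deeply sequenced baits means hundreds of calls of modest significance.
The local filter asks, per bait: which calls are more significant than
the bulk of what this bait does? For one bait's globally significant
calls:

1. round $-\log_{10}(q)$ to integer levels (half away from zero;
   granularity configurable via `digits`), flooring q at `min_q`
   (default 1e-300) first so the log is finite;
2. for each distinct level $v_k$ count the calls at or above it,
   $C(v_k)$ - the cumulative significance curve;
3. compute finite-difference slopes
   $s_k = (C(v_{k+1})-C(v_k))/(v_{k+1}-v_k)$;
4. set the bait's threshold where the curve stops being steep, and
   keep the calls whose level is at or above it.

"Stops being steep" admits two readings, both implemented:
`"last-above"` (default) places the threshold just above the *last*
segment with $|s_k| > 1$ strictly; `"first-at-or-below"` places it at
the first segment whose slope magnitude drops to 1 or below. On curves
that are steep throughout both give the top level; when no segment is
steep (including single-level curves) the threshold falls back to the
lowest level and the bait keeps everything - no elbow means no evidence
separating bulk from tail. A worked example: q-values
{0.04, 0.04, 0.03, 1e-3, 1e-6} give levels {1, 2, 3, 6}, cumulative
counts {5, 3, 2, 1}, slopes {-2, -1, -1/3}; only the first slope
exceeds 1 in magnitude, the threshold is 2, and three of five calls
survive. Note $|s| = 1$ exactly does not count as "above 1".

```{r lf-example}
library(chicbench)
cv <- cumulative_significance_curve(c(0.04, 0.04, 0.03, 1e-3, 1e-6))
lf_threshold(cv)               # 2
```

## Downstream metrics

**Reproducibility.** For one tool, the other ends of each bait are
overlapped across replicates. At pad 0 two calls match only if they
share the exact (bait, other-end) fragment pair. At pad 2500 or 20000
the other-end fragments of bait-other calls are extended by the pad on
both sides (clipped at chromosome bounds) and linked when the extended
intervals overlap by at least 1 bp; support propagates by single
linkage within a bait, the simplest order-independent rule
(one-to-one matching would depend on input order). Bait identity must
match exactly at every pad - baits are fixed by the capture design -
and bait-bait pairs are matched exactly on both ends. A pair is
reproducible with support in at least two replicates. Two denominators
are reported, since the choice is not canonical: the union of unique
pairs across replicates (symmetric; the headline number) and the mean
of per-replicate supported fractions. Bait-bait pairs are included by
default (`include_bait_bait = FALSE` to drop them). Reproducibility is
provably non-decreasing in the pad, and the tests assert this as an
invariant on random inputs.

**Joint mean threshold.** Undersampling makes a true loop significant
in one replicate and near-threshold in another. A pair present in the
full result tables of at least two replicates passes jointly when the
mean of its metric over the best two such replicates satisfies the
cutoff. The "best-subset" reading is deliberate: it is the only
reading under which a pair individually significant in two replicates
always passes (the mean preserves the bound), which the naive
mean-over-all-replicates violates whenever a weak third replicate drags
the mean past the cutoff. The reported statistic - relative growth of
the union of significant pairs when joint passes are added - is
consequently never negative.

**Functional overlap.** The proportion of unique non-baited other-end
fragments of bait-other calls whose (optionally padded) interval
overlaps a significant chromatin peak (DHS, H3K27ac, H3K4me1, H3K4me3)
by at least 1 bp. Unique fragments, not call rows, are counted;
bait-bait pairs are excluded because their ends are promoters by
design. Peaks come from BED/narrowPeak files (0-based half-open,
converted on read); narrowPeak column 9 is taken as $-\log_{10}(q)$
per the ENCODE convention and peaks are kept at q < 0.05, while plain
BED tracks lacking q-values are kept whole with a warning.

## The synthetic-data generator

The generator produces every input the pipeline consumes, from genome
to peak tracks, as a pure function of one configuration object and its
seed. Defaults describe the study conditions used throughout the tests
and the acceptance script:

* **Genome**: 4 chromosomes x 1.5 Mb of uniform-random A/C/G/T.
  Recognition sites are planted at geometric-spaced intervals (mean
  4 kb for HindIII-like, 400 bp for MboI-like digests) and accidental
  occurrences of the recognition sequence are scrubbed from the random
  background (one background base per accidental match is mutated until
  none remain), so the planted cut list is the *complete* digestion
  truth and recovery can be asserted exactly.
* **Baits**: 150 fragments sampled uniformly from those passing the
  probe-design rules. Promoter identity is abstracted away - the
  metrics depend only on bait/non-bait status.
* **Loops**: 2,000 unique true loops; bait uniform, other end at a
  signed power-law distance (exponent 1.0 by default, i.e. log-uniform
  between 5 kb and 300 kb; the decay exponent is configurable because
  real decay is assumed but not parameterised by the tools under
  study). Each loop enters each of 3 replicates independently with
  detection probability d = 0.6. True q-values follow a
  shifted-exponential tail, $-\log_{10} q = 2 + \mathrm{Exp}(0.5)$;
  2,000 noise calls per replicate get q uniform in (0.01, 0.05), just
  under the significance cutoff. The bulk-plus-tail mixture is chosen
  so the LF elbow exists; it is a modelling convenience, not a claim
  about real q-value distributions.
* **Noise uniqueness**: noise pairs are sampled without replacement
  jointly across replicates and disjointly from the planted loops, so
  noise contributes exactly zero replicate support. Under this model
  the expected union reproducibility is available in closed form,
  $$\frac{n_{\mathrm{true}}\,[1-(1-d)^R - R d (1-d)^{R-1}]}
         {n_{\mathrm{true}}\,[1-(1-d)^R] + R\,n_{\mathrm{noise}}},$$
  about 0.165 under the defaults, and the measured fraction is checked
  against the central 99% Monte-Carlo interval of this model.
* **Functional flags**: assigned per unique true-loop other-end
  fragment (not per loop) with probability p_func = 0.4, so the
  overlap of the true-loop subset follows a single binomial law. With
  background peak probability b = 0.05 per non-functional fragment the
  expected overlap is p_func + (1-p_func) b = 0.43. `background` is a
  per-fragment probability, not base-pair coverage: a 4 kb fragment
  intersected with uniform bp-coverage-0.05 peaks would overlap far
  more than 5% of the time, and the closed form would not hold.
  Decoy peaks with q >= 0.05 (20% extra by default) exercise the peak
  significance filter without touching the truth.
* **Contacts**: N = 200,000 pairs over a 300-fragment contact window
  with log-normal visibility bias (sdlog 0.5), 20 planted pairs
  enriched 50-fold. The window size makes mean per-pair depth ~4
  reads, comparable to a focused capture region at desk scale; spread
  over the whole map the planted enrichment would sit at depth << 1
  and recovery would hinge on luck rather than signal.

What the generator does *not* emulate: read-level artefacts (mapping,
duplicates, capture efficiency, GC bias), trans-chromosomal loops
(cis-only by default), correlated noise between replicates, and the
distance dependence of real caller backgrounds. Passing tests
therefore demonstrate the correctness of the metrics and filters under
a controlled model, not caller performance on real libraries.

## Problem sizes and numerical choices

The default study - 6 Mb genome, ~1,500 fragments, 150 baits, 3 x
~4,000 calls, 200,000 contact pairs - was chosen so a full end-to-end
run takes seconds to a couple of minutes on one core while keeping
every count large enough for the closed-form checks (n >= 2,000 loops,
~800 unique true other-ends). Ties in BH are handled by
`stats::p.adjust`; rounding of significance levels is half away from
zero (base R's `round()` would round half to even and shift elbow
levels); q = 0 is rejected, tiny q floored at 1e-300 before the log;
duplicate call rows collapse to the most significant value (minimum q
or maximum score), a conservative choice the upstream sources leave
unstated; bait-bait pairs are stored unordered and counted once, since
double-counting would bias the bait-bait proportion.

## Known limitations

* The binomial caller is intentionally minimal: no distance dependence,
  no bait-bait model, no dispersion beyond binomial. It is the
  reference implementation of the random-ligation background, not a
  replacement for production callers.
* The LF elbow rule operates on integer-rounded levels; with very few
  calls per bait the curve has one or two levels and the filter
  degenerates to keeping everything, by design.
* Extended-pad matching uses single linkage, so one promiscuous
  other-end can bridge otherwise separate clusters at 20 kb pads.
* Closed-form reproducibility ignores fragment-collision support among
  noise calls; the generator enforces noise uniqueness so the formula
  is exact for generated data, but real caller noise is not unique.
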