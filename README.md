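# chicbench

Benchmarking toolkit for Capture Hi-C (CHi-C) interaction calling at
restriction-fragment resolution.

Promoter capture Hi-C enriches ligation products involving baited
promoter fragments; several callers (global-background binomial,
distance-aware, local-maxima) then disagree wildly - by orders of
magnitude - on which bait/other-end pairs "interact". This package
provides the common ground needed to compare them:

* **Fragment maps**: in-silico digestion (HindIII, MboI, arbitrary
  enzymes), CHiCAGO-style rmap/baitmap I/O, and capture-probe
  eligibility under the standard design rules (120-mer probes, GC in
  25-65%, <= 2 consecutive Ns, within 330 bp of a fragment terminus).
* **A self-contained binomial caller**: the random-ligation background
  `p_ij = 2 r_i r_j` with visibility `r_i = c_i / 2N`, upper binomial
  tail p-values and Benjamini-Hochberg q-values.
* **Per-bait local filtering (LF)**: round `-log10(q)` of a bait's
  significant calls to integer levels, build the cumulative curve
  `C(v) = #{calls at level >= v}`, and keep the calls beyond the last
  slope of magnitude > 1 - the elbow separating a bait's significance
  bulk from its tail.
* **Caller-agnostic metrics**: replicate reproducibility (exact and
  with 2.5 kb / 20 kb other-end extension), threshold sweeps
  (q < 0.05/0.01/0.001, score >= 5/10/15), joint mean-threshold rescue,
  and functional overlap with DHS/histone-mark peaks.
* **A deterministic synthetic-data generator** producing every input
  with known ground truth, so all of the above can be validated
  against closed-form expectations.

## Worked example

The local filter on one bait with q-values
{0.04, 0.04, 0.03, 1e-3, 1e-6}:

```r
library(chicbench)
cv <- cumulative_significance_curve(c(0.04, 0.04, 0.03, 1e-3, 1e-6))
cv
#> <lf_curve> 5 calls over 4 levels
#>   level cum_count      slope
#> 1     1         5 -2.0000000
#> 2     2         3 -1.0000000
#> 3     3         2 -0.3333333
#> 4     6         1         NA
lf_threshold(cv)
#> [1] 2
```

Only the first slope magnitude exceeds 1, so the threshold lands at
level 2 and the three calls at levels {2, 3, 6} survive (`local_filter()`
applies this per bait across a whole call set).

The binomial caller on a three-fragment toy table:

```r
cc <- contact_counts(data.frame(frag_i = c(1, 1, 2),
                                frag_j = c(2, 3, 3),
                                count  = c(8, 1, 1)))
fragment_visibility(cc)
#>   frag_id end_count visibility
#> 1       1         9       0.45
#> 2       2         9       0.45
#> 3       3         2       0.10
binomial_interaction_test(cc)
#>   frag_i frag_j count expected_p     pvalue     qvalue
#> 1      1      2     8      0.405 0.01339451 0.04018354
#> 2      1      3     1      0.090 0.61058388 0.61058388
#> 3      2      3     1      0.090 0.61058388 0.61058388
```

Pair (1,2) carries 8 of 10 reads against an expected random-ligation
probability of 0.405, giving an upper-tail p-value of 0.013 and, after
BH over three tests, q = 0.040.

## Analysis workflow

The `analysis/` scripts run the full synthetic study end to end
(each accepts an optional `--seed=<int>`, default 1):

```sh
Rscript analysis/01_simulate.R       # generate the study under scratch/sim/
Rscript analysis/02_global_caller.R  # binomial calling + calibration
Rscript analysis/03_local_filter.R   # per-bait elbow thresholds
Rscript analysis/04_benchmark.R      # reproducibility / overlap report
```

Stage 4 writes the report tables (interaction counts per cutoff,
reproducibility per extension pad, DHS-overlap fractions, joint-mean
statistics) under `results/04_report/`. On the default study the raw
caller keeps ~3,200 significant calls per replicate of which local
filtering retains ~13%, exact-fragment reproducibility is ~0.16
(rising to ~0.93 at 20 kb extension), and LF raises the DHS-overlap
fraction from ~0.32 to ~0.40 - the qualitative pattern expected when a
permissive global background is post-filtered per bait.

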