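# dewindow

Moving-window differential expression trajectories for matched
case-control cohorts with randomized follow-up time.

## The problem

In a nested case-control design with banked blood samples, each cancer
case is matched to a healthy control (same birth year, same sampling
batch), and — because sampling dates were randomized independently of
diagnosis — the time elapsed from diagnosis to blood draw is close to
uniform over the follow-up range (here 0–8 years). That makes the
cohort a natural experiment for asking *when*, after diagnosis, the
blood transcriptome of cases differs from controls, and whether those
windows of difference depend on clinical stage and eventual outcome.

`dewindow` implements the full analysis chain for this design, plus a
synthetic-cohort generator that emulates its statistical structure
(registry-linked human expression data of this kind cannot be
deposited, so simulated cohorts are the test bed).

## The method

All testing operates on per-pair differences
`d_gj = log2(case_gj) − log2(control_gj)` for gene *g* and pair *j*,
produced by an Illumina-style preprocessing chain: HLA-probe removal →
normexp background correction fitted by moments from negative-control
probes → `log2(x + c)` transform and quantile normalization → a
detection-based presence filter (detection p < 0.05 in ≥ 70% of
samples) → probe-to-gene averaging.

- **Moving windows.** With pairs sorted by follow-up time
  `t_1 ≤ … ≤ t_T` and window size `S ≈ T/4`, the `T − S + 1` windows
  are `[t_1, t_S], [t_2, t_{S+1}], …`. Each window is tested
  independently and the number of FDR-significant genes (5%) is
  plotted against the window's mean time, smoothed with a width-9 mean
  filter.
- **Moderated paired test.** Per window, a one-sample empirical-Bayes
  moderated t-test: gene variances are shrunk towards a prior
  `(d_0, s_0²)` estimated by digamma/trigamma moment matching,
  `s̃² = (d_0 s_0² + (n−1)s²)/(d_0 + n − 1)`,
  `t = d̄ /(s̃/√n)` with `d_0 + n − 1` degrees of freedom, followed by
  Benjamini–Hochberg adjustment.
- **Stratum comparison.** To compare significant-gene counts between
  strata of unequal size, the smaller stratum's count is referenced
  against a null built by repeatedly subsampling the larger stratum to
  the matched size `m` and re-testing;
  `p = (1 + #{null ≥ reference})/(N + 1)`.
- **Gene ranking and enrichment.** Per gene, `S_i` counts the windows
  where it is significant and `p_i` summarizes its p-values (median
  over significant windows, else minimum over all). The rank value
  `V_i = S_i − k_i p_i` with class-wise `k_i = 0.8 / max_j p_j` orders
  genes exactly lexicographically by (`S_i` desc, `p_i` asc). The
  ranking feeds a permutation-based preranked GSEA (weighted
  Kolmogorov–Smirnov running sum) and hypergeometric overlap tests
  against GMT gene-set collections.

## Worked example

```r
library(dewindow)

cfg <- cohort_config(
  n_pairs = 120,
  signal_specs = list(signal_spec(stage = "all", time_window = c(2, 4),
                                  n_genes = 100, log2_effect = 1)),
  seed = 7)
coh  <- simulate_cohort(cfg)          # pair metadata + probe intensities
pp   <- preprocess_pipeline(coh$expr, coh$pairs)
str(pp$report)
#> $ n_probes_raw           : int 2538
#> $ n_hla_removed          : int 38
#> $ n_probes_after_presence: int 2000
#> $ n_genes                : int 1601
#> $ n_pairs                : int 120

traj <- de_trajectory(pp$diffs, S = "auto")   # S = 30, 91 windows
traj$series[14:18, ]
#>    index mean_time n_sig n_up n_down smoothed_n_sig
#> 14    14      1.43     0    0      0           12.4
#> 15    15      1.48    12   10      2           20.6
#> 16    16      1.53    14   13      1           30.3
#> 17    17      1.58    35   33      2           40.3
#> 18    18      1.63    51   49      2           51.9
```

The count series is flat near zero for windows before the injected
2–4-year signal and rises as windows start overlapping it. Ranking
genes by their window counts:

```r
head(rank_values(per_gene_window_stats(traj$tables)), 3)
#>    gene  S        p     k  V
#> 1 G0129 59 1.77e-11 158.7 59
#> 2 G1135 58 9.69e-13 158.7 58
#> 3 G0803 58 3.54e-10 158.7 58
```

`S` is the number of windows (of 91) in which each gene was
FDR-significant; the top genes are exactly the ones carrying the
injected signal. `plot_trajectory(traj)` draws the count curve with a
marker for every 10th pair along the time axis;
`gsea_preranked()` / `overlap_tests()` take the ranking into gene-set
analysis, and `subsample_null()` + `compare_strata()` test whether one
stratum's count exceeds another's at matched sample size.

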