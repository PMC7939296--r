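---
title: "Methods: moving-window expression trajectories after diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moving-window expression trajectories after diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dewindow)
```

## The design and the statistical model

`dewindow` analyses nested matched case-control cohorts in which every
case has a control matched on birth year and sampling batch, and in
which the *gene expression observation time* — the lag between
diagnosis and blood draw — is randomized by design, approximately
uniform over 0–8 years. Because case and control of a pair travel
together through every laboratory step, technical batch effects cancel
in the per-pair difference, and all inference operates on

\[ d_{gj} = \log_2 x^{case}_{gj} - \log_2 x^{ctrl}_{gj} \]

for gene \(g\) and pair \(j\). Under the null of no disease-associated
expression change at a given follow-up time, \(E[d_{gj}] = 0\).

**Moving windows.** Sorting pairs by observation time
\(t_1 \le \dots \le t_T\) and choosing a window size \(S\), the
\(T-S+1\) windows \([t_j, t_{j+S-1}]\) slide one pair at a time, so
consecutive windows share \(S-1\) pairs. Each window is analysed as an
independent experiment: the moderated paired test is run on its \(S\)
pairs (the variance prior re-fitted inside the window), significant
genes are counted at FDR 5%, and the count is plotted against the
window's mean observation time. The default \(S = \mathrm{round}(T/4)\)
(half-up, minimum 2) trades time resolution against per-window power.

**The moderated paired test.** Per gene, with \(n\) pairs, mean
\(\bar d\) and sample variance \(s^2\), the empirical-Bayes model
treats true variances as draws from a scaled inverse-chi-square prior
with hyperparameters \((d_0, s_0^2)\), estimated by matching the mean
and variance of \(\log s^2\) to digamma/trigamma theory (the trigamma
inversion is a Newton iteration converged to relative 1e-12). The
posterior variance \(\tilde s^2 = (d_0 s_0^2 + (n-1)s^2)/(d_0+n-1)\)
gives \(t = \bar d/(\tilde s/\sqrt n)\) on \(d_0+n-1\) degrees of
freedom. Two degenerate regimes are handled explicitly: \(d_0 = 0\)
reduces to the ordinary one-sample t-test, and when the observed spread
of \(\log s^2\) does not exceed its pure-sampling expectation the prior
is reported as \(d_0 = \infty\) with \(s_0^2\) the mean observed
variance, and p-values come from the normal reference. Tests are
two-sided; direction (up/down) is the sign of \(\bar d\);
Benjamini–Hochberg significance is strict (\(q < 0.05\)).

**Stratum comparison by subsampling.** Significant-gene counts are not
comparable between strata of different size, so the comparison stratum
is repeatedly subsampled without replacement to the matched size
\(m\) (the smaller stratum's size), the merged-period test is re-run on
each draw, and the one-sided empirical p-value
\(p = (1+\#\{\text{null} \ge \text{ref}\})/(N+1)\) carries an add-one
correction so finite replication never yields \(p = 0\). A small p
means the reference stratum produces more significant genes than the
comparison stratum can at the same sample size. The null counts are
exposed so other summaries can be layered on: a subsample of a
low-count stratum can rarely reach a very large reference count, so
this construction saturates at \(1/(N+1)\) and alternative two-way
constructions may be preferable when both counts are large.

**Ranking and enrichment.** For gene \(i\), \(S_i\) counts significant
windows and \(p_i\) is the median p over those windows (minimum over
all windows when \(S_i = 0\)). The rank value \(V_i = S_i - k_i p_i\)
uses \(k_i = 0.8/\max_j p_j\) within each class (\(S>0\) vs \(S=0\)),
which keeps \(k_i p_i \in (0, 0.8]\) and makes the \(V\) ordering
provably identical to the lexicographic ordering by (\(S_i\)
descending, \(p_i\) ascending) — a property the test suite verifies on
randomized instances. Remaining ties are broken by gene symbol for
determinism. The ranking feeds a preranked GSEA (weighted
Kolmogorov–Smirnov running sum, increments \(|V|^w\) with \(w = 1\) by
default; \(w = 0\) is rank-only and invariant to monotone rescaling)
whose null is gene-label permutation with matched set size, and
hypergeometric overlap tests whose universe defaults to the post-filter
gene list — overlap ratios \(k/K\) are universe-free, but p-values do
depend on that choice. Both the heatmap-style "top 50" selection and a
wider selection of all ever-significant genes are supported via the
gene-selection argument, since either convention is defensible.

## What the synthetic generator emulates

The generator reproduces the statistical structure the analysis relies
on, at desk scale:

- **Cohort composition** (defaults): 415 pairs; stage proportions
  51/227/137 (in situ / invasive / metastatic); metastatic substages
  126/2/9; death probabilities 22/227 (invasive) and 39/137
  (metastatic). The in-situ death probability is not available in the
  clinical overview and is set to 0.04, consistent with near-control
  survival for in-situ disease. Tumor sizes are drawn from the six
  clinical categories (0.3–5 cm) with stage-specific weights taken from
  the overview table; the regional-muscle substage has no printed size
  distribution and borrows pooled metastatic weights.
- **Observation times** i.i.d. uniform on 0–8 years. The real design
  produces times in weekly sampling batches, but batch structure is
  irrelevant to the window statistics.
- **Expression**: per-probe log-normal signal (baseline log2 levels
  uniform on 7–12 for expressed genes), per-sample log2 noise of sd
  0.25 (pair differences then have sd \(\approx 0.35\), typical of
  residual variation on whole-blood bead arrays), plus additive
  Gaussian optical background N(100, 10) shared with 100 dedicated
  negative-control probes. 2500 regular probes map onto 2000 genes
  (some genes carry two probes, exercising probe collapsing), 38 extra
  probes are flagged as HLA-system probes, and 20% of genes sit near
  the background so the presence filter is non-trivial. Detection
  p-values follow the bead-array convention: the empirical upper-tail
  probability of the observed intensity under the sample's
  negative-control distribution.
- **Signals**: each `signal_spec` adds a fixed log2 shift to case
  samples of pairs inside one stratum and one time window — the
  "transient increase" structure the windowed analysis is designed to
  detect.

This is a deliberate idealization. It does *not* emulate: bead-level
summarization (so the cited variance-stabilizing transform is
approximated by offset-log2, its large-intensity limit, with offset 16
intensity units), intensity-dependent variance trends, correlated genes
or co-expression modules, questionnaire covariates, or survival times.
Passing tests therefore demonstrate correctness of the procedures under
a clean generative model, not robustness to every artefact of real
array data; with correlated genes, per-window false-positive behaviour
would be burstier than the independent-gene calibration shown here.

## Numerical and design choices

- **Pipeline order** is fixed: HLA removal → background correction →
  transform/quantile normalization → presence filter → collapse →
  differences. Normalization precedes the presence filter (the
  alternative order is defensible; detection calls use raw-scale
  detection p-values either way). After quantile normalization all
  samples share a sorted value vector to 1e-9.
- **Background correction** fits the normexp model by moments (noise
  mean/sd from negative controls, exponential mean from the intensity
  excess, floored at 1) rather than maximum likelihood: closed-form,
  deterministic, and adequate at this scale; the posterior mean is
  evaluated by `limma::normexp.signal` and agrees with direct numeric
  integration of the posterior to 1e-4 relative.
- **Boundaries** mirror the stated inclusive/exclusive conventions:
  detection strictly < 0.05; presence fraction ≥ 0.70 inclusive; QC
  fails at RIN < 7, 260/280 < 2, 260/230 < 1.7, RNA outside the open
  interval (50, 500); year bins are half-open \((k-1, k]\) (ceiling,
  "year after diagnosis" counted from 1, times of exactly 0 assigned to
  year 1); quarter bins likewise; the 18-month late-follow-up
  restriction keeps `time >= 1.5` years inclusive.
- **Window size rounding**: "auto" uses half-up rounding of \(T/4\),
  because banker's rounding would make the window count depend on
  parity; any explicit \(S\) can be passed instead (for a ~30-pair
  stratum, \(S = 8\) and \(S = 9\) bracket the plausible historical
  choices).
- **Small-stratum recovery runs** (the acceptance script's stratified
  trajectory) use an explicit \(S = 5\) rather than auto. With
  \(S \approx T/4\) and a transient spanning a quarter of the follow-up
  range, the expected number of in-signal pairs *equals* the window
  size, so a window fully inside the signal exists only about half the
  time by construction; a ~1-year window restores the resolution needed
  to evaluate full-coverage recovery for ~40-pair strata.
- **Problem sizes**: simulations ship at desk scale — 2538 probes /
  2000 genes rather than 47,285 / 8,400, subsampling nulls of
  \(N = 1000\), permutation GSEA at 1000 permutations — chosen so the
  full suite and the acceptance run complete in minutes while leaving
  every estimator in its asymptotic regime.
- **Degenerate inputs** are handled explicitly and tested: zero-noise
  cohorts propagate to exactly zero differences; zero-variance negative
  controls reduce background correction to subtraction; single-window
  runs reduce to the merged-period analysis; `m =` stratum size makes
  the subsampling null deterministic; empty or undersized gene sets are
  skipped with a warning, and a gene class whose maximum p is zero
  makes the rank-value scale undefined (an error, not a silent NaN).

## Known limitations

Exact published gene counts from the motivating cohort (thousands of
significant genes in specific strata) require the original
registry-linked data and are out of scope; the package reproduces the
printed arithmetic that is checkable (mean tumor sizes, the exclusion
cascade, overlap ratios) and verifies every procedure by construction
on synthetic cohorts. The subsampling comparison's literal one-sided
construction cannot produce intermediate p-values when the reference
count dwarfs the comparison stratum's reach (it saturates at
\(1/(N+1)\)). Under the global null the expected fraction of windows
with zero significant genes is exactly \(1 - \alpha\), so "at least
95% of windows empty" is a borderline statement at \(\alpha = 0.05\);
tests allow Monte-Carlo slack around it. GSEA p-values use plain
permutation rather than the adaptive multilevel splitting of modern
implementations, so their resolution is bounded by \(1/(n_{perm}+1)\).
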