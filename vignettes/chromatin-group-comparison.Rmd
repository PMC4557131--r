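---
title: "Comparing chromatin-state landscapes between groups of epigenomes"
author: "chromCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing chromatin-state landscapes between groups of epigenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromCompare)
```

# The problem

Chromatin-state segmentations (ChromHMM-style annotations assigning every
genomic interval a label such as *Tx*, *Enh*, *ReprPC* or *Quies*) summarize
combinatorial histone-mark patterns per epigenome. Given two groups of
epigenomes — female vs male donors, brain vs gastrointestinal tissue —
the question is which genes carry *systematically different* chromatin
annotation between the groups, after discounting differences explained by
external covariates such as the processing lab.

chromCompare answers this in four steps:

1. **Encoding.** Each epigenome becomes a vector of (gene, state) features:
   the fraction of the gene body `[start, end)` annotated with each state.
   For gene $X$, state $Y$, epigenome $Z$:
   $$\mathrm{feature}_{X,Y}(Z) =
     \frac{\#\{i \in [\mathrm{start}_X, \mathrm{end}_X) : a_i = Y\}}
          {\mathrm{end}_X - \mathrm{start}_X},$$
   where $a_i$ is the state annotated at basepair $i$. Per gene the $S$
   fractions sum to 1 ($S = 15$ for the default palette), so a cohort of
   $E$ epigenomes and $G$ genes yields an $E \times GS$ matrix.
2. **Covariate correction.** Each feature column is refit by binomial
   logistic regression on the covariate design (intercept plus one
   fractional-membership column per category level), *excluding the tested
   property*. The fraction $y$ is treated as $yN$ successes out of
   $N = \mathrm{end}_X - \mathrm{start}_X$ trials. The corrected value is
   the signed deviance residual
   $d_i = \mathrm{sign}(y_i - \hat\pi_i)\sqrt{\mathrm{dev}_i}$: positive
   exactly when the observed coverage exceeds the covariate-predicted
   coverage.
3. **Testing.** Every corrected column is compared between the two groups
   with a two-sided Mann–Whitney–Wilcoxon test (Welch t and variance-ratio
   F are also available), followed by Benjamini–Hochberg correction over
   all tested columns (Bonferroni and Benjamini–Yekutieli are options).
   Features with adjusted $p < 0.05$ are significant; genes owning at
   least one significant feature are the *distinguishing genes*.
4. **Downstream.** Hypergeometric gene-set enrichment with Storey
   q-values, complete-linkage gene clustering with mean-ordered dendrogram
   leaves, dominant-state and expression heatmap matrices, per-gene
   differential expression of distinguishing vs non-distinguishing genes
   with a log odds ratio linking the two classifications, and
   label-shuffling randomization to confirm that shuffled groups yield no
   signal.

# A worked run on synthetic data

```{r example, eval = FALSE}
co <- generateCohort(syntheticCohortSpec(seed = 1L))
fm <- buildFeatureMatrix(co$segmentations, co$genes)
cm <- correctFeatures(fm, co$metadata, testedProperty = "group")
res <- compareGroups(cm, groupSpec(co$metadata, "group", "A", "B"))
res
distinguishingGenes(res)
```

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `backgroundState` | `"Quies"` | state receiving unannotated gene-body bp (counted and warned about, never silently renormalized, because complete segmentations tile the genome) |
| `flankUp`, `flankDown` | 0 bp | widen gene bodies to include proximal regulatory territory; clipped at chromosome ends |
| `covariateProperties` | sex, lab, type, state | the properties encoded into the design; the tested property is always excluded |
| `test` | `"mww"` | rank test: scale-free, so any positive rescaling of corrected values leaves results unchanged |
| `correction`, `alpha` | `"bh"`, 0.05 | FDR control over all tested columns; constant columns stay in $m$ |
| `cap` (`sampleFeatures`) | 10000 | visualization sampling: whole genes in rank order (most significant features first, ties by best adjusted p), the crossing gene truncated by ascending adjusted p so the count is exact |
| `clusterK` | 4 | cluster count at the dendrogram cut; the cut is intrinsically a judgment call, so the dendrogram is exported (Newick) for inspection |
| `nTrials` (`runRandomization`) | 100 | label shuffles per comparison |

# Numerical choices

* **IRLS.** At most 25 iterations, fitted probabilities clipped to
  $[10^{-10}, 1-10^{-10}]$, stopping when the relative deviance change
  falls below $10^{-12}$. The tight tolerance matters because residuals
  are square roots of deviance contributions: stopping at $10^{-8}$ would
  leave residuals of order $10^{-5}$ in perfectly fitted columns, which
  should be exactly zero.
* **Rank-deficient designs.** Complete one-hot level blocks plus an
  intercept are collinear by construction. The design is reduced once to a
  full-rank column basis via pivoted QR before fitting. Fitted values —
  and therefore residuals — are invariant to the parameterization, so this
  equals a minimum-norm solve while being independent of level ordering
  and much cheaper. The inner per-feature normal-equation solves run
  through a small compiled Cholesky kernel.
* **Binomial trial counts.** $N$ is the full gene-body length, exactly as
  defined; long genes therefore get near-deterministic fits and large
  residual magnitudes. The rank test downstream depends only on value
  order, so this scale has no effect on which features are significant.
* **MWW p-values.** Exact enumeration when both groups have at most 8
  values and the column is tie-free; otherwise the normal approximation
  with tie and continuity corrections. At 10 vs 10 the largest achievable
  two-sided level below 0.05 is 0.0433, and columns where a rare state is
  absent from every epigenome are fully tied and return $p = 1$; raw
  p-value histograms on null data are therefore conservative, never
  anti-conservative.
* **Degenerate t-test input.** Two constant groups give $p = 1$ with a
  warning rather than an error.
* **Storey q-values.** $\hat\pi_0$ from the $\lambda$ grid 0.05–0.90
  (step 0.05) with a df-3 smoothing spline evaluated at the grid end,
  clipped to $(0, 1]$; with fewer than 20 p-values the estimate is
  unstable, so $\hat\pi_0 = 1$ (plain BH) is used with a warning.
* **Odds-ratio p-values.** The compact approximation
  $p = e^{-0.717z - 0.416z^2}$ is reported alongside the exact two-sided
  normal p. The approximation tracks the normal tail within 10% for
  $z \lesssim 3$ and drifts upward beyond $z \approx 3.5$ (about +47% at
  $z = 5$) while preserving the order of magnitude; significance calls
  are made from the confidence interval, not from this p.
* **Zero cells.** Haldane–Anscombe +0.5 on all four cells, flagged; two
  zeros in one margin leave the ratio undefined and raise an error.
* **Ties in argmax.** The dominant state of a gene resolves ties toward
  the lowest state index, so exports are deterministic.
* **Expression heatmaps.** Values are $\log_2(\mathrm{RPKM} + 1)$;
  epigenomes lacking expression data appear as all-NA rows to stay
  row-aligned with the chromatin heatmaps.

# Design decisions

* **Randomization and correction.** The covariate design excludes only the
  tested property, and every per-feature fit uses *all* pooled epigenomes;
  neither depends on which epigenome carries which group label. Re-running
  the correction inside each shuffle trial therefore recomputes the same
  matrix, and `runRandomization()` reuses it by default (`recorrect =
  TRUE` re-fits per trial and is verified by a test to give identical
  counts). With the test fixed to MWW, ranks are also shuffle-invariant,
  so trials reduce to re-summing precomputed ranks — 100 trials cost about
  a second on the toy cohort.
* **Assessing correction under confounding.** With 10 + 10 epigenomes and
  a lab/group correlation of 0.6, a lab-biased feature's best achievable
  rank-test p given the 80/20 label mixture is about 0.02, which can never
  survive BH over ~3,000 columns — with or without correction. The
  correction benefit is therefore measured where it acts: among
  non-planted features, corrected runs produce roughly half as many raw
  $p < 0.05$ calls as uncorrected runs, and the paired comparison is what
  the validation suite asserts.
* **Group membership from metadata.** An epigenome annotated with both
  compared traits of a property is ambiguous and excluded from the
  comparison with a warning.

# What the synthetic generator emulates — and what it does not

`generateCohort()` produces segmentations that exactly tile two 2-Mb
chromosomes at 200-bp bins via a renewal process with geometric dwell
lengths (mean 5 bins) over a quiescent-dominated state frequency vector;
200 genes with log-uniform lengths between 2 and 50 kb; metadata with
balanced sex/lab/type/state assignments plus a six-level anatomy column;
and log-normal expression whose mean increases with transcribed-state
(TxFlnk/Tx/TxWk) coverage. Planted genes carry a fixed `sourceEnrichment`
fraction (default 0.7, evenly spread and deterministic, so dominance holds
by construction) of source-state bins in every epigenome, and group-B
epigenomes have the source state rewritten to the target state over the
leading `effectSize` fraction of each planted gene body. `plantConfounder()` re-assigns the lab with a
controlled group correlation and writes a lab-specific annotation bias
into non-planted genes. This scale was chosen so a full pipeline run takes
seconds and a hundred seeded replicates finish in minutes.

Real segmentations differ in ways the generator makes no attempt to copy:
empirical state frequencies and dwell lengths vary along the genome and
between states; gene density, gene length and chromatin structure are
correlated; covariates are unbalanced and partially missing; and group
effects are graded rather than planted switches. Passing the simulation
suite therefore demonstrates the statistical machinery — calibration under
the null, recovery of strong planted effects, confounder removal — not
performance guarantees on any particular real cohort.

# Known limitations

* Hard (maximum-posterior) segmentations only; no posterior-weighted
  coverage, no bigWig/bigBed input, no liftover.
* Strand is ignored throughout — state coverage is strand-agnostic.
* Two-group comparisons only; no paired designs or multi-group omnibus
  tests.
* Features of one gene are dependent (they sum to 1); BH remains valid
  under such positive dependence, and the more conservative
  Benjamini–Yekutieli option is available.
* The gene clustering cut (`clusterK`) is a user decision; clusters
  holding under 5% of clustered elements are labelled but not annotated
  or analysed downstream.
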