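---
title: "Cross-study reproducibility of differential DNA methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study reproducibility of differential DNA methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrepro)
```

# The problem

Array-based cancer methylation studies routinely call differentially
methylated (DM) promoter genes between tumour and normal samples, but two
practical hazards undermine such lists.  First, samples processed in
different experimental batches or collection laboratories carry systematic
non-biological signal; pooling batches confounds the biological contrast
with the technical one and can make apparent "differential methylation"
reflect batch membership.  Second, even clean studies of the same cancer
disagree in which genes clear a significance threshold, so the stability of
a DM list across independent datasets needs to be quantified rather than
assumed.  `methrepro` provides the analysis chain for both problems — batch
diagnosis, DM/DE calling, cross-dataset reproducibility scoring, and
methylation–expression concordance — plus a synthetic-cohort generator that
makes every stage testable against a known truth.

# Models and procedures

## Beta values

Probe methylation is summarised as
$\beta = M/(U + M + 100)$ from the methylated ($M$) and unmethylated ($U$)
intensities.  The +100 stabilising offset keeps $\beta \in [0, 1)$ for all
finite non-negative signals and shrinks noisy low-intensity probes toward
zero; `compute_beta()` applies the formula verbatim and rejects negative or
non-finite signals naming the offending probe and sample.

## Batch-effect assessment

`probe_batch_anova()` fits a one-way ANOVA of each probe's Beta values on
the categorical batch (or laboratory) label and reports the per-probe $F$
statistic, its p value, the Benjamini–Hochberg (BH) adjusted $q$, and the
fraction of probes with $q$ below the chosen level (default FDR < 0.05),
which serves as the dataset's batch-susceptibility summary.  With two
groups, $F = t^2$ for the pooled-variance two-sample $t$; this identity is
used as an independent oracle in the test-suite.  Probes with missing
values or zero total variance are excluded and counted.  The package
deliberately stops at diagnosis: no batch *correction* (ComBat-style
adjustment) is attempted.

`batch_purity_clustering()` complements the per-probe view: samples are
clustered on the Euclidean distance between their Beta profiles
(average linkage by default; configurable) and the tree is cut into as
many clusters as there are batches.  A "perfect split" indicator and the
adjusted Rand index between partition and batch labels quantify how
strongly batch structure dominates the data.

`batch_vs_batch_dm_corruption()` demonstrates the downstream consequence:
DM features are called for two tumour batches against one shared normal
group, and the direction consistency of the features significant in both
comparisons is reported.  When the two tumour batches carry opposing
technical offsets and no true signal, both comparisons still produce long
DM lists — but with contradictory directions, so consistency collapses
(in our synthetic demonstrations from ~100% to near 0%).

## Differential calling

*Methylation.* `dm_ttest()` applies a per-feature two-sided $t$-test —
Welch by default, or the paired $t$ on patient-matched differences when the
design permits (tumour/normal pairs from the same patients are the
motivating design, and pairing is the default in the pipeline).  BH
adjustment runs across all tested features; the effect size is
$\Delta\beta = \bar\beta_{tumour} - \bar\beta_{normal}$, with direction
*hyper* iff $\Delta\beta > 0$.  Features with $\Delta\beta = 0$ exactly get
direction `none` and are excluded from direction-based summaries.  Probe
results are collapsed to genes by a minimum-p representative (ties broken
by larger $|\Delta\beta|$, then probe id); genes whose probes disagree in
direction are flagged `discordant_probes`.  Whether the original analyses
tested probes or pre-collapsed genes is not documented anywhere we could
rely on; min-p collapsing is this package's convention, deterministic and
appropriate for promoter arrays where most genes carry a single probe.

*Expression.* `sam_de()` implements the SAM statistic
$d = (\bar x_1 - \bar x_2)/(s + s_0)$ with the pooled standard error $s$
and a fudge constant $s_0$ chosen by coefficient-of-variation minimisation
over the percentiles of $s$ (falling back to the median of $s$ when the
search degenerates).  Group labels are permuted (all distinct assignments
when enumerable, otherwise a seeded uniform sample; the observed assignment
receives no privileged place in the reference set) to estimate the expected
order statistics $\bar d_{(i)}$ and the false-call count of any cut.  The
symmetric threshold $\Delta$ is the smallest candidate whose estimated FDR
is at or below the requested level; candidates are the observed departures
$|d_{(i)} - \bar d_{(i)}|$, thinned to a 256-point quantile grid when
numerous (a purely numerical economy).  The estimated FDR of a cut is the
**mean**, across permutations, of the number of permuted $d$ values outside
the cut points, divided by the number of observed calls.  The mean is the
original estimator for this statistic; we also expose median and
90th-percentile variants (`fdr_summary=`), but the median collapses to zero
at extreme tails where false-call counts are small integers, which lets a
fully null dataset earn a spurious call in a large fraction of runs — the
mean keeps the procedure calibrated, and our null simulations confirm it.
Each gene's $q$ is the estimated FDR of the symmetric $|d|$ cut placed at
that gene, made monotone in $|d|$.

The DM threshold defaults to FDR < 0.05 and the DE threshold to
FDR < 0.01 (the stricter level used for the headline expression analyses);
both are configurable.  Effect filters (`apply_effect_filters()`) subset
results at $|\Delta\beta| \ge$ a threshold or linear fold change $\ge$ a
threshold ($|\log_2 FC| \ge \log_2 FC_{min}$); both bounds are inclusive.

## Reproducibility scoring

For two significant lists of lengths $L_1$ and $L_2$ sharing $k$ genes,
`pog()` reports the percentage of overlapping genes
$POG_{12} = k/L_1$ and $POG_{21} = k/L_2$ (stored as exact ratios with
counts; percentages are a formatting concern).  `direction_consistency()`
scores the fraction of shared genes with the same direction in both lists
and its significance under an exact one-sided binomial null with success
probability ½ — agreement by coin flip when both directions are equally
likely; the tail is computed exactly via `pbinom` and additionally on the
log10 scale, since perfect agreement of thousands of genes underflows
double precision.  `solely_detected_consistency()` evaluates genes
significant in only one dataset against the *unthresholded* effect sign in
the other; shared-gene consistency, in contrast, uses both lists' assigned
directions.  This asymmetry is deliberate: a gene missed by one dataset's
threshold still has a measured effect there, and its sign is the honest
comparison.  `compare_hyper_proportions()` contrasts the hypermethylated
fraction of two lists by Pearson's chi-squared on the 2×2 table
(continuity correction off by default).

## Concordance with expression

`concordance_analysis()` takes gene-level DM and DE results, forms the
universe $N$ of genes tested on *both* platforms (post-collapse, before any
significance filter — concordance must be judged against what could have
been drawn), and computes, for hypermethylated genes with differential
expression, the fraction down-regulated, with the one-sided upper-tail
hypergeometric p value $P(X \ge x_{down})$ for
$X \sim \mathrm{Hypergeom}(N, n_{down}, k_{hyper,DE})$; symmetric fields
cover hypomethylated/up-regulated genes.  Because the original analyses do
not document their universe, hypergeometric p values are
implementation-defined under this documented choice; the rates themselves
are pure count arithmetic.  `concordance_by_threshold_sweep()` tabulates
reports across a $\Delta\beta \times FC$ grid without any inference across
grid points.  When two methylation datasets are available the pipeline
restricts DM directionality to the reproducible set — genes significant in
both with consistent direction — before the concordance stage.

## Gene-set enrichment

`enrich()` is a plain hypergeometric over-representation test over GMT
collections with BH adjustment across sets.  Topology-aware GO algorithms
(which require the GO graph) are intentionally out of scope; term lists
will therefore differ from analyses that decorrelate the GO hierarchy.
The universe defaults to all genes tested for differential methylation.

# The synthetic-cohort generator

`simulation_config()` fixes the study conditions; the defaults are the
regime the pipeline is validated in: 2000 probes (one probe per gene,
HM27-like; `probes_per_gene > 1` exercises collapsing), two batches of 30
tumour/normal pairs, 10% of probes truly DM (half hyper), a target
$|\Delta\beta|$ of 0.3, logit-scale batch offsets with SD 0.5, within-group
logit noise SD 0.5, methylation–expression coupling
`concordance_hyper = 0.9` and `concordance_hypo = 0.6`, 5% background DE
among non-DM genes, |log2 FC| 2 for true DE genes, and expression noise SD
0.5.  Sample sizes and effect directions mirror the paired tumour/normal,
same-batch design; where the literature gives no generative values (it
analyses real data), the defaults are conventions chosen once to be
realistic for promoter arrays, and the tests treat them as fixed study
conditions.

All systematic effects act on the logit of Beta and are mapped back
through the inverse logit, so Beta stays strictly inside (0, 1) — the
standard device for bounded methylation fractions.  Baseline Beta is drawn
from a two-mode mixture (low mode ≈ 0.1, high mode ≈ 0.8) mimicking
CpG-island bimodality.  `delta_beta_effect` is interpreted on the *Beta*
scale: the applied logit offset is the one that moves the probe's baseline
by ±`delta_beta_effect` (clamped away from the boundaries), because a raw
logit shift of 0.3 would produce a Beta difference of only ~0.07 at
mid-range baselines and would not represent the intended effect size.
True-DM baselines are kept away from the clamp so the intended shift can
land.  Expression coupling draws each true-hyper gene down-regulated with
probability `concordance_hyper` and *up-regulated otherwise* (analogously
for hypo): among truly DE methylation-coupled genes the down fraction then
estimates the configured probability, which is what the recovery analyses
measure.  `beta_to_signals()` inverts the Beta computation to emit (M, U)
signal pairs for exercising the raw-signal path.

What the generator does **not** model: probe cross-hybridisation,
SNP-affected probes, copy-number aberrations, detection-p failures, or
realistic chip noise covariance.  Passing tests therefore demonstrate the
pipeline's statistical correctness under an idealised generative model,
not robustness to every artefact of real arrays.

# Numerical and design choices

- BH adjustment is `stats::p.adjust(method = "BH")` throughout; the tests
  verify it against the step-up definition on random p vectors.
- Degenerate features: identical groups give $p = 1$ (no evidence), zero
  within-group variance with separated means gives $F = \infty, p \to 0$;
  constant probes are skipped and counted.
- Binomial/hypergeometric tails are exact (`pbinom`/`phyper`), verified
  against brute-force enumeration for all small instances
  ($k \le 20$, $N \le 25$).
- Determinism: simulation output is bit-identical given config + seed;
  `sam_de` is deterministic given its seed; the pipeline threads one
  top-level seed through every stochastic stage, and identical
  config + seed reproduce byte-identical summary tables.
- Problem sizes used by the validation suite (chosen to make Monte-Carlo
  behaviour visible at interactive run times): 20 replicates of the
  two-dataset design at 1000 probes × 30 pairs for consistency; 50
  global-null replicates at 150–200 features for FDR calibration; a
  2000-gene cohort for concordance-rate recovery.

# Known limitations

- The hypergeometric concordance p depends on the universe definition;
  only the documented universe (genes tested on both platforms) is
  implemented.
- Laboratory labels are handled as an alternative grouping for the same
  one-way ANOVA; no nested batch-within-laboratory model is fitted.
- The per-cancer aggregation of many batch-pair comparisons seen in
  published box-plot figures is not reproduced; the building block (one
  assessment per label pair) is exposed instead.
- SAM equivalence is to the published definition of the statistic and its
  permutation FDR, not to any specific software release.

# A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
reps <- generate_two_batch_replicates(cfg)
dm1 <- dm_ttest(reps$d1$beta, reps$d1$sheet, paired = TRUE,
                annotation = reps$annotation)
dm2 <- dm_ttest(reps$d2$beta, reps$d2$sheet, paired = TRUE,
                annotation = reps$annotation)
overlap_report(dm1, dm2)

ex <- generate_expression_cohort(cfg, reps$truth)
de <- sam_de(ex$expr, ex$sheet, fdr = 0.01, seed = 1)
de$gene_id <- de$id
concordance_analysis(dm1, de)
```
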