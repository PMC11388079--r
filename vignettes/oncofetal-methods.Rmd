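---
title: "Methods: detecting and scoring the oncofetal state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and scoring the oncofetal state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical procedures
it implements, the assumptions behind them, and the design decisions that
were genuinely open. The README shows the workflow; here we explain why
each step looks the way it does.

## The scientific object

The package targets a single phenomenon: a subpopulation of malignant
liver epithelial cells re-activates a fetal hepatoblast/hepatocyte
expression program. Operationally this resolves into five questions, each
with its own module:

1. do fetal and tumor epithelial profiles co-cluster at the pseudobulk
   level (module discovery)?
2. which genes define that shared program (signature derivation)?
3. which individual cells express it, and how prevalent are they per
   sample (scoring and classification)?
4. are the signature-positive tumor cells genuinely malignant
   (CNV-based calling)?
5. which genes are both associated with the program and required for
   proliferation (regulator prioritization), and does the program carry
   prognostic information (bulk cohort analysis)?

## Preprocessing convention

All expression-based steps run on log counts-per-10K: each cell is scaled
to a library size of 10,000 and transformed with `log1p` (natural log).
No method in the pipeline depends on absolute expression levels — every
statistic is a rank, a contrast, or a correlation — so the specific
library-size target is immaterial; it is fixed once so that thresholds
(e.g. fold changes, clip bounds) have stable units. Cells with zero
counts are kept as all-zero rows rather than dropped: silently removing
them would change the per-sample denominators used for fetal-like
proportions.

## Module discovery

Pseudobulks are arithmetic means of normalized rows per sample × cell
type, with a minimum of 10 cells (below that, a mean profile is mostly
sampling noise). Correlations are Pearson over the 2,000 most variable
genes across pseudobulks — the variable-gene restriction concentrates the
comparison on axes that actually differ between pseudobulks instead of
the grand mean expression profile shared by everything.

Clustering is average linkage on `1 − r`, cut into `n_clusters`
(default 4). The cut size is deliberately exposed: a mixed-cell-type
pseudobulk panel resolves first by cell type, and four clusters is the
natural resolution for a panel with epithelial, endothelial and immune
compartments where the epithelial block then splits into
(fetal + tumor) vs (normal + adjacent). The module is selected
algorithmically rather than by eye: the cluster maximizing
(fraction of fetal members) × 1{cluster contains a tumor pseudobulk},
ties broken toward the larger cluster, then the lowest cluster id. The
tumor gate matters: without it a pure-fetal cluster always wins and the
selection would never certify co-clustering.

## Signature derivation

The program genes are found by a per-gene two-sided Wilcoxon rank-sum
test of module epithelial cells against the remaining epithelial cells,
BH-adjusted. The rank-sum test is the robust default for single-cell
contrasts (no distributional assumption on zero-inflated counts). Genes
qualify with adjusted p ≤ 0.05 and positive log2 fold change computed on
the CP10K scale with a pseudocount of 1:
`log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`. Ranking is by
fold change, not p-value: with hundreds of cells per group essentially
every expressed gene is "significant", and effect size is the quantity
with scientific content. The signature keeps the top 200 by default.

## Cell scoring and the zeroing rule

The raw score is a control-binned module score: all expressed genes are
ranked by mean expression and split into 25 equal-frequency bins; each
signature gene is paired with 50 control genes drawn uniformly from its
bin (without replacement when the bin allows, the gene itself excluded);
the score of a cell is the mean over signature genes of
(gene value − mean control value). Bin-matching removes the baseline
expression component, so a cell scores high only when signature genes are
elevated *relative to expression-matched background*. The sampling
protocol (one `sample()` call per signature gene, in signature order,
from a fixed seed) is documented so scores are exactly reproducible; the
test suite holds the implementation to an independently written naive
version at 1e-10.

The zeroing rule sets a cell's score to zero unless it strictly exceeds
the 95th percentile (linear interpolation between order statistics) of
raw scores among normal reference cells. Strict inequality was chosen so
ties at the threshold are zeroed — with the practical consequence that on
pure-null data at most ~5 % of cells survive, which the calibration test
verifies. Fetal-like status additionally requires the cell to be
epithelial; non-epithelial cells are scored but never classified, since
the biological claim concerns the epithelial compartment.

The differentiation-potential surrogate is deliberately modest: detected
genes per cell, smoothed over the 30 nearest neighbours in the top-2,000
variable-gene space, min-max rescaled. It is a stand-in for
gene-count-based developmental potential estimators, not a
reimplementation of any of them, and is only used to check the *direction*
of the association with the oncofetal score.

## CNV inference and malignancy calling

The profile is the classic expression-smoothing surrogate for copy
number: genes ordered by (chromosome, start), per-gene centring on the
reference (normal epithelial + endothelial cells), clipping at 3
reference SDs (floored at 0.1 to avoid zero-variance blowups), a
101-gene moving average within each chromosome (window shrinking at the
edges; chromosomes smaller than the window are smoothed whole, with a
warning), per-cell median centring, and a final per-gene re-centring so
the reference mean is exactly zero. The per-cell median centring step
exists because library-size and composition effects shift a whole cell's
profile coherently along the genome; without it, that offset masquerades
as a uniform gain or loss and dominates the per-cell score.

The CNV score is the mean |residual| per cell. The literal alternative —
the raw mean of the residuals — is retained as `mode = "raw-mean"`, but
it is nearly constant across cells once profiles are centred, which is
why the deviation-based score is the default.

Malignancy is called per cluster, not per cell: candidate clusters
(those not dominated by reference cells) are compared to the pooled
reference scores with a rank-sum test, BH-adjusted across clusters, and a
call requires BOTH an effect (difference of medians above `min_effect`)
and significance (adjusted p ≤ 0.01). The double gate is deliberate:
cluster sizes in the hundreds make trivially small shifts significant,
and a pure significance rule would call everything.

One known confound is documented rather than hidden: any strong
expression program leaks into an expression-derived CNV score. Fetal
cells carrying the planted program at full strength acquire nonzero
residuals over the program genes and can approach the malignant effect
size, exactly as fetal or highly distinctive cell states confound real
expression-based CNV callers. The malignancy question is therefore posed
the way it is posed clinically — for clusters from tumor and adjacent
samples against the normal reference — and fetal-liver clusters are not
candidates.

## Regulator prioritization

Cell lines are scored by the mean z (across lines) of log2(TPM+1) over
signature genes. The association analysis runs on the liver-lineage
subset of the panel — the lineage in which the dependency question is
meaningful — while lineage specificity of a single gene is computed on
the full pan-cancer panel. A gene passes the filter when its Pearson r
with the line score is at least 0.3 and its mean gene effect is at most
−0.4 (the printed dependency bound; gene-effect convention, lower = more
essential). Because the two criteria live on different scales, the
combined rank is the sum of the two standardized criteria
(z of r plus z of |mean effect|) among passing genes. Genes with no
dependency data anywhere are kept in the table, flagged, and excluded
from ranking rather than silently dropped.

## Bulk cohort analysis

Bulk samples are scored by per-gene z within each dataset, then
concatenated — a deliberate double guard against source batch shifts,
complementing the dataset indicator covariate in the association
regressions. The regressions themselves are ordinary least squares of
score on one clinical parameter at a time plus dataset indicators
(ordinal covariates integer-coded, binary 0/1), with exact t-based 95 %
confidence intervals as `confint()` reports, and BH adjustment across the
requested parameters.

The survival cutpoint re-implements maximally selected rank statistics as
an explicit scan: every distinct score value is a candidate threshold
(strictly-greater defines the high group) subject to both groups holding
at least `min_prop = 0.1` of the cohort; at each candidate the
standardized two-group log-rank statistic is computed from a precomputed
risk-set tabulation (ties handled by the simultaneous-event convention);
the returned cutoff maximizes |z|, ties toward the lower cutoff. The
p-value is a permutation p (default 1,000 permutations of the scores
against the fixed survival data, always reported with the
`(1 + #{exceed}) / (1 + B)` estimator), because the naive log-rank p at a
maximally selected cutoff is badly anti-conservative. The scan +
permutation route was chosen over the asymptotic maximally-selected
approximation because it is transparent, exactly seed-reproducible, and
testable against brute force; the calibration test confirms the
permutation p is uniform under a null cohort. Kaplan–Meier curves and the
log-rank χ² are in-package implementations — the scan needs the statistic
evaluated tens of thousands of times, so it is a vectorized O(n) kernel —
and the test suite pins both to `survival::survdiff`/`survfit` at 1e-10.

## What the synthetic data emulates — and what it does not

The generator is the package's definition of the study conditions, and
its defaults are fixed once:

* **Single-cell cohort** (default ~940 cells × 2,000 genes over two equal
  chromosomes): negative binomial counts (size 2) with log-normal
  per-gene baselines (meanlog −0.5, sdlog 1), log-normal cell size
  factors (sdlog 0.3) and 10 % independent zero-inflation. Planted
  structure: a 150-gene oncofetal program (4-fold) in fetal epithelium
  and in a per-sample fraction of malignant cells (defaults 0.5–0.8
  across the tumor samples); a 150-gene adult maturation program (4-fold)
  in normal/adjacent epithelium and the benign tumor admixture (20 % of
  tumor epithelium) but not in fetal or malignant cells; 100-gene
  identity programs per non-epithelial cell type; and four CNV segments
  (two gains at 2.0 and 1.5, one 0.5 loss, one 1.5 gain; 500 genes
  total) in malignant cells only.

  The adult program deserves a comment, because it is the one structural
  ingredient that a minimal "module + CNV" generator lacks. Without it,
  tumor pseudobulks are statistically a noisy copy of normal pseudobulks
  plus CNV, and no parameter setting makes fetal and tumor co-cluster
  while normals stay outside — the module covariance is diluted by the
  fetal-like fraction while the shared CNV pulls tumors toward each
  other. Real tumors do not behave like perturbed normals: malignant
  dedifferentiation *loses* the adult hepatocyte program that fetal cells
  never had, and that negative tumor–normal covariance is precisely what
  makes the oncofetal module the first within-epithelial split. The
  generator encodes that biology explicitly.

* **Cell-line panel** (60 lines, 500 genes): line scores N(0,1) with the
  liver lineage shifted +1.5; three driver genes whose log2 expression
  tracks the line score (noise SD 0.3) and whose gene effect is
  N(−0.8, 0.1) in lines with score > 0 and N(0, 0.1) otherwise.

* **Bulk cohort** (300 samples in two datasets): true scores N(0,1) plus
  ordinal/binary covariate effects (grade 0.5, stage 0.3, fibrosis 0.4,
  HBV 0.3 per unit); signature-gene expression = score + N(0, 0.5);
  dataset-specific global shifts; exponential survival with log-HR 0.8
  per score SD and independent exponential censoring (rate 0.015/month,
  truncated at 120 months) — exponential hazards keep closed-form sanity
  checks available.

What it does **not** emulate: ambient RNA, doublets, batch effects beyond
additive dataset shifts, realistic gene-gene correlation beyond the
planted programs, lineage trees or subclonal CNV structure, and the
marginal distributions of any real cohort. Passing recovery tests on this
generator certifies the *machinery* — that each estimator finds what was
planted at realistic noise levels — not performance on real data.

## Numerical choices and degenerate inputs

* Percentiles use linear interpolation between order statistics
  (`1 + p(n−1)`), the common continuous-sample definition.
* Zero-variance pseudobulks correlate as 0 (flagged); zero-variance genes
  are excluded from z-scores (warned); genes flat in both DE groups get
  `NA` p-values and cannot qualify.
* Equal-frequency expression bins break ties by first-occurrence rank so
  binning is deterministic.
* Clusters of size 1 are tested with a warning; chromosomes smaller than
  the CNV window are smoothed whole with a warning; `smooth_k` clamps to
  n−1 with a warning.
* The monotonicity of the zeroing rule holds in the survivor-set sense:
  raising the percentile only shrinks the set of nonzero cells (a
  negative raw score that gets zeroed moves *up* to zero, so the naive
  "no score ever increases" phrasing is false for negative scores).
* All generators and every stochastic routine (control-gene draws,
  permutation p) are pure functions of an explicit integer seed.

## Problem sizes

The test-suite and acceptance runs use the default generator sizes
(~940-cell cohorts, 300-sample bulk cohorts, 60-line panels), a reduced
~310-cell × 800-gene cohort for unit fixtures, 10 seeds for recovery
checks, 20 for the DE null, 50 null cohorts × 1,000 permutations for the
cutpoint calibration, and 100 simulations for CI coverage. These sizes
were chosen so each claim is tested at meaningful power while a full run
stays in the minutes range on one core.

## Known limitations

* The signature's DE method, fold-change definition, gene universe for
  correlations and the clustering cut are all pinned choices; upstream
  descriptions of this analysis style leave them open, so other
  reasonable pins exist and would change gene-level details (the module
  membership and recovery behaviour are robust to them in our tests).
* The CNV caller is an expression surrogate: it cannot distinguish a
  strong transcriptional program from a copy-number change on the same
  genes, and it does not call discrete CNV states (no HMM).
* `clinical_association()` fits one covariate at a time (plus dataset);
  it is not a multivariable prognostic model, and the survival analysis
  is KM/log-rank, not Cox regression.
* The cutpoint permutation p is exchangeable-null exact but costs
  B × O(candidates × n); for very large cohorts reduce `n_perm` or
  pre-thin candidates.
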