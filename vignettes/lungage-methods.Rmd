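---
title: "Methods: cell-type-resolved transcriptomic aging analysis"
author: "lungage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-resolved transcriptomic aging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`lungage` implements a donor-level analysis of how aging reshapes the
transcriptome of a complex tissue measured by single-cell RNA-seq. Cells are
pre-annotated with a sample (donor), a cell type, an age group (`YOUNG`,
`MIDDLE`, `AGED`) and a batch/chemistry label. The pipeline then runs five
stages:

1. **QC** — keep cells with more than 200 detected features and a
   mitochondrial fraction below 35% (both inequalities strict).
2. **Pseudobulk differential expression** — sum counts to sample level within
   each cell type and test aged vs young donors per gene with a
   negative-binomial likelihood-ratio test, batch entering as a model
   covariate; BH adjustment within each cell type at FDR < 0.1.
3. **Consensus signatures** — genes up- (down-) regulated in at least two
   cell types form the up (down) aging signature, with upset-style
   intersection accounting.
4. **Module scores** — per-cell mean expression of a gene set minus the mean
   of expression-bin-matched random control genes; applied to the aging
   signatures and to user-supplied senescence sets; groups compared by
   Wilcoxon rank-sum tests.
5. **Age-state classifier** — a random forest on signature-gene expression
   with a stratified 90:10 split, three-times-repeated 10-fold
   cross-validation, AUROC evaluation and Gini variable importance.

A synthetic count generator with planted ground truth accompanies the
pipeline so that every stage can be validated against known effects.

# The pseudobulk model

Single cells from one donor are not independent replicates; testing them as
such badly inflates significance ("pseudo-replication"). Counts are therefore
summed over the cells of each (sample, cell type) stratum, and donors become
the experimental units. For gene $g$ and sample $s$ the model is

$$ y_{gs} \sim \mathrm{NB}(\mu_{gs}, \alpha_g), \qquad
   \log \mu_{gs} = \log c_s + \beta_0 + \beta_{\mathrm{batch}(s)} +
   \beta_{\mathrm{age}} \, [s \in \mathrm{AGED}], $$

with $\mathrm{Var}(y) = \mu + \alpha \mu^2$, size factors $c_s$ by the
median-of-ratios method (median taken on the log scale; a documented
total-count fallback is used when fewer than 10 genes have all-positive
counts, since the gene-wise geometric means are then degenerate). The
likelihood-ratio statistic compares this full model against the reduced model
without the age term, with the dispersion held fixed at the gene's estimate;
$2\Delta\ell$ is referred to $\chi^2_1$ and the reported fold change is
$\beta_{\mathrm{age}} / \ln 2$, unshrunk. Cell types with fewer than 500
cells, or without at least two samples per age group, are excluded as
underpowered; `MIDDLE` donors are excluded before aggregation so the contrast
is strictly young vs aged.

**Batch handling.** Where the original workflow corrected counts with an
external batch-adjustment step before modeling, this package keeps raw counts
and puts batch in the design. The intent is identical — remove chemistry- and
cohort-level mean shifts — but a covariate preserves the count distribution,
makes the adjustment explicit and testable, and lets the synthetic
generator's planted batch shifts verify it directly.

**Dispersion.** Per-gene dispersions come from a method-of-moments estimate
on size-factor-normalized counts, $\hat\alpha = \max(\mathrm{floor},
(s^2 - \bar m)/\bar m^2)$, where $s^2$ is the *pooled within-stratum*
variance over batch-by-age strata. Pooling within strata matters: the raw
across-sample variance absorbs the batch mean shifts that the GLM removes,
which would systematically inflate $\hat\alpha$ and make the test grossly
conservative. Estimates are then shrunk toward their median (weight 0.3,
configurable) and floored at the median. The floor is a deliberate
calibration choice: with around eight residual degrees of freedom the
gene-wise estimate is noisy, and trusting a below-typical value makes the
plug-in LRT anticonservative exactly in the far tail that survives BH; on
planted fixtures the floor brings the pooled empirical FDR from roughly 0.2
down to near the nominal 0.1 while leaving per-gene recall above 0.9. No
mean-dispersion trend or full empirical-Bayes machinery is fitted; at
pseudobulk depths the dispersion is dominated by a common small component and
the median is an adequate anchor.

**Numerical details.** Gene-wise fits use Fisher scoring with step-halving,
converged on both coefficients and log-likelihood; linear predictors are
clamped to $\pm 30$. Fits are unpenalized, so the statistic is exactly the
maximized likelihood ratio (tests compare it to brute-force numerical
maximization at $10^{-4}$ tolerance). Complete separation (a gene observed in
only one age group) or a singular solve triggers a ridge-stabilized refit
(penalty $10^{-6}$) and the gene is flagged. Genes with total pseudobulk
count below 10 get `pvalue = NA` and do not count toward the BH multiplicity.
A design in which age is constant or confounded with batch raises
"contrast not estimable".

# Consensus signatures

For each direction a boolean gene-by-cell-type membership matrix is built
over the significant genes, and genes supported by at least `min_celltypes`
(default 2) cell types enter the signature. Genes qualifying in *both*
directions (up in some cell types, down in others) are removed from both
lists and reported — directional ambiguity must not leak into scores. This
conflict rule is an explicit choice of this package: disjoint published
up/down lists imply directional consistency but do not say how conflicts
were resolved. One consequence worth knowing: the nesting of signatures in
`min_celltypes` holds per direction before conflict removal, but a conflicted
gene can re-enter one list when a higher threshold disqualifies it from the
other. Signature genes are ordered by descending support, then
lexicographically, so outputs are deterministic.

# Module scores

Genes are ranked by dataset-wide mean log-normalized expression and cut into
`n_bins = 24` equal-frequency bins; for each set gene, `n_ctrl_per_gene =
100` control genes are drawn uniformly with replacement from its bin,
excluding all set genes (self-subtraction would bias scores toward zero from
the wrong direction). The score of a cell is the mean expression of the set
genes minus the mean over the pooled control draws. Random sets therefore
center at zero by construction, and adding $\delta$ to every set gene in one
cell moves that cell's score by exactly $\delta$. The bin and control counts
are the conventional defaults of the widely used module-score procedure this
reproduces; the original description names the procedure but not its
parameters, so both are configurable. Ties in the expression ranking and the
order of each control pool are resolved by gene name, which makes scores
invariant to row and column permutations of the input; the control draws are
seeded, so a configuration reproduces scores exactly.

Normalization for scoring is log-CP10K, $\ln(1 + 10^4 \, y_{gc} / N_c)$. The
variance-stabilizing regression used upstream in the original workflow is
intentionally not reimplemented: the DEG test operates on raw pseudobulk
counts, and for scoring, the control-gene subtraction already absorbs
depth-driven effects, so a heavier normalization would add a dependency
without changing what the tests measure.

Group comparisons use the two-sided Wilcoxon rank-sum test: exact enumeration
when both groups have at most 10 observations and no ties, otherwise the
normal approximation with tie and continuity corrections. For group sizes of
five and above the approximation stays within about 0.02 of the exact
p-value; below that it can deviate by up to ~0.03, which is precisely why the
exact path exists. Cells are the default units, matching how such comparisons
are usually displayed; because cells within a donor are correlated, this is
pseudo-replicated, so `compare_groups(..., unit = "sample")` provides a
donor-level variant (mean score per sample) for honest inference.

# The classifier

Signature genes are the features, cells the units, and the age group the
label. Within each (sample, cell type, age group) stratum a seeded 10% of
cells (rounded up) is held out; cell types with fewer than 200 cells are
removed first, and singleton strata go to training with a warning. The
forest uses 500 trees, $\sqrt p$ features per split and no depth limit —
standard defaults; only the seed and tree count are configurable. Training
never pools datasets across chemistries: the pipeline trains within one
batch label (the largest by default), mirroring the per-dataset design the
method prescribes, and cross-batch pooling measurably degrades held-out
AUROC on the synthetic fixture. Repeated stratified cross-validation
(3 times 10-fold by default) reports mean and sd of the AUROC; AUROC itself
is the rank statistic with midranks for ties, verified in tests against the
brute-force pairwise definition. Because cell-level splits leak donor
identity (cells of one donor appear on both sides), a fully honest
alternative is to hold out whole samples; with only 12 synthetic donors the
default remains the cell-level split, and the leakage caveat applies to any
interpretation of its AUROC as donor-level generalization.

# The synthetic generator

`generate_dataset()` emulates the data structure the analysis assumes:
multiple donors in two age groups across two batches; five cell types with
40:25:15:12:8 abundance (defaults 275:172:103:82:55 mean cells per donor, so
even the rarest type clears the 500-cell rule with Poisson margin);
negative-binomial counts with per-gene dispersion drawn from a gamma law
(mean 0.5); log-normal per-cell size factors (sd 0.3); gene-by-batch mean
shifts (sd 0.2 on the log2 scale); 60 up- and 30 down-planted aging genes at
$|\log_2 \mathrm{FC}| = 1$ whose cross-cell-type sharing follows a
configurable profile (by default about half the planted genes affect two or
more of the five cell types); and a 20-gene senescence set up-shifted by one
log2 unit in aged cells of three immune/progenitor-like target cell types.
Planted and senescence genes are drawn from the expressed stratum (baseline
natural-log mean at least −2) so the planted truth is identifiable at desk
scale. The mitochondrial fraction is drawn from a Beta(2, 18) law
independently of the counts — it exists to exercise the QC filter, not to
model mitochondrial biology. All stages derive their seeds from one global
seed via named substreams, so a configuration reproduces the dataset
byte-for-byte.

The magnitude of real aging effects is not quantified in the source
material, so the planted log2 fold change of 1 is a testability choice, not
a biological estimate. The generator also deliberately omits doublets, empty
droplets, ambient RNA, UMI saturation and continuous age; passing tests
demonstrate that the pipeline recovers the effects it models — planted mean
shifts under NB noise, batch offsets, unequal abundances — and say nothing
about artifacts outside that model.

# Validation summary

The test suite validates each stage against independent oracles on fixed
problem sizes chosen to keep a full run around two minutes: a null fixture
(12 donors, 3 cell types, 2,000 genes, nothing planted) for calibration of
p-values and the FDR; the default planted fixture (12 donors, 5 cell types,
3,000 genes, ~8,200 cells) for recovery, scoring and classification; 20
four-sample instances for brute-force LRT agreement; and reduced pipeline
runs for byte-identical reproducibility. On the planted fixture, per-cell-
type recall of planted genes exceeds 0.8 with pooled empirical FDR near 0.1,
the recovered signatures match the planted ≥2-cell-type truth at Jaccard
above 0.7, aged cells score significantly higher on the up-signature in
every cell type, and the within-batch classifier reaches held-out AUROC
above 0.95 while permuted labels stay at chance. Planted senescence genes
are genuine age effects in their target cell types, so recovery accounting
treats them as true positives there.

# Limitations

- The pipeline consumes pre-labeled cells; clustering, annotation, doublet
  and empty-droplet handling, and embedding are out of scope.
- Dispersion moderation is deliberately simple (median shrink + floor); very
  heterogeneous real pseudobulk data may prefer a trended empirical-Bayes
  estimator.
- Cell-level Wilcoxon tests and cell-level splits are pseudo-replicated;
  sample-level options are provided and should be preferred for inference
  about donors.
- Senescence gene lists are user-supplied; none are bundled beyond the
  synthetic planted set.
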