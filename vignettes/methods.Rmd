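---
title: "Classifying cancer-related lncRNAs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cancer-related lncRNAs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lncScout` labels lncRNA genes as cancer-related or not by integrating
four categories of gene-level features and training balanced classifier
ensembles over resampled negative sets. This vignette documents the
statistical model, every tunable that matters, the synthetic data the
package tests itself on, and the design decisions taken where the
problem was genuinely open.

## Label construction

Positives are a user-supplied curated list. The presumed-negative pool
contains intergenic lncRNAs with no cancer-trait GWAS SNP within
`window_bp = 10000` bases (10 kb) of the gene body, i.e. the window
`[start - w, end + w)` measured from the gene body ends. Two details are
deliberate:

* The SNP catalog is pre-filtered by a configurable trait keyword list
  (`cancer, carcinoma, tumor, leukemia, lymphoma, melanoma, glioma`);
  `filter_snps_by_trait()` makes the filter explicit and testable rather
  than an implicit property of the input file.
* The pool is restricted to intergenic lncRNAs by default
  (`intergenic_only = TRUE`), since antisense/overlapping genes inherit
  SNP proximity from their host loci; a flag lifts the restriction.

Because presumed negatives vastly outnumber positives, training uses
`n_sets` balanced sets of `set_size = 150` negatives each, drawn
independently and uniformly without replacement within each set (the
same gene may recur across sets). The mild residual imbalance between
the positive count and 150 is left as is; no reweighting is applied.

## Feature model

The default manifest defines 83 features; counts always follow the
manifest, never a hard-coded total.

* "TSS up- and down-stream *w*" is read as one merged window
  `[tss - w, tss + w)`, clipped at zero. This single reading yields the
  self-consistent category sizes (5 GC + 3 conservation + 8 repeat +
  1 miRNA + 1 micropeptide = 18 genomic; 9 tracks × 3 regions = 27
  epigenetic). Flank windows do not exclude gene-body bases; with
  typical gene lengths comparable to the window, exclusion would leave
  near-empty upstream-only windows on short genes.
* Conservation and repeat features use the 1 kb flank only; the 5 kb
  flank feeds GC (and the epigenetic means), following the narrower
  reading of which resources apply at which scale.
* Exon (intron) sequence features use the union of exons (introns);
  intron features of intronless genes are *missing*, never zero, and the
  missing mask survives into the feature table.
* Micropeptide length: a user-supplied per-gene peptide table takes
  precedence; the fallback is the longest ATG-initiated ORF over the
  three forward frames of the spliced transcript, in codons excluding
  the stop.
* Uncovered track bases count as signal 0 (bedGraph sparse semantics),
  not missing.
* Missing values are imputed per column with the median of the assembly
  population (`imputation = "median"`); `"zero"` and `"none"` are
  available, and the mask is retained regardless so downstream code can
  distinguish imputed cells.

## Co-expression network

All gene pairs (coding and lncRNA) are tested with Spearman's Rs
(Pearson correlation of average ranks; constant genes are excluded and
logged). Significance uses the variance-stabilized transform
`F(Rs) = atanh(Rs)` and `Z = sqrt((n - 3)/1.06) * F(Rs)`, two-sided
against the standard normal. Multiple testing is controlled by
Benjamini–Hochberg over *all tested pairs* — the standard, monotone
choice where only "adjusted p-value" is specified. An edge requires both
`Rs >= 0.6` (signed) and adjusted `p <= 0.01`.

Driver-gene correlation features keep the raw signed Rs with each of the
18 default driver genes whether or not the pair passes the edge cutoffs;
degree and cancer-protein neighbor counts use the thresholded network.
With 16 samples the BH step is the binding constraint in practice: the
smallest correlation that survives depends on the global p-value
landscape and typically sits near 0.75 rather than 0.6.

## Classifiers and evaluation

Five algorithms run over each balanced set: random forest (ranger),
naive Bayes and RBF-kernel SVM (e1071), logistic regression
(`stats::glm`) and k-nearest neighbors (`class::knn`, k = 5). Defaults
are explicit and serialized via `classifier_config()`: 500 trees, RF
`mtry = floor(p/3)` (keeps informative features visible in wide tables),
SVM decision values as scores, feature standardization fit on training
folds only for SVM/LR/KNN (tree and NB models consume raw features),
and zero-variance columns dropped per training fold.

Cross-validation is stratified ten-fold; the AUC of one training set is
the AUC of the *pooled* out-of-fold scores rather than the mean of ten
per-fold AUCs — with ~15 held-out genes per class per fold, per-fold
AUCs are too noisy to average meaningfully. `roc_auc()` is the
rank/Mann–Whitney statistic, so tied scores count one half.

Unknown genes are scored, by default, with the mean positive-class
probability over one RF per negative set (`mode = "ensemble"`); a
`single_best` mode (the set with the highest CV AUC) is provided because
"best model" phrasing is ambiguous between the two. The candidate
threshold is 0.5 on the ensemble mean — no calibration is attempted, so
the threshold is a convention, exposed as a parameter.

Feature importance is impurity importance from extremely randomized
trees (ranger, `splitrule = "extratrees"`, no bootstrap, all features
per split), averaged over negative sets and normalized to sum to one.

## Candidate evaluation

* Two-sample KS test: D is the ECDF sup-gap; p uses the asymptotic
  Kolmogorov distribution with effective size `n1*n2/(n1+n2)`
  (`stats::ks.test(exact = FALSE)`), adequate at the n ≈ 150 scale the
  tests run at.
* Tumor/normal fold changes: `log2((mean_t + 1)/(mean_n + 1))`, with a
  pseudocount of one normalized count since zero means occur.
* Distance to cancer proteins: minimum gap to any same-chromosome
  anchor (0 if overlapping); the background is 10× the query count of
  uniform seeded positions per chromosome.
* GO transfer: for each term annotating a network neighbor, a one-sided
  hypergeometric test of the neighbors against all GO-annotated coding
  nodes in the network (the defensible background when annotations are
  only supplied for coding genes). Transfer keeps terms with p < 0.05
  without multiple-testing correction — this matches the
  guilt-by-association annotation rule being emulated; a BH option
  exists for set-level analyses. Terms are used as given, with no
  propagation up the GO graph.

## The synthetic bundle

`simulate_bundle()` generates, from one seed, every resource the
pipeline consumes: gene models on 4 chromosomes (one gene per 12.5 kb
slot, so 10 kb SNP windows of neighbors stay disjoint), chromosome
sequences, repeats, GWAS SNPs (cancer-trait SNPs inside "decoy" gene
bodies; benign-trait SNPs sprinkled into pool genes to exercise the
trait filter), conservation and nine histone tracks, a 16-tissue count
matrix, miRNA interactions, GO annotations, tumor/normal matrices,
somatic mutations, and a hidden truth table. Defaults are the reference
study conditions: 150 positives, 600 pool genes, 60 decoys, 200 unknowns
with 50/50 hidden truth.

Ten planted features differ between classes (`planted_features()`):
gene-body SINE and LINE counts (Poisson rates 5 vs 3 and 4.7 vs 2.5),
H1hesc H3k4me1/H3k4me3 gene-body signal (+0.6/+0.6 on sd 0.8), intron GC
(+0.025), exon conservation (+0.075 on sd 0.10), Spearman correlation
with ERBB2/CTNNB1/CDKN2A, and the cancer-miRNA interaction count
(fraction 0.75 vs 0.2 of a class-identical Pois(4) interaction total).
Effect sizes were chosen to land in the KS range D ≈ 0.25–0.6 at
n = 150/150 — clearly detectable but not degenerate, so that no single
category saturates and the integrative comparison stays meaningful.
`effect_scale` multiplies every planted difference; at 0 the classes
share one generative distribution exactly, which is the null
configuration used by the calibration tests.

Expression profiles are built from a small dictionary of four shared
"tissue programs": every lncRNA gets a random unit loading vector over
the programs, and positives receive a boosted loading on program 1, the
cancer program carried by the hot drivers and cancer proteins. Two
properties motivated this design over independent noise profiles:
negatives have *structured* profiles (so profile shape alone does not
trivially separate the classes), and random-sign loadings cancel across
genes, keeping the median-of-ratios size-factor reference clean. The
positive-class loading on the cancer program carries a *random sign*
(activating or suppressing co-expression), so the planted driver signal
lives in correlation magnitude rather than in marginal tissue levels;
the per-tissue expression features carry only a mild planted level shift
(0.3 log2).

What the generator does **not** emulate: realistic genome sequence
composition, read-level noise, transcript isoforms, batch effects,
correlated repeat/epigenetic structure along the chromosome, or GO term
hierarchy. Passing tests therefore demonstrate that the implementation
recovers signal it provably planted — not that the method achieves any
particular accuracy on real data.

`truth_auc_bound()` gives the analytic single-feature ceiling
`pnorm(delta / (sigma * sqrt(2)))` for the Gaussian planted features
(with sigma the feature-level sd, i.e. the per-chunk sd over the square
root of the number of averaged chunks); non-Gaussian features are
flagged not applicable.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run the reference conditions
with 20 negative sets (importance: 10 sets, 300 trees) rather than the
full 100 × 500 design; the across-set spread of per-set AUCs is a few
hundredths, so 20 sets pin the mean AUC to ~0.01 while keeping runs in
the minutes range. All coordinates are 0-based half-open internally;
GTF (1-based closed) and BED conversions live only in the readers and
writers. All randomness flows from explicit seeds through per-stage
derived sub-seeds; library code restores the caller's RNG state.

## Known limitations

* With 16 expression samples, edge significance is coarse: BH makes the
  effective correlation cutoff data-dependent (≈0.75), so degree-based
  features are sensitive to the overall correlation landscape.
* KS p-values are asymptotic; at n below ~25 they are approximate (the
  D statistic itself is always exact).
* Probabilities from the RF ensemble are not calibrated; the 0.5
  threshold is a convention, and candidate counts shift with it.
* The micropeptide ORF fallback scans forward frames of the spliced
  transcript only; it is a proxy, not a peptide predictor.
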