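# netsdecon

Cell-type-resolved analysis of nuclear RNA-seq from sorted and unsorted
brain cell populations, built around the cerebellum, where one population
(granule neurons, ~70% of nuclei) dominates and the clinically central one
(Purkinje neurons, ~0.7%) is nearly invisible to bulk methods. The package
is aimed at analysts who have sorted-population reference profiles (e.g.
FANS-purified nuclei sequenced per cell type) and unsorted bulk samples from
cases and controls, and who want to ask: *which cell types change in
disease, by how much, and what is changing inside each type?*

## What it computes

**Global deconvolution.** For an unsorted sample with expression vector
*x* (counts per million) and a gene-by-cell-type signature matrix *S* of
sorted reference profiles, the cell-type composition is estimated as

    f* = argmin_f || x - S f ||_2   subject to  f >= 0,  sum(f) = 1

solved exactly by active-set enumeration (at most 9 cell types, so the
2^K - 1 candidate supports are cheap and the solution provably attains the
constrained optimum).

**Comparative deconvolution.** Absolute fractions of rare types sit at the
noise floor, so condition contrasts use a two-signature variant: for each
target type a panel [s_target, s_rest] is built, where s_rest is the
unweighted average of all other types' signatures, and the same constrained
fit returns a single "fraction of similarity" per sample. Ratios of group
mean fractions between conditions track the underlying abundance fold
changes. Panels are restricted to genes on which the pooled rest is
homogeneous (the target's markers plus shared background genes); the
methods vignette derives why this is required for unbiased contrasts when
one cell type dominates the mixture.

**Specificity index.** For gene *g* and cell type *A*, the SI is the mean
over all other types *B* of the rank of mean_A(g) - mean_B(g) (descending,
average ranks on ties), averaged over bootstrap resamples of samples within
each type. Low SI = specific marker. Tertile stratification, contamination
scoring (ambient granule RNA detection) and cross-platform signature
correlation build on it.

**Differential expression (simplified).** Per-gene ordinary least squares
on log2 CPM with observed covariates plus residual-PCA hidden covariates,
t-tests on the condition coefficient, Benjamini-Hochberg correction. This
is deliberately *not* a negative-binomial Wald framework; it feeds the same
interface (baseMean, log2FC, stat, pvalue, padj) downstream.

**Gene-set stages.** Preranked GSEA (weighted running-sum enrichment score,
gene-label permutation null, NES-based FDR), gene-set scores with group
contrasts (Δ = log2 fold change in mean set expression), signature-panel
tests, and a transcriptomic age axis: PC1 of age-associated genes regressed
on age in controls, with disease displacement along that axis expressed in
years of apparent aging acceleration.

**Synthetic cohorts.** A negative-binomial generator with full ground truth
(composition presets, marker structure, RNA-content factors, ambient
contamination, donor effects, library sizes) emulating the sorted +
unsorted study design, so every stage above is testable without external
data.

## Worked example

Simulate a control cohort and a disease cohort carrying a single planted
effect (Purkinje loss, 1.85-fold), then recover composition and the fold
change:

```r
library(netsdecon)
library(SummarizedExperiment)

ref  <- makeReference(seed = 7)                      # 2000 genes, 8 cell types
ctrl <- simulateUnsorted(ref, controlCerebellum(), nSamples = 25, seed = 7)
atW  <- singleEffectComposition(controlCerebellum(), "purkinje",
                                1.85, "decrease")
at   <- simulateUnsorted(ref, atW, nSamples = 12, condition = "AT", seed = 8)

expr <- normalizeCounts(cbind(assay(ctrl), assay(at)))
sig  <- truthSignature(ref, genes = unlist(ref@markers))

## global composition of the control samples
fr <- deconvolveGlobal(expr, sig)
round(colMeans(fr[1:25, colnames(sig)]), 4)
#>        granule          basket           golgi        purkinje
#>         0.7002          0.0607          0.0197          0.0071
#>      astrocyte       microglia oligodendrocyte             opc
#>         0.0221          0.1116          0.0132          0.0654

## comparative contrast for the Purkinje panel
panel <- buildComparativePanels(truthSignature(ref),
                                markers = ref@markers)$purkinje
sim  <- deconvolveComparative(expr, panel)
cond <- setNames(c(rep("control", 25), rep("AT", 12)), colnames(expr))
contrastConditions(sim, cond)
#>   cell_type meanControl  meanAT fold direction    t   df   pvalue     padj
#> 1  purkinje     0.00707 0.00364 1.94  decrease 20.4 27.6 3.77e-18 3.77e-18
```

The estimated control composition matches the preset (granule 70%,
Purkinje 0.7%), and the recovered similarity-fraction ratio (1.94) matches
the planted 1.85-fold Purkinje loss within the sampling noise of a
25-vs-12 cohort.

`runPipeline(config, outDir)` wires these stages together from a YAML or
list config (seeded, with a manifest of parameters and output checksums);
see `?runPipeline`.

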