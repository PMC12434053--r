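---
title: "netsdecon: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netsdecon: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
statistical models, the assumptions behind them, the parameters a user can
turn, the decisions made where the design was genuinely open, and what the
synthetic validation does and does not establish about real data.

## The setting

Cerebellar tissue is an extreme deconvolution problem. Granule neurons make
up roughly 70% of nuclei; Purkinje neurons — the cell type most affected in
cerebellar degeneration — are below 1%. Sorted-population nuclear RNA-seq
(fluorescence-activated nuclei sorting followed by bulk sequencing of each
population) provides deep, clean per-type reference profiles. The package
uses those references in two ways: to estimate the absolute composition of
unsorted samples, and to contrast cell-type abundance between disease and
control when the absolute fraction of a rare type is too noisy to compare
directly.

## Normalization

Counts are scaled per million within each sample (`normalizeCounts`);
log expression is `log2(cpm + 1)`. No gene-length correction is applied:
nuclear libraries are quantified with intron-inclusive counting, for which
an effective transcript length is ill-defined, so the per-million scale is
used throughout and the log pseudocount is fixed at 1. Batch and other
technical structure are handled as covariates in the differential stage,
not inside normalization.

## Global deconvolution

For sample expression $x$ (linear per-million) and signature matrix $S$
(per-type means of sorted per-million profiles on a marker gene set), the
composition estimate is

$$\hat f = \arg\min_{f \ge 0,\ \sum f = 1} \lVert x - S f \rVert_2 .$$

The solver enumerates all $2^K - 1$ candidate supports and solves the
equality-constrained least-squares problem on each; by the KKT conditions
the global optimum of this convex program is among the feasible candidates,
so the solution is exact (to linear-solve precision) rather than
iteratively approximate. With at most nine cell types this costs
microseconds per sample. The KKT system is scaled by the mean signature
magnitude for conditioning; this does not change the solution. $x$ and $S$
must share the per-million scale — the pipeline guarantees this by
construction. For inputs on an arbitrary scale, `rescale = TRUE` fits a
free positive scale jointly (equivalently: non-negative least squares
followed by renormalization), which makes the fractions invariant to
rescaling of $x$ at the cost of no longer solving the fixed-scale program;
the default is the literal fixed-scale fit.

Assumptions: expression mixes linearly in linear space; the references
match the mixture's cell states. The estimated fractions are **mRNA
fractions**, not nuclei fractions — a cell type with RNA content per
nucleus $\rho_c \ne 1$ is mis-weighted by exactly that factor. The package
reproduces rather than hides this bias: the generator exposes per-type
$\rho$, and a property test verifies that halving granule RNA content
systematically deflates its estimated mRNA fraction relative to the nuclei
fraction.

## Comparative (target-vs-rest) deconvolution

Absolute fractions of types at the 1% scale carry little contrast
information. The comparative mode builds, per target type $t$, a two-column
panel $[s_t, \bar s_{-t}]$ with $\bar s_{-t}$ the unweighted mean of all
other signatures, and fits the same constrained model, reporting the target
coefficient as a *fraction of similarity*. Group contrasts then compare
these fractions between conditions (Welch t per type,
Benjamini–Hochberg across the types tested together), with the fold change
defined as the ratio of group means, direction reported explicitly.

**Panel gene choice.** Writing the mixture as
$x = w_t s_t + (1 - w_t)\, m_w$, with $m_w$ the *composition-weighted*
mean of the rest, the fitted fraction is approximately

$$\hat g \approx w_t + (1 - w_t)\,
  \frac{\langle m_w - \bar s_{-t},\ s_t - \bar s_{-t}\rangle}
       {\lVert s_t - \bar s_{-t}\rVert^2},$$

so $\hat g$ is proportional to $w_t$ — and fold changes of $\hat g$ equal
fold changes of $w_t$ — only when the second (offset) term vanishes. In a
granule-dominated tissue $m_w$ is far from the unweighted average precisely
on genes specific to individual rest types, and negative-binomial noise on
the dominant type's markers couples into $\hat g$ with a per-sample
standard deviation that can exceed the Purkinje fraction itself. Each
panel is therefore restricted to genes on which the pooled rest is
homogeneous: the target's own specific genes plus the shared background,
excluding every other type's specific genes (`buildComparativePanels`
with `markers` supplied). On that gene set $m_w = \bar s_{-t}$ holds by
construction for the dominant contributions, the offset vanishes, and the
similarity-fraction ratio is an asymptotically unbiased estimate of the
abundance ratio. Without marker information the panels fall back to the
full signature gene set, which remains useful for quality checks (e.g.
sorted-sample purity) but is not recommended for condition contrasts in
strongly imbalanced tissues.

One panel is emitted per signature cell type (eight at the defaults); a
mixed "unsorted" column is not given a panel.

## Specificity index

For gene $g$ and type $A$: over every other type $B$, rank genes by
$\Delta(g; A, B) = \text{mean}_A - \text{mean}_B$ of log2 expression
(descending, average ranks on ties) and take the mean rank; average this
over bootstrap iterations. The published descriptions of this family of
indices leave the resampling unit open; the package resamples **samples
(donors) with replacement within each cell type**, the unit over which a
marker must be stable. With a single iteration the index reduces to the
plain mean-rank statistic, which is what the package's worked oracle tests
pin down. Ties use fractional ranks, making the all-equal case well
defined (every gene gets the midpoint rank). "Specific genes" are the
top-$k$ per type by ascending SI, ties broken lexicographically by gene
identifier — preferred over a significance threshold because downstream
stages need fixed-size panels.

Tertile stratification uses the 33% and 66% linear-interpolation quantiles
(R type 7) of each type's specific-gene mean expression in that type's
samples, with half-open bins $[0, q_{33})$, $[q_{33}, q_{66})$,
$[q_{66}, \infty)$; fully degenerate inputs collapse into one bin with a
warning rather than an error.

## Differential expression, hidden covariates, age

`fitDE` is an ordinary least-squares model on log2 CPM per gene with a
t-test on the condition coefficient and BH correction — an intentionally
simplified, fully deterministic stand-in for count-model inference.
It does **not** implement negative-binomial dispersion estimation, Wald
shrinkage, independent filtering or outlier replacement; users comparing
against count-model results should expect reduced power at low counts.
Zero-variance genes are flagged and reported at $p = 1$. Rank-deficient
designs abort with the collinear columns named (a fully confounded
condition/batch design is never silently absorbed).

Hidden covariates (`estimateHiddenCovariates`) are the top-$k$ principal
components of the residuals after regressing out the primary design — a
deterministic analogue of surrogate-variable detection. $k$ is a user
choice (default 2); the residual-PCA components are orthogonal to nothing
in particular, so they are passed into the design like any observed
covariate and the rank check applies.

`ageAssociation` regresses each gene on age in years (slope units:
log2 expression per year). The transcriptomic age axis
(`transcriptomicAgeAxis`) takes PC1 over all samples of the significant
age genes, oriented so the control slope against age is positive (PCA signs
are otherwise arbitrary; the orientation rule plus the largest-|loading|
sign convention make every result reproducible). Acceleration is defined as

$$\frac{\overline{\text{PC1}}_{\text{disease}} - a}{b} -
  \overline{\text{age}}_{\text{disease}},$$

with $(a, b)$ the control intercept and slope: the disease samples' mean
position expressed in control-years, minus their mean chronological age.
When PC1 barely tracks age in controls ($|r| < 0.3$) the statistic is
undefined and flagged instead of reported. This acceleration summary is the
package's formalization of "disease samples align with much older
controls"; it is a descriptive projection, not a causal estimate.

## Gene-set stages

`gseaPreranked` implements the classic weighted running-sum enrichment
score (hit increments $\propto |stat|^{weight}$ normalized to sum 1, miss
decrements $1/(N - n)$, ES = signed maximum deviation; weight default 1).
Because the input is a preranked list, the null is **gene-label
permutation**: random same-size gene sets. NES divides ES by the mean
|null ES| of matching sign; the nominal p is the same-sign exceedance
fraction (with the +1 correction); FDR q follows the standard NES-based
pooled-null procedure. Leading edge = hits up to the score extremum. Sets
smaller than `minSize` (default 5) in the ranked universe, or spanning the
whole universe (where the miss decrement is undefined), are skipped with a
message. The rank list applies the low-expression filter first: genes with
baseMean strictly below 10 (linear per-million) are removed; ordering ties
are broken by gene identifier so the list is a total order.

Gene-set scores are per-sample means of log2 expression over the set
(z-scoring per gene available, off by default, since the source method's
exact standardization is not restated in the literature the package
follows); Δ is the difference of group mean scores, i.e. a log2 fold
change of geometric-mean expression. Δ is exactly invariant to per-gene
constants shared across samples, but **not** to per-sample shifts — global
normalization differences move scores, which is normalization's job to
prevent, and is documented here as a sensitivity. Signature panels
(astrocyte activation A1/A2/PAN, microglial state clusters MG00–MG12) are
user-supplied GMT files; the tests use small synthetic stand-ins, not the
published lists. Set construction from external single-cell DE tables uses
strict padj < 0.05 and inclusive expressing-fraction ≥ 0.25 boundaries.

## The synthetic cohort generator

`makeReference` + `simulateSorted` / `simulateUnsorted` emulate the study
design the package targets: eight sorted cerebellar populations plus
unsorted mixtures, negative-binomial counts (default dispersion 0.1,
library sizes log-normal around 2×10⁶ — the scale of a desk-size
experiment), per-donor per-gene log-normal effects (sd 0.1, natural log)
shared across a donor's sorted samples, control composition preset
(granule 0.70, Purkinje 0.007, astrocyte 0.022, oligodendrocyte 0.013 from
the tissue literature; basket 0.060, Golgi 0.020, OPC 0.065, microglia
0.113 are configuration defaults closing the simplex), disease effect
preset (÷1.85 Purkinje, ÷1.35 granule, ÷1.52 Golgi, ÷1.45 basket, ×2
oligodendrocyte, ×1.35 OPC, ×1.37 astrocyte, ×1.44 microglia), per-type
RNA-content factors ρ, and ambient contamination: sorted samples can be
mixed with rate α toward the control-composition-weighted pool, which is
granule-dominated — the signature of ambient RNA in droplet-based
single-nucleus data.

**Marker model.** Background genes draw log-normal means (log2 mean 1,
sd 1) with a small independent per-type log-normal deviation (log2 sd 0.1)
so types differ genome-wide, as real sorted profiles do. Marker genes are
modelled as *balanced panels*: every panel gene has the same base
magnitude (default 0.5) in every type and is enriched `boost`-fold
(default 300) in its own type only. Two deliberate choices sit here:

* *Balance.* If marker magnitudes are drawn independently per type from a
  heavy-tailed distribution, the per-type deviation norms
  $\lVert s_c - \bar s\rVert^2$ differ by large random factors, and the
  comparative offset term above acquires a reference-draw-specific bias
  that no estimator downstream can remove — the generator itself would
  make the printed fold changes unrecoverable at any seed. Balanced panels
  are also the realistic description: sorting panels are assembled from
  canonical, comparably expressed markers.
* *Strength.* Canonical cell-type markers in sorted nuclei data are
  enriched by orders of magnitude (often effectively absent outside their
  type). The default boost of 300 encodes that; the per-sample noise floor
  of a rare type's similarity fraction scales like
  $(w_t + 1/(\text{boost}-1))$, so weak markers (boost ≲ 50) push
  Purkinje-scale contrasts below the noise floor of a 25-vs-12 cohort.

**Single-effect mode.** The published per-type abundance ratios are ratios
of independent two-group comparisons and are not jointly consistent with a
single simplex re-normalization; applying all of them simultaneously
cannot reproduce each printed ratio exactly. `singleEffectComposition`
therefore plants one effect per simulated cohort, moving the compensating
mass to (or from) the granule fraction — the dominant pool — and
redistributing proportionally across the other seven types when granule
itself is the target.

**What the generator does not emulate:** read-level artifacts (FASTQ,
alignment, duplication), per-cell single-nucleus data (contamination is
modelled at pseudobulk level), batch structure beyond what users inject as
covariates, correlated gene-gene modules, and compositional presets other
than those configured. Passing recovery tests on these cohorts shows the
estimators are correct under the stated generative model; it does not show
robustness to reference/mixture state mismatch or platform effects in real
tissue.

## Numerical and reproducibility conventions

* Simplex solver: exact active-set enumeration; objective reported as the
  squared residual norm; the grid-search equivalence suite checks it to
  1e-6 on random instances. Degenerate (singular) supports are skipped; a
  sample where no feasible support solves is flagged `converged = FALSE`
  and warned about, never silent.
* Ties: every ranking (variance, SI, rank lists, specific-gene selection)
  breaks ties lexicographically by gene identifier.
* PCA: gene-wise centering, no scaling; each loading vector's
  largest-magnitude entry is made positive.
* Quantiles: R type 7 (linear interpolation), stated wherever used.
* Every stochastic stage takes an explicit integer seed and is
  byte-identical on rerun; the pipeline manifest records parameters, seeds
  and output checksums.
* Problem sizes in the test and acceptance suites (2,000 genes, 30
  markers/type, 25 control + 12 disease unsorted samples, 200–1,000
  permutations, 20-seed Monte-Carlo loops) are chosen so the full suite
  runs in about a minute on one CPU while keeping the Monte-Carlo margins
  far from the pass thresholds.

## Known limitations

* Fractions are mRNA fractions; converting to nuclei fractions requires
  external RNA-content estimates (the ρ machinery shows the direction and
  size of the bias but cannot remove it from real data).
* The DE stage is a linear model on log2 CPM; no count-level variance
  modelling. Its calibration is verified on Gaussian-like synthetic data;
  heavy-tailed real counts at low expression will be conservative or
  anti-conservative in ways count models handle better.
* The comparative mode's unbiasedness argument assumes the panel's
  rest-homogeneous gene set is identifiable (markers known or estimable);
  with badly contaminated references the exclusion list itself degrades.
* Gene-label permutation GSEA ignores inter-gene correlation; q-values are
  anti-conservative for strongly co-expressed sets, as with all preranked
  nulls of this kind.
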