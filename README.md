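# DeconvoMap

Reference-optional deconvolution of bulk tumor RNA-seq into constituent
cell-type expression profiles and per-sample proportions, with projection of
the cancer-epithelial fractions onto a Basal–HER2–Luminal **cancer cell
state map**.

Bulk tumor profiles are mixtures of cancer epithelium, normal epithelium,
stroma and immune cells. Most deconvolution tools regress bulks onto fixed
reference signatures; DeconvoMap instead uses references only to pick
*informative genes* and lets the factorization discover the constituent
profiles from the cohort itself, so novel cell states are not averaged away.

## Method at a glance

1. **Transform.** Counts are mapped to the unit interval by
   `y = 1 − exp(−a·x)` with `a = 1/max{x}` (one global scalar per matrix);
   zeros map to 0 and the observed maximum to `1 − e⁻¹`.
2. **Stage 0 — informative genes.** Welch t-tests on (pseudo-bulk)
   reference profiles, one-vs-rest per cell-type class plus optional
   pairwise contrasts; the top 25 up/down genes per contrast at `p < 1e-4`
   are pooled and any gene selected by more than one contrast is excluded;
   a literature list (e.g. PAM50) can be unioned last.
3. **Stage 1 — factorization.** Alternating exact constrained least squares
   on `T ≈ M·P` over the informative genes: per-gene profiles `M ∈ [0,1]`
   (box QP), per-sample proportions `P` on the simplex (`p ≥ 0`, `Σp = 1`).
   The number of cell types is chosen by replicate-subsample stability.
4. **Stage 2 — counts-scale profiles.** With `P` fixed, per-gene
   nonnegative least squares on the untransformed matrix recovers average
   cell-type expression for any sample group.
5. **Map.** Samples dominated by epithelium are projected onto the
   2-simplex spanned by the Basal/HER2/Luminal components and classified by
   nearest vertex; the three proportions also feed a logistic model of
   therapy response with rank-based ROC evaluation.

A seeded synthetic-data module reproduces the package's validation design —
a four-type reference panel (12/10/10/4 replicates, 25 planted markers
each), profile noise at 10%/5% of the maximum per-gene variance, and 100
mixtures across four purity classes (high / impure / low / control) — so the
whole pipeline is testable without any external download.

## Worked example

```r
library(DeconvoMap)

sim <- simulateMixtureStudy(seed = 1)          # 2000 genes, 100 mixtures
genes <- selectInformativeGenes(
  sim$refs, pThreshold = 1e-4, nTop = 25,
  pairwise = list(
    list(classA = "cancer_epithelial", classB = "stromal"),
    list(classA = "normal_epithelial", classB = "stromal")))
genes
#> InformativeGeneSet: n = 46 genes
#>   sources: cancer_epithelial_vs_rest (11), immune_vs_rest (22),
#>     normal_epithelial_vs_rest (6), normal_epithelial_vs_stromal (3),
#>     stromal_vs_rest (4)

tm <- exprValues(sim$mixtures)
tm <- tm[intersect(geneIds(genes), rownames(tm)), ]
anchors <- anchorProfiles(sim$refs, c(normal_epithelial = 4, immune = 4,
                                      stromal = 4))[rownames(tm), ]
fit <- runStage1(tm, k = 4, seed = 7920, anchors = anchors)
fit
#> DeconvolutionResult: k = 4 cell types, 100 samples, 46 genes
#>   iterations: 208 (converged)
#>   final RSS: 0.0431992
#>   explained variance (centered): 0.9871 ; (uncentered): 0.997

scoreRecovery(fit, sim$truth, genes)@table
#>     component             truth proportion_r2 profile_r2
#> 1 component_1            immune     0.9960827  0.9995630
#> 2 component_2           stromal     0.9925865  0.9990615
#> 3 component_3 normal_epithelial     0.9991626  0.9979064
#> 4 component_4 cancer_epithelial     0.9984112  0.9958497
```

`proportion_r2` is the squared Pearson correlation between estimated and
true per-sample proportions for each matched cell type (profiles
analogously, over the informative genes): values near 1 mean the
factorization recovered both who is in each sample and what each cell type
expresses. (Output shown from a run with these exact calls; the numbers at
other seeds differ within a few percent.)

Cohort-style post-processing:

```r
asn <- assignCellTypes(fit, sim$refs, genes)   # identity per component
prof <- runStage2(inverseTransform(sim$mixtures), fit)  # counts-scale
```

A thin CLI over the same functions ships in `inst/cli/decomap.R`
(subcommands `simulate`, `transform`, `stage0`, `stage1`, `stage2`, `map`,
`respond`, `pipeline`), and `runPipeline()` drives the simulated study
end-to-end from an INI-style config with a reproducibility manifest.

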