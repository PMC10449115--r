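---
title: "Reference-optional deconvolution of bulk tumor transcriptomes"
author: "DeconvoMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-optional deconvolution of bulk tumor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DeconvoMap)
```

## The problem

A bulk tumor RNA-seq profile is a mixture: cancer epithelial cells, normal
epithelium, stroma and immune infiltrate all contribute reads in unknown
proportions. DeconvoMap factorizes a cohort of bulk profiles into a small
number of constituent cell-type expression profiles and per-sample mixing
proportions. The method is *reference-optional*: reference profiles
(cell-line panels or pseudo-bulked single cells) are used only to choose
*which genes* the factorization looks at, never to constrain the solution
itself, so previously uncharacterized cell states can be discovered. The
cancer-epithelial fractions are then projected onto a Basal–HER2–Luminal
simplex (the cancer cell state map) for classification and downstream
modelling such as therapy-response prediction.

## The model

### The unit-interval transform

Stage 1 operates on expression values mapped into the unit interval by the
single-parameter negative exponential

$$y = 1 - e^{-a x}, \qquad a = \frac{1}{\max\{x\}},$$

with one global $a$ per matrix. The formula's image on observed data is
$[0, 1 - e^{-1}]$ — the observed maximum maps to $1-e^{-1} \approx 0.632$,
and the supremum 1 is never attained; we implement the formula verbatim
rather than rescaling to a full $[0,1]$ range. A global $a$ (rather than
per-gene) preserves cross-gene comparability; per-gene scaling is available
as `transformCounts(..., perGene = TRUE)` for experimentation. When two
matrices must live on comparable scales the caller decides whether to reuse
`a` or refit; the default is an independent refit per matrix, matching the
independent preprocessing of reference panels and bulk cohorts.

The transform is strictly increasing, so rankings within genes and samples
are preserved, and it has the analytic inverse $x = -\log(1-y)/a$
(`inverseTransform()`), exact to numerical precision.

### Stage 0: informative genes

`selectInformativeGenes()` runs per-gene Welch t-tests on transformed
reference values, one-vs-rest for every cell-type class and optionally for
extra pairwise contrasts (e.g. cancer-vs-stroma, whose separation the
one-vs-rest contrasts dilute). Among genes passing the p-value gate, the
`nTop` most up- and downregulated per contrast are kept, ranked by the
difference of group means — "upregulated" denotes effect direction and
size; significance is already gated by the threshold. Ties are broken by
absolute difference and then gene identifier, so selection is
deterministic. A gene selected by more than one contrast does not
discriminate a single class and is *excluded entirely* rather than
de-duplicated. A literature list (e.g. PAM50) is intersected with the
available genes, added last, and is exempt from the exclusion rule, since
its purpose is to inject subtype-specific signal regardless of the
reference contrasts. Welch's unequal-variance test is used throughout
because reference classes are routinely unbalanced (over a hundred
epithelial pseudo-bulks against ten T-cell pseudo-bulks).

Pseudo-bulk references are built by `buildPseudobulks()`: cells below
100,000 total counts are dropped, survivors are ranked by coverage, blocks
of five cells are summed (incomplete trailing blocks dropped, keeping
pseudo-bulk depth comparable), every pseudo-bulk is rescaled to the highest
pseudo-bulk total across classes, and the panel is transformed. Classes
that cannot produce two pseudo-bulks are dropped with a warning, since the
Stage 0 t-tests need within-class replication.

### Stage 1: constrained factorization

Given the transformed bulk matrix $T$ (informative genes × samples) and a
chosen number of cell types $k$, Stage 1 alternates two exact convex
solves:

* profile step — per gene $g$: $\min_{0 \le m \le 1} \lVert T_{g\cdot} -
  m^\top P \rVert^2$ (box-constrained least squares);
* proportion step — per sample $j$: $\min_{p \ge 0,\ \sum p = 1}
  \lVert T_{\cdot j} - M p \rVert^2$ (simplex-constrained least squares).

Both reduce to nonnegative least squares and are solved by a compiled
Lawson–Hanson active-set routine; the equality and box constraints are
imposed through heavily weighted auxiliary rows (weight $10^6$ on
unit-scale data), which perturbs solutions by far less than any tolerance
used downstream, and unit tests verify the solutions against exhaustive
grid search. Because each half-step is an exact minimization, the residual
sum of squares is non-increasing; if floating-point noise ever produces a
negligible uptick the iteration reverts to the previous factors and stops,
so recorded trajectories are monotone by construction. Iteration stops when
the RSS decrease falls below `rssTol` (default 1e-10) or at `maxIter`
(default 2000).

The factorization is biconvex, not convex, so alternating minimization can
settle in a poorer local optimum depending on the start. Initialization
samples $k$ distinct sample columns (drawn from the *sorted* sample names,
making the fit invariant to input column order) and perturbs them with
uniform noise of amplitude 0.05, clipped to $[0,1]$ — data-plausible starts
converge much faster than uniform random matrices. `runStage1()` runs
`nStarts = 5` seeded restarts by default and returns the lowest-RSS fit;
in testing, single starts occasionally (roughly one run in ten) landed in
local optima with visibly degraded recovery while the best-of-five never
did.

Pure reference profiles can be appended to the input as *anchors*
(`anchors =` argument): they take part in the fit, stabilizing components
that are rare in the cohort, and are excluded from all reported outputs.
The simulated validation study anchors four normal-epithelial, four immune
and four stromal profiles alongside the 100 mixtures, and cohort-scale runs
may do the same.

Explained variance is reported against both the centered and the
uncentered total sum of squares (`explainedVariance`,
`explainedVarianceUncentered`), since the appropriate baseline for a
bounded transformed scale is debatable; the centered figure is the
headline one.

### Choosing k: replicate-subsample stability

`estimateStability()` runs, for every candidate $k$, Stage 1 on `nReps = 3`
subsamples of 80% of the samples (drawn without replacement; genes are
never subsampled) and matches components between every replicate pair by
maximizing total Pearson correlation of the proportion estimates over the
shared samples (Hungarian assignment). A $k$ is *stable* when every matched
correlation is significant (two-sided Pearson test, $\alpha = 0.05$);
scanning upward, the chosen $k$ is the largest stable value before the
first loss of stability. Each replicate re-randomizes both the subsample
and the initialization, and uses the same best-of-restarts rule as
`runStage1` so that replicate disagreement reflects the data rather than
initialization luck.

Two caveats are worth stating plainly. First, replicate pairs share about
64% of their samples, so an overfitted extra component can reproduce
between replicates through the shared noise realizations; with ~60-80
shared samples the $\alpha = 0.05$ gate has enough power to declare such
correlations significant, which biases the criterion toward one component
too many on data where the true $k$ is clean-cut. The per-$k$ mean and
minimum matched correlations are therefore reported alongside the binary
choice — a sharp drop (say from above 0.98 to below 0.9) is a more
informative signal than the significance gate alone, and users should
inspect the table rather than consume `chosenK` blindly. Second, a $k$
below the first stable value can be unstable simply because distinct merges
of true types compete; the scan therefore ignores instability before the
first stable $k$.

### Identity assignment

`assignCellTypes()` correlates each estimated profile column with
class-mean reference profiles over the informative genes and assigns the
best-correlating class; components correlating below 0.2 with everything
(or with zero variance) are labelled `unassigned`.
`labelEpithelialSubtypes()` labels epithelial components with the
annotation subtype in which their mean proportion is highest; a component
dominant in control tissue becomes `Normal`, and two components claiming
the same subtype are both labelled with the tie reported, never silently
reassigned.

### Stage 2: untransformed profiles

With proportions fixed, per-cell-type average expression on the raw count
scale solves, per gene, $\min_{m \ge 0} \lVert x_g - m^\top P \rVert^2$
(plain NNLS). The estimate is the average over the chosen sample group, so
the caller may subset samples (dominant-profile groups, subtype cohorts,
and so on — group definitions are caller-supplied, not hard-coded).
Components whose mean proportion in the group falls below 0.01 are not
identifiable there and are reported as `NA` — silent zeros would
masquerade as biology. Rank-deficient proportion matrices are solved with
a ridge of 1e-10 and a warning, as in Stage 1. When quantile normalization
was applied upstream, Stage 2 takes the normalized but untransformed
matrix.

### The cancer cell state map

Samples well explained by the three cancer-epithelial components are
selected by strict thresholds (combined epithelial proportion > 0.7 and
Basal + HER2 + Luminal > 0.1), the trio is renormalized to sum to one, and
plotted in ternary coordinates $x = h + l/2$, $y = (\sqrt{3}/2)\,l$ —
Basal at the left vertex, HER2 right, Luminal top, unit side length; the
convention is fixed so maps are comparable across runs. Classification is
the argmax coordinate, with exact ties broken Basal > HER2 > Luminal and
flagged. Because normalization is a positive rescaling, classifying the
normalized point equals the argmax over the raw trio; a property test
asserts this on ten thousand random points.

### Therapy response

`fitResponseGLM()` fits a binomial GLM (logit link) of a binary response on
the three subtype proportions. Quasi-complete separation is detected
(boundary fitted probabilities or divergent coefficients) and flagged; the
maximum-likelihood coefficients are then unreliable, and prediction falls
back to a weakly ridge-penalized fit ($\lambda = 10^{-3}$) maximized
directly. RECIST categories can be dichotomized as CR-vs-else or
CRPR-vs-else. `rocAUC()` uses the rank (Mann–Whitney) formulation with
midranks, which equals pair enumeration with ties counted a half — the
test suite asserts this identity on tied fixtures.

## The synthetic validation study

`simulateMixtureStudy()` reproduces the package's end-to-end validation
design, standing in for an external 36-profile reference panel:

* **Reference panel.** Four types — cancer epithelial (12 replicate
  profiles), normal epithelial (10), immune (10), stromal (4). Per gene, a
  log-normal baseline (meanlog $\log 100$, sdlog 0.6); per type, a
  log-normal per-gene effect of sd 0.9 on the log scale, so types differ
  transcriptome-wide as distinct lineages do; 25 planted, pairwise-disjoint
  marker genes per type at eightfold elevation; replicate profiles jitter
  by multiplicative log-normal noise of sd 0.05, the scale of technical
  replication. 2,000 genes by default.
* **Noise.** After transformation, each profile receives additive Gaussian
  noise with variance equal to 10% (cancer) or 5% (normal types) of the
  maximum per-gene variance across that type's replicates, clipped into
  $[0,1)$. "Maximum variance" is read as the maximum per-gene variance
  within the type's replicate panel; noise is applied on the transformed
  scale because profiles are transformed before mixing (a raw-scale option
  exists).
* **Mixtures.** 100 mixtures, 25 per purity class: high purity draws the
  cancer fraction from Uniform(0.6, 0.9); impure fixes it at 0.40; low
  purity fixes cancer at 0.10 with normal epithelium from Uniform(0.5,
  0.8); controls have zero cancer and normal epithelium at 0.70. The upper
  bounds keep all four types present. The remainder is split between
  stroma and immune by a symmetric Dirichlet(1,1) draw. Each mixture is the
  linear blend of one randomly chosen noisy replicate per type.

Recovery is scored by `scoreRecovery()`: components are matched to truth by
the optimal correlation assignment on proportions, and the squared Pearson
correlation is reported per matched pair for the proportion vectors and for
the profile columns over the informative genes. `scripts/acceptance.R`
reruns the whole design — generator, Stage 0 selection with the
cancer-vs-stroma and normal-vs-stroma pairwise contrasts, anchored Stage 1
at $k = 4$ — and reports the minimum per-type R².

What the generator does *not* emulate: count-level sampling noise in the
bulk mixtures (mixing is exact on the transformed scale), batch effects,
within-type continuous gradients, and the correlated gene-gene structure of
real transcriptomes (type effects are drawn independently per gene). One
visible consequence: with independent effects the same strong genes top
several contrast rankings, so the multi-list exclusion rule removes more
genes than it does on real panels, and the surviving informative set is
smaller (typically 40–60 genes here) than reference panels yield in
practice; the set still spans every contrast. Passing the simulation study
therefore demonstrates correctness of the machinery under the stated noise
model, not robustness to everything real cohorts contain.

A second fixture — mixtures built from exactly four type-mean profiles
plus unstructured Gaussian noise (sd 0.01) — is used wherever a test needs
data containing *exactly* four cell types, in particular for the stability
scan: the purity-structured study proper contains genuine replicate
substructure (each mixture draws one of twelve cancer replicate profiles),
so "how many types are really there" is ambiguous beyond four.

## Numerical choices

* Constraint penalty weight $10^6$; constraint violation after
  renormalization is below $10^{-10}$.
* Ridge 1e-10 with a warning for rank-deficient systems — never silent.
* Stage 1 restarts: 5; stability replicates use the same rule.
* Assignment floor 0.2 for `unassigned`; Stage 2 identifiability floor
  0.01.
* Dominant-component and vertex ties break deterministically (component
  order; Basal > HER2 > Luminal) and are always flagged or logged.
* Seeds: every stochastic entry point takes an integer seed; derived seeds
  stay below $2^{31}$.

## Problem sizes in the test suite

The suite exercises the full study at its native size (2,000 genes, 100
mixtures, $k=4$) and the stability scan at $k = 3..8$ on the
exactly-four-type fixture; grid-search oracle checks run on instances of up
to 5 genes and 3 components at step $10^{-3}$, where exhaustive enumeration
is exact and fast. These sizes keep any single check within seconds to a
few minutes on one core while leaving no algorithmic path untested.

## Known limitations

* The stability criterion's $\alpha = 0.05$ gate is permissive on clean
  data (see above); treat `chosenK` as a recommendation accompanied by the
  correlation table.
* Stage 2 estimates cohort-average profiles, not per-sample expression.
* The simplex map assumes the three cancer components have been correctly
  identified; `filterMappableSamples()` errors if the assignment lacks one
  of them rather than guessing.
* Cell lines and other pure samples are mapped through the same
  proportion-estimation route as tumors; no separate clustering step is
  attempted.
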