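---
title: "Models and methods behind metabnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metabnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

metabnet implements the analysis workflow of a case–control untargeted
plasma metabolomics study of rheumatoid arthritis (RA) and systemic lupus
erythematosus (SLE): QC-based drift normalization and filtering, OPLS-DA/VIP
feature selection with rank-based univariate testing, chemical-similarity
module analysis, metabolite–cytokine/HDL correlation networks, and
combined-metabolite logistic biomarkers. This vignette explains the models,
the defaults and their rationale, the synthetic cohort the test suite is
built on, and the package's known limitations.

## The synthetic cohort generator

Raw data for cohorts of this kind are usually available only on request, so
the package treats the *generative model* of such a study as a first-class,
tested component. `simulate_cohort()` draws, for feature $j$ on platform
$p$ and biological sample $i$ in group $g$:

$$\log X_{ij} = \mu_j + \beta_{c(j),g}\,\sigma + d_j(t_i) +
  \sigma\left(\lambda_j Z_{f(j),i} + \sqrt{1-\lambda_j^2}\,\varepsilon_{ij}\right)$$

* $\mu_j \sim U(\log 10^4, \log 10^6)$ is the feature baseline.
* $\beta_{c,g}$ is the planted group effect of chemical class $c$, in units
  of the within-group SD $\sigma$ (default $\sigma = 0.4$ on the log scale,
  a mid-range biological CV for plasma metabolites). Defaults encode the
  qualitative disease signature: phospholipids and sphingolipids at
  $-1$ SD and glycerolipids at $+1$ SD in both diseases, fatty acids at
  $-0.5$ SD. Per-feature overrides support planting exact biomarker pairs.
* $d_j(t)$ is injection-order drift: one shared instrument trend per
  platform (monotone plus a 1–2-cycle smooth component), followed by each
  feature with its own amplitude (up to `drift_amplitude`, default 0.3 log
  units), direction, and a smaller feature-specific wobble (30%). Sharing
  the trend across features reflects instrument-sensitivity drift and is
  what cross-feature QC regression exploits.
* $Z_f$ are latent factors shared with cytokines and HDL. A covariate may
  load on several factors; its residual variance is
  $1-\sum_k \lambda_k^2$. The default "inflammation hub" splits the
  GM-CSF loading (0.7 + 0.7) over two factors with disjoint sphingolipid
  groups (loadings $-0.95$): a single shared factor would force the linked
  metabolites to inter-correlate as strongly as they correlate with the
  cytokine, which no real hub shows, and at $n = 23$ the hub could then
  never dominate the network degree.
* Pooled-QC injections are replicates of the cohort mean at each feature,
  with small replicate noise (default log-SD 0.05, i.e. ~5% CV) modulated
  by the same drift. Schedules follow the emulated design: LC, 10 leading
  QCs then one per 8 samples; GC, 6 then one per 5.
* Missingness is left-censoring below the per-feature `missingness`
  quantile (default 0.10) of the biological values — missing-not-at-random,
  as in MS data. A small fraction of features is censored heavily (85%) or
  given poor QC repeatability (log-SD 0.35) so the presence and %CV filters
  have genuine work to do.

Annotation SMILES are homologous series on one fixed head group per class
(diacyl-PC, ether-PE, ceramide-type sphingolipid, diacylglycerol,
arylalkanoic acid, fatty acid) with acyl chains of ≥ 8 carbons varying in
length. Path fingerprints saturate on long linear chains, so each class is
a tight group in Tanimoto space while head groups keep classes apart — the
structure the chemical-clustering stage is meant to recover. The flip side
is that within-class fingerprint variation is essentially nil, so in
pipeline runs the modules coincide with the clusters; the module-splitting
logic is exercised on constructed distance matrices in the test suite
instead.

What the generator does **not** emulate: raw spectra, retention-time
drift, adducts/isotopes, batch effects across studies, non-Gaussian heavy
tails, and correlated missingness across features. Passing tests therefore
certify the statistical machinery under a plausible model of the design,
not performance on any real cohort.

## QC normalization and filtering

`serrf_normalize()` trains, per feature, a random forest on the pooled-QC
injections of that feature's platform; predictors are the injection order
plus the `k_correlated = 10` features most correlated with it across QC
injections, with 500 trees (fixed, reproducible defaults in the spirit of
the cited QC-RF method). Two implementation details matter numerically:

* predictor features are standardized **within QC and within biological
  injections separately** — biological variation is much larger than QC
  repeatability, and unstandardized predictors would push the forest
  outside its training range;
* the regression target is standardized before fitting and unscaled after
  prediction, which makes the normalization exactly scale-equivariant
  (multiplying a feature by $c$ multiplies its normalized values by $c$).

Each sample is divided by predicted/QC-median intensity, and the feature
is re-anchored so its QC median is preserved exactly. Platforms with fewer
than 5 QCs fall back to a LOESS fit on injection order (span 0.75, a
robust default for sparse series), with a warning. On drifted synthetic
data the normalization strongly reduces QC %CV (typically ~10% → ~2–3%
at the defaults) and removes the bulk of the drift–order rank correlation
in biological samples; a residual above the pure-noise floor remains
because biological predictor noise leaks into the per-sample drift
estimate — an inherent property of cross-feature QC regression, visible
in the drift-removal test's thresholds.

Filters follow the published rules: presence in ≥ 80% of at least one
study group (computed on biological samples of the feature's platform; the
QC pool is not a study group), and QC %CV ≤ 20% (LC) / ≤ 30% (GC) —
boundary values pass, since exclusion applies to CVs *greater than* the
threshold. Features with fewer than two observed QC values fail the CV
filter (repeatability cannot be demonstrated); this convention keeps the
two filters order-independent. Whether the original analysis imputed after
filtering is unstated; metabnet imputes left-censored remnants with half
the feature minimum, the standard stand-in for sub-LOD intensities, and
normalizes *before* filtering because the QC-based method needs the raw
drift.

## Differential analysis

Intensities are log-transformed and Pareto-scaled per comparison
($x \to (\log x - \overline{\log x})/\sqrt{s}$); Pareto scaling leaves the
scaled variance equal to the SD of the log values, a compromise that keeps
large fold changes influential without letting them dominate.

`fit_oplsda()` is a NIPALS O-PLS for a binary class: orthogonal components
are estimated and deflated sequentially
($w_o \propto p - (w^\top p)\,w$), then a single predictive component is
fitted on the deflated matrix. With `n_ortho = 0` the fit reduces exactly
to single-component PLS1 (tested against an independent iterative NIPALS
oracle). Defaults: one orthogonal component — the standard two-class
choice; the original software's automatic component selection is not
reproducible from its outputs. VIP is computed on the predictive component
only (the common convention), giving the exact identity mean(VIP²) = 1.
Because OPLS-DA with $p \gg n$ always separates in-sample, the package
exposes `q2_oplsda()` (k-fold CV of the whole fit) as the permutation
diagnostic: under shuffled labels Q² ≤ 0 almost always.

Univariate testing is the two-sided Wilcoxon–Mann–Whitney test per
feature (exact for small untied samples, tie-corrected normal
approximation otherwise) with Benjamini–Hochberg correction across the
comparison's features — "FDR-corrected" is unspecified in such reports
and BH is the field default. Fold change is the ratio of raw-scale group
medians, robust to the transform choice. The selection rule is
**VIP > 1 and q < 0.05**, both strict; a `mode = "raw"` switch thresholds
the unadjusted p instead, since published descriptions of this rule are
ambiguous between raw p and FDR q (q is the default as the conservative
reading). OPLS-DA is refit per pairwise comparison on that comparison's
samples only, as a two-class method requires.

## Chemical mapping and WMCSA

Fingerprints are deterministic 1024-bit hashed path fingerprints computed
from SMILES (OpenBabel FP2 via ChemmineR/ChemmineOB); Tanimoto similarity
is $|a \wedge b| / |a \vee b|$ and the clustering metric is
$1 - T$. Clusters come from Ward-linkage hierarchical clustering with K
chosen to maximize the mean silhouette width over K = 2…10 (smallest K on
ties); all-identical inputs degrade to a single cluster with a warning.

Module refinement re-cuts each cluster's own Ward subtree at the number of
sub-branches that maximizes the mean silhouette among cuts whose smallest
module still has `min_size` (default 3) members; clusters too small to
split stay single modules. This guarantees that modules partition the
metabolite set and refine the clusters. A literal "every branch of
sufficient size becomes a module" rule degenerates on chain-shaped
dendrograms (it peels leaves one at a time), which is why the
silhouette-constrained cut was chosen instead.

The exact weighting of the summarization step in the cited methodology is
not restated in available descriptions, so WMCSA is realized here
explicitly as the module eigenvector: the first principal component of the
standardized log-abundance submatrix of the module's members,
sign-oriented to correlate positively with the member mean and
standardized to zero mean / unit variance. As a first PC it provably
explains at least as much member variance as any single member profile.
Group comparisons of module scores use Kruskal–Wallis followed by
pairwise Dunn z tests (tie-corrected) with Bonferroni adjustment over the
three group pairs.

## Correlation networks

Networks are built per disease on that disease's samples only. All
pairwise Spearman correlations among the panel — metabolites with
q < 0.05 for the comparison, the disease's cytokine panel (RA: GM-CSF,
CX3CL1, IFN-α2, IL-12p70, IL-17A, TNF-α, IL-1β, IFN-γ, IL-2; SLE: the
same core plus MCP-1 and IL-10, minus IL-2), or the clinical set — are
computed with average-rank ties; p-values are exact (full enumeration) for
n ≤ 9 untied pairs and t-approximate otherwise. Edges keep every pair
with raw p < α = 0.05 (no multiplicity correction, matching the source
convention) and record the sign.

The distance transform is $d = 1 - |\rho|$: strong correlations of either
sign indicate proximity (negative edges are drawn inside the layout, not
pushed away); a `distance = "signed"` switch provides $(1-\rho)/2$ for
users who want anticorrelated nodes far apart. Non-significant pairs have
no direct edge ($d = \infty$) before Floyd–Warshall completion; after it,
still-disconnected pairs are placed at 1.5× the largest finite geodesic
*for the embedding only* (the geodesic matrix keeps the $\infty$).
The 2-D layout is classical (Torgerson) MDS of the geodesics with the
Kruskal-type stress reported; a published workflow refines such layouts
with an additional learning step, which is a visualization-only concern
and out of scope here.

## Biomarker scoring

`combined_biomarker()` log-transforms one or two metabolites (consistent
with the preprocessing scale; the scale entering the original models is
unstated), fits a plain binomial GLM by IRLS, scores every sample with its
predicted probability, and reports the **apparent** (in-sample) ROC and
AUC — published AUCs of 0.997 at n = 23 + 27 imply no held-out
evaluation, and the package mirrors that procedure while offering a
`cv = k` option (off by default). Quasi-separation is detected and
flagged, not corrected (no Firth penalty): the fitted probabilities, and
hence the ROC, remain well defined. The ROC sweeps unique thresholds;
tied scores advance the curve diagonally, so the trapezoidal AUC equals
the Mann–Whitney statistic with tie-halving exactly.

The generator supplies the matching oracle: for equal-covariance Gaussian
log intensities with independent features, the optimal two-class AUC is
$\Phi(\sqrt{\delta^\top\Sigma^{-1}\delta}/\sqrt 2)$, which
`theoretical_auc()` evaluates from the planted effect sizes (it refuses
latent-factor features, whose covariance is not $\sigma^2 I$).

## Clinical table statistics

Numeric variables: median (IQR) per group, Kruskal–Wallis (tie-corrected,
via `stats::kruskal.test`), pairwise Dunn z with tie correction and
Bonferroni flags. Categorical variables: the Freeman–Halton extension of
Fisher's exact test, implemented by complete enumeration of all tables
with the observed margins; the two-sided p sums the probabilities of
tables no more probable than the observed one (within a 1e-7 relative
tolerance for floating-point ties), the convention of mainstream
statistical software. Enumeration is limited to 3×3 tables, which covers
the three-group/two-level tables this design produces; the enumerated
probabilities sum to 1 as an invariant test.

## Numerical choices and degenerate inputs

* Zero-variance features Pareto-scale to zeros (warning); constant
  features pass through normalization unchanged.
* OPLS stops adding orthogonal components when no orthogonal variation
  remains (weight norm < 1e-10); a data matrix with no covariance with the
  class is an error, as VIP would be undefined.
* Identical group values give Wilcoxon p = 1 and fold change 1;
  all-identical observations give Kruskal–Wallis H = 0, p = 1 (warning).
* Silhouette K selection breaks ties toward the smallest K; module ids are
  deterministic (`c<cluster>.m<index>`).
* Fisher tests with a zero margin return p = 1 with a warning.
* All simulation-based functions take explicit seeds; the pipeline driver
  derives every stage's randomness from the single configured seed and
  writes MD5s of all artifacts to the manifest, making a run a pure
  function of (inputs, config, seed).

## Problem sizes used in the checks

The packaged tests run the generator at the study's group sizes
(27/23/22) with reduced feature panels (24–120 features) and moderate
replicate counts (10–60 per property), and the acceptance script runs the
full 431-feature design once plus the recovery studies at reduced panel
sizes; these sizes were chosen to give stable Monte-Carlo estimates of
each property while keeping a complete run in the minutes range on a
single core.

## Known limitations

* SERRF-style correction attenuates but does not eliminate drift at
  biological injections (predictor-noise leakage, discussed above).
* Apparent AUCs are optimistic by construction; use `cv` for honest
  discrimination estimates.
* The Freeman–Halton implementation enumerates exhaustively and is meant
  for small tables only.
* Fingerprint-identical molecules (long-chain homologues) are
  indistinguishable to the chemical mapping; this is a property of path
  fingerprints, not of the clustering.
* The pipeline assumes one injection-order sequence per platform and one
  plasma aliquot per sample per platform; longitudinal or multi-batch
  designs are out of scope.
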