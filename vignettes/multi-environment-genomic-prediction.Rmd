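---
title: "Factor-analytic multi-environment genomic prediction with faGBLUP"
author: "faGBLUP maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factor-analytic multi-environment genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The model

faGBLUP analyses multi-environment plant breeding trials with a
single-stage linear mixed model

$$ y = X\tau + Z_g u_a + Z_g u_{\bar a} + Z_u u + \eta $$

where $y$ stacks the plot-level trait records over $p$ experiments
(a year-site-irrigation combination is one experiment), $\tau$ holds
experiment means and any further fixed design effects, $u$ collects
design random effects from the field phase (replicate, irrigation bay,
row, range) and the laboratory phase (measurement day, instrument
carousel, carousel well), and $\eta$ is the residual, with one variance
per level of a grouping column (by default the laboratory-phase year).

The genetic signal of each line in each environment is split into two
components with different kernels across lines:

* **additive** effects $u_a$ with $\mathrm{var}(u_a) = G_a \otimes K$,
  where $K$ is the genomic relationship matrix; these are transmissible
  and predictable for lines without phenotypes, through their genomic
  relationships;
* **residual genetic** effects $u_{\bar a}$ with
  $\mathrm{var}(u_{\bar a}) = G_{\bar a} \otimes I_m$: line-specific,
  independent among lines (dominance, epistasis and other non-additive
  variation); they improve the estimate of a phenotyped line's total
  genotypic value but cannot be transferred to untested lines.

$G_a$ and $G_{\bar a}$ are $p \times p$ covariance matrices across
environments. Each can be diagonal (`"diag"`: heterogeneous variances,
zero across-environment covariance) or factor analytic of order $k$
(`"fa<k>"`): $G = \Lambda\Lambda' + \Psi$ with a $p \times k$ loading
matrix and environment-specific variances. The FA form captures
genotype-by-environment correlation heterogeneity with
$pk - k(k-1)/2 + p$ parameters per component instead of the $p(p+1)/2$
of an unstructured matrix. For identifiability the upper triangle of
$\Lambda$ is constrained to zero; the likelihood is invariant to
orthogonal rotation of the loadings, so only $\Lambda\Lambda'$ is
interpretable.

Downstream summaries are the field's standard ones:

* GEBV$_{ij} = \hat u_{a,ij}$ and GV$_{ij} = \hat u_{a,ij} +
  \hat u_{\bar a, ij}$ (`extractGEBV()`, `extractGV()`);
* between-environment genetic correlation matrices from $G_a$,
  $G_{\bar a}$ or their sum (`envCorrelation()`), clustered with
  agglomerative hierarchical clustering on $1 - r$
  (`clusterEnvironments()`);
* generalized heritabilities from the average pairwise prediction error
  variance (APPEV) of the BLUPs,
  $H_j = 1 - \mathrm{APPEV}_{GV,j} / (2(\sigma^2_{a,j} +
  \sigma^2_{\bar a, j}))$ and
  $h^2_j = 1 - \mathrm{APPEV}_{GEBV,j} / (2\sigma^2_{a,j})$ — the
  Cullis-type form appropriate for unbalanced data;
* model ladders compared by $AIC = 2k - 2\ell_R$ (genetic covariance
  parameters only, as design and residual parameters are shared) and
  likelihood-ratio tests (`modelLadder()`, `aic()`, `lrt()`);
* replicated fivefold cross-validation of untested-line GEBVs against
  full-data GVs, with relative accuracies
  $\mathrm{RAPV} = r/\sqrt{H}$ and $\mathrm{RABV} = r/\sqrt{h^2}$ and a
  gain-per-unit-time projection $2 \times \mathrm{RABV}$ under a halved
  breeding cycle (`runCV()`, `rapv()`, `rabv()`, `gainPerTime()`).

# REML estimation: algorithm and numerical choices

All variance parameters are estimated by maximizing the restricted
log-likelihood directly with L-BFGS-B on an unconstrained
parameterization: FA loadings are free, variances ($\psi$, design and
residual variances, diagonal genetic variances) are optimized on the
log scale with a floor of $10^{-8}$ times the phenotypic variance.
Gradients are analytic, via
$\partial \ell / \partial \theta = -\tfrac12[\mathrm{tr}(P\,
\partial V) - y'P\,\partial V\,P y]$, which makes each iteration cost a
single Cholesky factorization plus $O(n^2)$ work per parameter class.
We chose direct gradient-based maximization over average-information
updates because it is simpler to verify (the gradient is tested against
finite differences) and robust near the parameter-space boundary; the
stationary point is the same.

Two exact computational routes evaluate the same likelihood:

* a **dense route** that forms the $n \times n$ marginal covariance
  $V$ directly — used for general unbalanced two-phase data with design
  random terms; practical to a few thousand records;
* an **eigendecomposition route** for balanced data (one record per
  line per experiment, no design terms, residual grouping constant
  within experiment): with $K = U D U'$ the likelihood factors over the
  $m$ eigencomponents, each a $p$-dimensional Gaussian with covariance
  $d_i G_a + G_{\bar a} + R_p$, giving $O(m\,p^3)$ evaluations.

The two routes are tested to agree with each other and with an
independently coded error-contrast (projection-matrix) oracle
(`loglikOracle()`); BLUPs and PEV blocks are tested against a dense
Henderson mixed-model-equation solver written in the scaled
($u = G^{1/2} v$) form.

Other numerical choices:

* **Starting values**: deterministic, from per-experiment phenotypic
  variances (25% genetic per component, the remainder split between
  design terms and residual); the first FA loading column starts at the
  square root of 70% of the component share and later columns at small
  alternating values. Along a model ladder each fit warm-starts from
  the best nested converged model, rotating its covariance estimate
  into the constrained loading form.
* **Convergence**: L-BFGS-B default tolerances with an iteration cap of
  500; an abnormal line-search termination triggers up to two restarts
  (resetting the Hessian approximation) and is finally accepted only if
  the projected gradient is numerically zero. Non-converged fits are
  flagged, never silently used; the ladder excludes them from AIC
  selection and cross-validation drops such folds (more than 20%
  dropped folds aborts the run).
* **Conditioning**: $K$ carries a ridge of $10^{-6} \times$ its mean
  diagonal; linear solves apply one step of iterative refinement so
  that solutions stay accurate when a variance component collapses to
  its bound.
* **Ties and ordering**: experiments keep their order of first
  appearance; clustering ties follow `hclust`'s deterministic
  tie-breaking.

A degeneracy worth knowing about: with a single record per
line-experiment cell, the *diagonal* of $G_{\bar a}$ and the residual
variance are confounded (their sum is identified; only the
off-diagonals of $G_{\bar a}$ are separately identified, through
cross-environment covariances of the same line). The likelihood is then
flat along that ridge; estimates of the two terms individually are
arbitrary even though BLUPs of $u_a$, all covariances, and model
comparisons are unaffected. Replicated designs (the two-phase simulator
default) identify both terms.

# The trial simulator

`simulateMarkers()` draws independent biallelic markers with uniform
minor allele frequencies on the configured range and an optional
missing-call rate — no linkage disequilibrium and no population
structure, emulating a diverse panel with no detectable clustering, and
keeping the relationship-matrix oracle analytic.
`simulateTrial()` draws the two genetic components from their exact
Kronecker covariances, then lays records out as a split-plot field
phase (irrigation as the main-plot factor; lines randomized within
replicates on a row-by-range grid) and a partially replicated
laboratory phase: field plots are pooled per year, a random 20%
(replication level 1.20) is measured twice, and samples are assigned
sequentially to measurement days (capacity 150), carousels (30) and
wells.

An optional `nDroppedLines` removes a random subset of lines from the
last year's records, emulating lines excluded from a follow-up season;
the default is 0.

Default conditions mirror the motivating study's design: 358 lines,
4,162 post-QC markers, 8 experiments (2 years x 2 sites x 2 irrigation
treatments), 2 field replicates, laboratory replication 1.20. The
default generating parameters use genetic variance magnitudes on the
study's reported scale (additive about 0.012, residual genetic about
0.030 per experiment) arranged in a two-cluster pattern (the first
year's rainfed experiments versus the rest; within-cluster genetic
correlation about 0.9, across about 0.2). The study does not report
laboratory-phase or field design variance components, so the generator
uses small plausible defaults (0.001–0.006, relative to residual
variances of about 0.02 per year); they are free parameters of the
generator, fixed once here.

What the simulator does **not** emulate: spatial field trend, linkage
disequilibrium, pedigree or population structure, spectral measurement
error models, or design optimization of plot placement. Passing tests
therefore demonstrate correctness of the estimation machinery under
the model's own assumptions, not robustness to real-data violations of
them.

# Problem sizes used in the test-suite studies

The packaged simulation studies use deliberately chosen sizes:
engine-verification instances are small ($m \le 30$, $p \le 4$, a few
hundred records) so that dense oracles are exact companions;
parameter-recovery and model-selection studies use balanced data at
$m = 300$, $p = 6$ with 700 markers (10 replicate datasets per
scenario), where the eigendecomposition route makes each REML fit a
few seconds; cross-validation studies use $m$ of 150–200 lines and 4
experiments with 3–4 replicates of fivefold masking. The full
two-phase, study-scale configuration (`defaultRunConfig("full")`) runs
the identical code path; it is compute-intensive with the dense route
and is intended for overnight reproduction rather than routine checks,
which is why the default pipeline preset is the small configuration.

# Design decisions on points the analysis leaves open

* **Duplicated markers** are columns whose complete dosage vector
  (including the missing pattern) equals an earlier column's; the first
  occurrence is kept. A minor allele frequency *exactly* at the
  threshold is retained ("less than" is exclusive).
* **Imputation** is marker-mean dosage imputation. The downstream model
  consumes markers only through $K$, for which mean imputation is the
  centering-consistent simple choice; haplotype-based imputation would
  change $K$ only marginally at these marker densities.
* **GRM scaling**: centered cross-products over
  $c = \sum_j 2q_j(1-q_j)$, then rescaled so the mean diagonal is
  exactly 1. This makes the additive and residual genetic components
  commensurable, which in turn justifies defining the *total* genetic
  covariance between environments as $G_a + G_{\bar a}$ for Figure-style
  correlation summaries.
* **Clustering linkage** is average linkage on $1 - r$ by default
  (complete and single linkage are available); clustering uses the
  total-genetic correlations by default.
* **Cluster-level variances** average the strictly off-diagonal
  pairwise covariances among member experiments (a switch includes the
  diagonal); a singleton cluster falls back to its own variance with a
  warning. Cluster-level APPEVs use the PEV of the cluster-mean BLUPs,
  so cluster heritabilities are internally consistent with the
  cluster-mean genetic values.
* **Heritabilities outside [0, 1]** are reported raw with a warning and
  a clipped value attached, never silently truncated; undefined cases
  (nonpositive averaged variances) are `NA`.
* **Cross-validation masking** removes *all* phenotype records of
  validation lines; variance parameters are re-estimated in every fold;
  correlations are Pearson; per-replicate values are fold averages and
  reported standard deviations are taken over the replicate means.
  Cluster-level and overall GEBVs/GVs are unweighted means over member
  experiments.
* **Design-variance grouping** defaults to one variance per design
  factor; per-experiment (field) and per-year (laboratory) variance
  grouping is available as `varianceGrouping = "scope"`. The single
  grouping keeps the optimization dimension modest at package-demo
  sizes without changing the model family.
* **LRT reference distribution** is the plain chi-square on the
  parameter-count difference, with no boundary mixture correction —
  matching common practice in model-ladder tables, and anti-conservative
  for variance parameters on the boundary (stated, not hidden).

# Known limitations

* The dense route scales as $O(n^3)$ per iteration; full-scale
  two-phase datasets (about 7,000 records) are hours, not minutes.
* Spatial autoregressive residual structures, epistatic or dominance
  kernels, factor-analytic orders above $p - 1$, and Bayesian
  marker-effect models are out of scope.
* Prediction into entirely unobserved environments is not modeled;
  `runCV(holdoutEnvironment = ...)` can mask one environment's records
  during training as a crude scenario, but the held-out environment then
  has no estimable loadings and no GEBVs of its own — only other
  environments' GEBVs predicting its full-data GVs. Predictive
  abilities for untested lines within tested environments are
  upward-biased relative to that harder task.
* PEV blocks (hence heritabilities) are computed over phenotyped lines.
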