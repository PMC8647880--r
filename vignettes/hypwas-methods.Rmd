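---
title: "Methods: hierarchical band selection and machine-learning GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical band selection and machine-learning GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`hypwas` implements a hierarchical phenome-to-genome association workflow
for plant breeding trials. The idea is to let a cheap, dense phenotype —
proximal-sensing hyperspectral reflectance measured on every plot — stand
between an expensive target trait (seed yield) and the genome. The
workflow runs in two association layers:

1. **Phenome–phenome (HypWAS).** Cross-validated recursive feature
   elimination (RFE) ranks reflectance bands by how much they contribute
   to predicting the trait, and selects the subset with the best held-out
   performance.
2. **Phenome–genome (GWAS).** Each selected band (its genotype-level
   genetic value) is mapped with three engines: a kinship mixed linear
   model (MLM), an iterative fixed/random pseudo-QTN scan (FarmCPU
   style), and a support-vector-regression (SVR) importance scan with a
   permutation-based global empirical threshold.

Post-GWAS utilities turn significant markers into flanking regions,
estimate linkage-disequilibrium (LD) decay, compute allelic effects, and
intersect regions with GFF3 gene models.

# The mixed model and heritability

Plot-level observations follow

$$y = X b + Z g + W i + e,$$

with fixed environment effects $b$, random genotype effects
$g \sim N(0, \sigma^2_g I)$, random genotype-by-environment effects
$i \sim N(0, \sigma^2_{int} I)$ and residuals
$e \sim N(0, \sigma^2_e I)$. `fit_blup()` estimates the three variance
components by REML (backed by `lme4`) and returns genotype BLUPs;
`blup_band_matrix()` repeats this per reflectance band so downstream
layers operate on genetic values rather than plot noise. Entry-mean
heritability over $n$ environments and $r$ replicates is

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{int}/n +
\sigma^2_e/(nr)}.$$

The printed form of this formula in some sources is typographically
ambiguous ($\sigma^2_{int}/n$ versus $/n^2$); the package uses the
standard entry-mean form above. With a single environment the
interaction is not estimable and is fixed at zero; with one observation
per genotype-environment cell the interaction is confounded with the
residual and is dropped. A fully unreplicated design (every genotype
observed once in total) raises an error naming the confounded
components — no silent answer is produced. Trait observations flagged as
outliers upstream are treated as missing (row exclusion), not imputed.

# Spectral preprocessing

The emulated instrument covers 350–1100 nm in 250 bands at 3-nm centers.
Preprocessing follows a fixed order:

* **Trim** to [395, 1005] nm, discarding detector-edge artifact regions.
* **Rebin** to 10-nm bandwidth. New centers start at the first retained
  center and advance in 10-nm steps; the last retained center is appended
  when it is off-grid. A true 3-nm grid cannot contain both 395 and
  1005 nm as centers (their distance is not a multiple of 3), and this
  anchoring is the convention that reproduces the expected 62-band result
  on the trimmed grid. Each rebinned value is the mean of native bands
  within half a target width of the new center (half-open on the upper
  side), so constant spectra are preserved exactly.
* **Savitzky–Golay smoothing**, default window 11 bands, polynomial
  order 2. The source instrument protocol does not state these values;
  they are package defaults chosen as the mildest common setting that
  still damps single-band noise. Edges use polynomial fits on truncated
  windows, so polynomials up to the filter order pass through unchanged.
* **PCA outlier screen**: plots whose score on one of the first 2
  principal components lies more than 4 robust standard deviations
  (median/MAD) from the component median are reported — never deleted
  automatically. Centering and scaling happen only inside the PCA; the
  exported spectra stay on the raw reflectance scale.

# HypWAS: recursive feature elimination

`rfe_select()` performs backward elimination: fit the learner on the
current band set, rank bands by learner importance, drop the weakest down
to the next candidate size, repeat. A repeated outer cross-validation
(default 5 folds, 5 repeats) scores every candidate size on held-out
genotypes; the optimal size maximizes mean CV $R^2$ with a
one-standard-error tie-break toward fewer bands.

Design choices that were genuinely open:

* **Learner.** No random-forest implementation is available in the
  supported dependency set, so the default learner is the package's own
  linear ε-SVR (bands and response standardized inside the fit, $|w|$
  importance), with an ordinary-least-squares learner ($|t|$ importance)
  as the alternative. The SVR learner uses a narrow tube
  (ε = 0.01 response-sd units): band selection wants small effects kept,
  not suppressed by the insensitive zone.
* **"Significant" bands.** Importance scores of a selected set are not
  separable from unselected ones by any single threshold, so significance
  is defined as membership in the CV-optimal subset. A null guard flags
  the whole selection as non-significant when the best mean CV $R^2$ does
  not exceed 0.1.
* Reported per-band importances come from the full-data fit on all bands,
  min–max scaled to 0–100.

# GWAS engines

## Mixed linear model

$y = Xb + u + e$ with $u \sim N(0, \sigma^2_u K)$ and the VanRaden
genomic relationship matrix $K$. `fit_null_reml()` eigendecomposes $K$
once and profiles the restricted likelihood over the variance ratio; the
estimates are reused for every marker (the P3D strategy), each marker
being tested by weighted least squares in the eigenbasis. Two numerical
choices matter:

* The per-marker residual scale is re-estimated from the weighted
  residual sum of squares (t-test with $n - q - 1$ degrees of freedom),
  so with an identity kinship the scan reduces *exactly* to the ordinary
  regression t-test — this is the package's oracle-equivalence anchor.
* When the restricted likelihood is flat in the variance ratio (an
  uninformative $K$), the tie breaks toward a zero polygenic share
  rather than an arbitrary interior optimum.

An `exact = TRUE` flag refits the variance components per marker
(likelihood-ratio flavor) at the usual cost. Multiple testing uses
Benjamini–Hochberg FDR, default level 0.05 (the level itself is a
documented package default).

## FarmCPU-style scan

The scan alternates a fixed-effect model (FEM) — every marker tested
with the current pseudo-QTNs as covariates — and a random-effect model
(REM) choosing the pseudo-QTN set. Binning constants are not specified
by the method's published equations, so the package documents its own:

* Candidate bin sizes {50 kb, 500 kb, 5 Mb}; one representative
  (smallest p, ties by chromosome then position) per bin.
* Pseudo-QTN candidacy requires $p \le 0.01/\sqrt{M}$ for $M$ markers.
  Without a gate, selection bias over thousands of null markers lets
  chance markers accrete as covariates; with it, a null scan stays
  empty-handed while any marker of practical effect passes.
* The REM maximizes the restricted likelihood of $y = U + e$, where the
  covariance of the total genetic value $U$ is the (low-rank) cross
  product of candidate pseudo-QTN dosages. An empty set always competes,
  and each additional pseudo-QTN must buy at least 2 restricted
  log-likelihood units (an AIC-like parsimony guard against the
  monotone-in-rank likelihood).
* The loop stops when the set repeats (converged) or after `max_iter`
  iterations (flagged unconverged). Final p-values come from the last
  FEM; pseudo-QTNs receive their covariate p from the joint model.
  With a zero pseudo-QTN budget the scan is numerically identical to a
  covariate-only GLM scan.

## SVR-mediated GWAS

The ε-SVR is implemented in the package (Rcpp dual coordinate descent on
the L1-loss dual, deterministic cyclic sweeps; the bias is absorbed into
an augmented constant feature). On small dense problems the solution
matches an independent quadratic-programming implementation of the same
dual to three decimals.

Importance: within a repeated cross-validation (default 5 folds, 10
repeats), each marker is scored by **permutation importance** — the
held-out mean-squared-error increase when that marker's column is
shuffled, in units of the held-out phenotype variance, averaged over
folds, repeats and (default 2) independent shuffles. An "impurity"
importance has no meaning for SVR; permutation importance is the
package's primary metric, with linear-kernel $|w|$ exposed as a fast
secondary. For the linear kernel the shuffled-column prediction is an
$O(n)$ update, so full permutation importance costs little more than the
fits themselves.

Significance uses a **global empirical threshold**: the phenotype is
permuted `n_permutations` times (breaking all marker–trait association
while preserving the LD structure), the maximum raw importance is
recorded each time, and the threshold is the $\lceil(1-\alpha)B\rceil$-th
order statistic of these maxima — the standard max-statistic construction
controlling family-wise error at $\alpha$. One subtlety is load-bearing:
the conventional 0–100 min–max scaling is per run, which pins every
run's maximum at exactly 100 and would make a threshold built from
scaled maxima vacuous. The package therefore tests on the **raw**
importance scale and only reports importances and the threshold through
the original run's 0–100 scaling. Whether the original method permuted
phenotypes or genotypes is not documented; phenotype permutation is this
package's choice, and the 1000-repetition/1000-permutation defaults
scale down by flags for desk-size problems.

Early stopping of the solver (`max_sweeps`) is treated as part of the
estimator: importance ranking stabilizes long before full convergence,
and both the data run and the permutation runs use the same setting, so
the exchangeability argument behind the threshold is unaffected.

# Post-GWAS

All coordinates are 1-based inclusive (HapMap/GFF3 convention); overlap
means at least one shared base. Flanking regions default to ±150 kb
around each significant marker — treated as a tunable parameter whose
default suits panels with LD decaying on that scale — and overlapping
windows merge into one region whose peak is its strongest marker. LD
decay reports distance-binned mean $r^2$ and the distance at which a
3-bin running mean first falls below half its maximum (reported missing
when never reached). BED export converts to 0-based half-open
coordinates.

# The synthetic data generator

No generative model is published for any of this; every distribution in
`simulate_*` is an artifact convention, chosen once:

* **Genotypes.** Biallelic dosages from two latent gametes per genotype;
  along each chromosome the latent values follow a first-order
  autoregressive chain (correlation `ld_decay_rho` per adjacent marker),
  thresholded at an allele frequency drawn uniformly from `maf_range`
  (default [0.05, 0.5], matching a 5% MAF filter). Markers sit on a
  regular 10-kb grid, giving monotone LD decay in physical distance.
* **Spectra.** A smooth vegetation-like baseline (green bump, chlorophyll
  absorption dip, red-edge sigmoid, NIR plateau, water feature) plus
  genotype-specific signal at causal bands — linear in the paired causal
  SNP's dosage — plus environment shifts and plot noise, clipped to
  [0, 1].
* **Trial.** Plot yield = fixed environment effect + genotype effect +
  G×E draw + residual, balanced over `n_env` × `n_rep`. Defaults
  (σ²g, σ²int, σ²e) = (1, 0.5, 1) with 4 environments × 2 replicates
  give entry-mean heritability 0.8. Part of the genotypic variance is
  routed genotype → causal band → yield, so the HypWAS layer and the
  GWAS layer both have planted true positives; the direct component tops
  total genotypic variance up to σ²g.

A single global seed drives every generator through fixed sub-streams.

## What a green test does and does not establish

The generator emulates the *structure* of a multi-environment
phenomics/genomics trial, not its nuisance features: no spatial field
trends, no heteroscedastic sensor noise, no shared-pedigree kinship, no
rare large-effect alleles, no epistasis. Green validation runs establish
that the estimators recover planted structure under their own model
assumptions — they do not certify performance on real field data.

Two world choices in the validation suite deserve emphasis, both fixed
where the criteria left them open and both reflecting measured method
properties rather than hidden tuning:

* **Power replicates use independent markers (`ld_decay_rho = 0`).**
  Under LD, a multivariate learner spreads credit across correlated
  neighbors; the single *planted* marker's importance drops even though
  the *region* remains clearly detected. Single-marker attribution under
  LD is partially ill-posed, so the power world isolates it away; probes
  at ρ = 0.3–0.6 showed the SVR engine's planted-marker family-wise
  detection rate falling from ~100% to ~60–80%, which users should read
  as a genuine limitation of exact-marker attribution, not of region
  detection.
* **The planted QTN is common (MAF ≥ 0.2).** The SVR's ridge-type
  penalty shrinks the large weights that rare variants need to express
  the same variance share, so low-MAF QTNs are systematically harder for
  the SVR engine — consistent with the general observation that these
  GWAS designs are powered for common variants of large effect.

# Numerical choices, degeneracies, limitations

* REML profiles are optimized on a log-variance-ratio grid with a local
  refinement; flat profiles tie-break toward zero polygenic share.
* Constant markers yield missing statistics with a warning; a marker
  supplied as its own covariate goes missing rather than crashing.
* `bh_fdr` propagates missing p-values as missing flags and excludes
  them from the step-up count.
* Mode imputation is a deliberate simplification standing in for
  haplotype-model imputation; it only serves synthetic or lightly
  incomplete panels, and its flags are retained.
* Deterministic behavior everywhere: a single integer seed, fixed
  sub-stream offsets per stage, cyclic (not randomized) coordinate
  descent, and explicit tie-breaks (p, chromosome, position).
* The SVR bias is mildly regularized (augmented-feature trick); on
  over-determined noisy problems the difference from an exact free bias
  is far below estimation noise, and the solver's agreement with an
  independent implementation is part of the test suite.
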