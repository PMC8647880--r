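# hypwas

Hierarchical phenome-to-genome association for plant breeding trials:
hyperspectral band selection (HypWAS) feeding three GWAS engines, with a
synthetic-data module that makes the whole pipeline testable end to end.

## Who this is for

Breeders and quantitative geneticists who measure a dense, cheap phenotype
— plot-level hyperspectral reflectance from proximal sensing — alongside an
expensive target trait (seed yield), and want to know (1) which reflectance
bands carry yield information and (2) which genomic regions drive those
bands. The package implements the full chain on delimited text, HapMap and
VCF inputs.

## The methods at its core

**Mixed model / heritability.** Plot values follow
`y = Xb + Zg + Wi + e` with fixed environments, random genotypes
(`g ~ N(0, σ²g)`), random G×E (`σ²int`) and residual (`σ²e`); REML variance
components and genotype BLUPs come from `fit_blup()`, and entry-mean
heritability is `H² = σ²g / (σ²g + σ²int/n + σ²e/(nr))`.

**HypWAS.** `rfe_select()` runs cross-validated recursive feature
elimination of reflectance bands against the trait, reports per-band
importance on a 0–100 scale and the CV-optimal band subset.

**GWAS engines.** For each selected band's genetic values:

* `mlm_scan()` — kinship mixed linear model `y = Xb + marker + u + e`,
  `u ~ N(0, σ²u K)` with VanRaden `K`, spectral REML fitted once (P3D) and
  per-marker GLS t-tests; Benjamini–Hochberg FDR.
* `farmcpu_scan()` — iterative fixed/random scan: every marker tested with
  pseudo-QTN covariates, pseudo-QTNs re-selected per iteration by a
  restricted-likelihood criterion over genomic bins.
* `svr_gwas()` — the machine-learning engine: ε-SVR of the phenotype on all
  markers (in-package Rcpp dual coordinate-descent solver), per-marker
  permutation importance scaled 0–100, and a *global empirical threshold* —
  the (1−α) order statistic of max-importance over phenotype permutations —
  controlling family-wise error at α = 0.05.

**Post-GWAS.** `bh_fdr()`, ±150-kb flanking regions with merging
(`extract_regions()`), LD decay with half-maximum summary (`ld_decay()`),
allelic effects, and GFF3 gene overlap (`overlap_genes()`).

## Worked example

```r
library(hypwas)

# a synthetic trial with known truth: 200 genotypes x 4 environments x
# 2 replicates, 250-band spectra, 1000 SNPs, 3 planted SNP->band->yield routes
sim <- simulate_dataset(sim_config(seed = 1))

# preprocess spectra: trim to 395-1005 nm, rebin to 10 nm, smooth, screen
pre <- preprocess_spectra(sim$spectra)
pre$spectra
#> spectra_matrix: 1600 plots x 62 bands (395-1004 nm, width 10 nm)

# genotype-level mixed model for the trait
fit <- fit_blup(sim$plots)
fit
#> blup_result for 'yield': 200 genotypes, 4 environments
#>   var_g=0.9907  var_int=0.4793  var_e=1.007  H2(entry-mean)=0.801

# kinship mixed-model scan of the trait BLUPs
res <- mlm_scan(fit$blup, sim$genotypes)
res
#> gwas_result [mlm]: 1000 markers, 1 significant (fdr 0.05 = 2.795585e-07)
head(res[order(res$p), c("marker", "chrom", "pos", "p", "fdr_q")], 3)
#>       marker chrom     pos            p     fdr_q
#> 400 snp00400  Chr4 1000000 2.796e-07 0.0002796
#> 700 snp00700  Chr7 1000000 8.184e-04 0.3765069
#> 243 snp00243  Chr3 4.3e+05 1.500e-03 0.3765069
```

The variance components land on the simulated truth (1, 0.5, 1; entry-mean
heritability 0.8), and the two strongest markers are planted causal SNPs
(`sim$truth$causal_snps` is `100, 400, 700`). Only one clears the
genome-wide FDR cutoff: each planted route carries under a tenth of the
genotypic variance, and the kinship term absorbs part of it — exactly the
conservatism the mixed model is chosen for. The power suite in
`tests/testthat/test-acceptance.R` quantifies detection rates under a
single 20%-variance QTN instead.

The full pipeline — preprocess → BLUP → HypWAS → GWAS on selected bands →
regions/genes — runs from one config:

```r
run_pipeline(list(simulate = TRUE, engines = c("mlm", "svr"),
                  out_dir = "run1", seed = 1))
```

or from the command line via `inst/cli/hypwas-pipeline run --config cfg.yaml`.

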