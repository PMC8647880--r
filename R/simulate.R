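#' Simulation configuration
#'
#' Describes the synthetic world used to validate the pipeline end to end: a
#' biallelic SNP panel with positional linkage disequilibrium, plot-level
#' hyperspectral reflectance spectra, and a balanced multi-environment RCBD
#' yield trial. Genetic signal is routed genotype -> causal band -> yield for
#' part of the genotypic variance, so both the band-selection layer and the
#' GWAS layer have planted true positives; the remaining genotypic variance is
#' direct. Defaults emulate a soybean-scale trial: a 250-band 350-1100 nm grid
#' at 3-nm centers, four environments with two replicates, and variance
#' components (var_g, var_int, var_e) = (1, 0.5, 1), giving entry-mean
#' heritability 0.8.
#'
#' @param n_genotypes number of genotypes.
#' @param n_markers total SNP count, split evenly across chromosomes.
#' @param n_chromosomes chromosome count.
#' @param ld_decay_rho first-order autoregressive correlation between adjacent
#'   markers on the latent gamete scale, in `[0, 1)`.
#' @param maf_range minor-allele-frequency sampling range, within `(0, 0.5]`.
#' @param marker_step_bp physical spacing between adjacent markers (bp).
#' @param causal_snps integer vector of causal marker indices. Paired
#'   elementwise (recycled) with `causal_bands`.
#' @param snp_band_effect reflectance change per alternative allele at the
#'   paired causal band (reflectance units).
#' @param causal_bands integer vector of causal band indices into `band_grid`.
#' @param band_trait_effect trait change per unit reflectance at each causal
#'   band (trait units per reflectance unit).
#' @param band_grid strictly increasing wavelength centers in nm.
#' @param spectra_noise_sd plot-level reflectance noise standard deviation.
#' @param spectra_env_sd environment-level additive reflectance shift sd.
#' @param var_g,var_int,var_e genotype, genotype-by-environment and residual
#'   variance components of the yield model (trait units squared).
#' @param n_env,n_rep environments and replicates per environment.
#' @param seed integer seed governing all draws through fixed sub-streams.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 200L,
                       n_markers = 1000L,
                       n_chromosomes = 10L,
                       ld_decay_rho = 0.6,
                       maf_range = c(0.05, 0.5),
                       marker_step_bp = 10000L,
                       causal_snps = NULL,
                       snp_band_effect = 0.05,
                       causal_bands = NULL,
                       band_trait_effect = 10,
                       band_grid = seq(350, by = 3, length.out = 250),
                       spectra_noise_sd = 0.01,
                       spectra_env_sd = 0.005,
                       var_g = 1, var_int = 0.5, var_e = 1,
                       n_env = 4L, n_rep = 2L,
                       seed = 1L) {
  # default planted architecture: three SNP->band->trait routes spread over
  # the genome (10%, 40%, 70% marks) and over the visible / red-edge / NIR
  # spectral regions
  if (is.null(causal_snps))
    causal_snps <- pmax(1L, as.integer(round(n_markers * c(0.1, 0.4, 0.7))))
  if (is.null(causal_bands))
    causal_bands <- pmax(1L, as.integer(round(length(band_grid) *
                                                c(0.06, 0.27, 0.63))))
  cfg <- list(
    n_genotypes = as.integer(n_genotypes), n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes), ld_decay_rho = ld_decay_rho,
    maf_range = maf_range, marker_step_bp = as.integer(marker_step_bp),
    causal_snps = as.integer(causal_snps),
    snp_band_effect = rep_len(snp_band_effect, length(causal_snps)),
    causal_bands = as.integer(causal_bands),
    band_trait_effect = rep_len(band_trait_effect, length(causal_bands)),
    band_grid = band_grid,
    spectra_noise_sd = spectra_noise_sd, spectra_env_sd = spectra_env_sd,
    var_g = var_g, var_int = var_int, var_e = var_e,
    n_env = as.integer(n_env), n_rep = as.integer(n_rep),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop_config("maf_range must lie within (0, 0.5] with min <= max")
  if (cfg$ld_decay_rho < 0 || cfg$ld_decay_rho >= 1)
    stop_config("ld_decay_rho must be in [0, 1)")
  if (any(c(cfg$var_g, cfg$var_int, cfg$var_e) < 0))
    stop_config("variance components must be >= 0")
  if (cfg$n_env < 1 || cfg$n_rep < 1)
    stop_config("n_env and n_rep must be >= 1")
  if (is.unsorted(cfg$band_grid, strictly = TRUE))
    stop_config("band_grid must be strictly increasing")
  if (length(cfg$causal_snps) &&
      any(cfg$causal_snps < 1 | cfg$causal_snps > cfg$n_markers))
    stop_config("causal marker index out of range 1..n_markers")
  if (length(cfg$causal_bands) &&
      any(cfg$causal_bands < 1 | cfg$causal_bands > length(cfg$band_grid)))
    stop_config("causal band index out of the band grid")
  invisible(cfg)
}

#' Simulate a biallelic SNP dosage panel with positional LD
#'
#' Dosages in `{0,1,2}` arise from two independent latent gametes per
#' genotype. Along each chromosome the latent values follow a first-order
#' autoregressive chain with correlation `ld_decay_rho` per adjacent-marker
#' step, then are thresholded at the marker's allele frequency, producing
#' monotone LD decay with physical distance. Per-marker allele frequencies are
#' drawn uniformly within `maf_range`.
#'
#' @param cfg a [sim_config()].
#' @return a `genotype_matrix` (see [genotype_matrix()]).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, 11L))
  n <- cfg$n_genotypes
  m <- cfg$n_markers
  per_chr <- rep(m %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- m %% cfg$n_chromosomes
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  freq <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  rho <- cfg$ld_decay_rho
  dosage <- matrix(0L, n, m)
  col0 <- 0L
  for (chr in seq_len(cfg$n_chromosomes)) {
    mc <- per_chr[chr]
    if (mc == 0L) next
    gam <- vector("list", 2)
    for (g in 1:2) {
      z <- matrix(0, n, mc)
      z[, 1] <- rnorm(n)
      if (mc > 1) {
        eps <- matrix(rnorm(n * (mc - 1)), n, mc - 1)
        for (k in 2:mc) z[, k] <- rho * z[, k - 1] + sqrt(1 - rho^2) * eps[, k - 1]
      }
      thr <- qnorm(freq[col0 + seq_len(mc)])
      gam[[g]] <- sweep(z, 2, thr, `<`)
    }
    dosage[, col0 + seq_len(mc)] <- gam[[1]] + gam[[2]]
    col0 <- col0 + mc
  }
  storage.mode(dosage) <- "integer"
  map <- data.frame(
    id = sprintf("snp%05d", seq_len(m)),
    chrom = rep(paste0("Chr", seq_len(cfg$n_chromosomes)), per_chr),
    pos = unlist(lapply(per_chr, function(k) seq_len(k) * cfg$marker_step_bp)),
    ref = "A", alt = "T",
    stringsAsFactors = FALSE)
  genotype_matrix(sprintf("G%04d", seq_len(n)), map, dosage)
}

# Smooth vegetation-like baseline: low visible reflectance with a green bump
# near 550 nm, chlorophyll absorption dip near 670 nm, red-edge sigmoid to a
# NIR plateau, mild water-feature dip near 970 nm.
spectral_baseline <- function(wl) {
  0.05 +
    0.06 * exp(-((wl - 550)^2) / (2 * 40^2)) -
    0.03 * exp(-((wl - 670)^2) / (2 * 25^2)) +
    0.40 / (1 + exp(-(wl - 715) / 15)) -
    0.04 * exp(-((wl - 970)^2) / (2 * 30^2))
}

#' Simulate plot-level hyperspectral reflectance spectra
#'
#' Each plot's spectrum is a smooth vegetation-like baseline plus
#' genotype-specific signal at the causal bands (linear in the paired causal
#' SNP dosage), an environment-level additive shift, and i.i.d. noise; values
#' are clipped to `[0, 1]`. Plots follow the same genotype x environment x
#' replicate layout as [simulate_trial()].
#'
#' @param cfg a [sim_config()].
#' @param G the `genotype_matrix` from [simulate_genotypes()].
#' @return a `spectra_matrix` with one row per plot; plot ids are
#'   `<genotype>_<env>_<rep>`.
#' @export
simulate_spectra <- function(cfg, G) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, 23L))
  wl <- cfg$band_grid
  nb <- length(wl)
  base <- spectral_baseline(wl)
  layout <- plot_layout(cfg)
  npl <- nrow(layout)
  refl <- matrix(rep(base, each = npl), npl, nb)
  ncau <- length(cfg$causal_bands)
  if (ncau) {
    snp_idx <- rep_len(cfg$causal_snps, ncau)
    for (k in seq_len(ncau)) {
      dos <- G$dosage[layout$geno_i, snp_idx[k]]
      refl[, cfg$causal_bands[k]] <-
        refl[, cfg$causal_bands[k]] + cfg$snp_band_effect[k] * dos
    }
  }
  env_shift <- rnorm(cfg$n_env, 0, cfg$spectra_env_sd)
  refl <- refl + env_shift[layout$env_i]
  if (cfg$spectra_noise_sd > 0)
    refl <- refl + matrix(rnorm(npl * nb, 0, cfg$spectra_noise_sd), npl, nb)
  refl <- pmin(pmax(refl, 0), 1)
  spectra_matrix(layout$plot_id, wl, refl, band_width_nm = diff(wl[1:2]))
}

plot_layout <- function(cfg) {
  geno <- sprintf("G%04d", seq_len(cfg$n_genotypes))
  grid <- expand.grid(geno_i = seq_len(cfg$n_genotypes),
                      env_i = seq_len(cfg$n_env),
                      rep_i = seq_len(cfg$n_rep))
  grid$genotype <- geno[grid$geno_i]
  grid$environment <- paste0("Env", grid$env_i)
  grid$replicate <- paste0("Rep", grid$rep_i)
  grid$plot_id <- paste(grid$genotype, grid$environment, grid$replicate, sep = "_")
  grid
}

#' Simulate a balanced multi-environment yield trial
#'
#' The generative model mirrors the analysis model: plot yield = fixed
#' environment effect + random genotype effect + random genotype-by-environment
#' effect + residual. Part of the genotypic variance is mediated through the
#' causal bands (band-to-trait effects applied to the genetic component of the
#' causal band values); the direct genotype effect tops the total genotypic
#' variance up to `var_g`.
#'
#' @param cfg a [sim_config()].
#' @param G the `genotype_matrix` from [simulate_genotypes()].
#' @return a long-format `plot_table` data.frame (genotype, environment,
#'   replicate, trait, value) with attribute `"truth"` (a list: genotype
#'   effects, causal identities and effects, realized entry-mean heritability).
#' @export
simulate_trial <- function(cfg, G) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, 37L))
  n <- cfg$n_genotypes
  ncau <- length(cfg$causal_bands)
  g_med <- numeric(n)
  if (ncau) {
    snp_idx <- rep_len(cfg$causal_snps, ncau)
    for (k in seq_len(ncau)) {
      dos <- G$dosage[, snp_idx[k]]
      g_med <- g_med + cfg$band_trait_effect[k] * cfg$snp_band_effect[k] *
        (dos - mean(dos))
    }
  }
  var_med <- if (n > 1) var(g_med) else 0
  var_direct <- max(0, cfg$var_g - var_med)
  g_dir <- if (cfg$var_g > 0) rnorm(n, 0, sqrt(var_direct)) else numeric(n)
  g <- g_med + g_dir - mean(g_med + g_dir)

  env_eff <- seq_len(cfg$n_env) * 0.5
  int_eff <- matrix(rnorm(n * cfg$n_env, 0, sqrt(cfg$var_int)), n, cfg$n_env)
  layout <- plot_layout(cfg)
  mu <- 4
  y <- mu + env_eff[layout$env_i] + g[layout$geno_i] +
    int_eff[cbind(layout$geno_i, layout$env_i)] +
    rnorm(nrow(layout), 0, sqrt(cfg$var_e))
  tbl <- data.frame(genotype = layout$genotype,
                    environment = layout$environment,
                    replicate = layout$replicate,
                    trait = "yield", value = y,
                    stringsAsFactors = FALSE)
  class(tbl) <- c("plot_table", "data.frame")
  realized_h2 <- {
    vg <- var(g)
    vg / (vg + cfg$var_int / cfg$n_env + cfg$var_e / (cfg$n_env * cfg$n_rep))
  }
  attr(tbl, "truth") <- list(
    genotype_effects = setNames(g, sprintf("G%04d", seq_len(n))),
    causal_snps = cfg$causal_snps, snp_band_effect = cfg$snp_band_effect,
    causal_bands = cfg$causal_bands, band_trait_effect = cfg$band_trait_effect,
    realized_h2 = realized_h2)
  tbl
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_spectra()]
#' and [simulate_trial()] under one configuration.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `genotypes`, `spectra`, `plots`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  G <- simulate_genotypes(cfg)
  S <- simulate_spectra(cfg, G)
  P <- simulate_trial(cfg, G)
  list(genotypes = G, spectra = S, plots = P,
       truth = attr(P, "truth"), config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Plot table and spectra as tab-delimited text, genotypes as HapMap, ground
#' truth as JSON.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plots = file.path(dir, "plots.tsv"),
             spectra = file.path(dir, "spectra.tsv"),
             genotypes = file.path(dir, "genotypes.hmp.txt"),
             truth = file.path(dir, "truth.json"))
  data.table::fwrite(sim$plots, paths[["plots"]], sep = "\t")
  write_spectra(sim$spectra, paths[["spectra"]])
  write_hapmap(sim$genotypes, paths[["genotypes"]])
  truth <- sim$truth
  truth$genotype_effects <- as.list(truth$genotype_effects)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
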