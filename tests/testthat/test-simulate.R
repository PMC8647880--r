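test_that("sim_config validates its invariants", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
  expect_error(sim_config(ld_decay_rho = 1), "ld_decay_rho")
  expect_error(sim_config(var_e = -1), "variance")
  expect_error(sim_config(n_env = 0), "n_env")
  expect_error(sim_config(band_grid = c(400, 350)), "increasing")
  expect_error(sim_config(n_markers = 50, causal_snps = 60L), "out of range")
  expect_error(sim_config(causal_bands = 999L), "band index")
})

test_that("genotype simulation is deterministic and respects dosage codes", {
  cfg <- sim_config(n_genotypes = 40, n_markers = 80, n_chromosomes = 2,
                    seed = 11)
  G1 <- simulate_genotypes(cfg)
  G2 <- simulate_genotypes(cfg)
  expect_identical(G1$dosage, G2$dosage)
  expect_true(all(G1$dosage %in% 0:2))
  expect_equal(dim(G1$dosage), c(40, 80))
  maf <- pmin(colMeans(G1$dosage) / 2, 1 - colMeans(G1$dosage) / 2)
  expect_true(all(maf <= 0.5))
})

test_that("adjacent-marker LD increases with ld_decay_rho", {
  adj_r2 <- function(rho) {
    G <- simulate_genotypes(sim_config(n_genotypes = 400, n_markers = 200,
                                       n_chromosomes = 2, ld_decay_rho = rho,
                                       seed = 9))
    ks <- setdiff(seq_len(199), 100)  # skip the chromosome boundary
    mean(vapply(ks, function(k) {
      suppressWarnings(cor(G$dosage[, k], G$dosage[, k + 1]))^2
    }, 0), na.rm = TRUE)
  }
  r2_0 <- adj_r2(0)
  r2_hi <- adj_r2(0.95)
  # background level of independent markers is ~1/n
  expect_lt(r2_0, 0.02)
  expect_gt(r2_hi, r2_0 * 10)
})

test_that("spectra carry the planted SNP-band signal and instrument band count", {
  cfg <- sim_config(n_genotypes = 300, seed = 4)
  G <- simulate_genotypes(cfg)
  S <- simulate_spectra(cfg, G)
  expect_identical(length(S$wavelengths_nm), 250L)
  expect_true(all(S$reflectance >= 0 & S$reflectance <= 1))
  # OLS of a causal band on its paired SNP recovers the planted slope
  lay <- do.call(rbind, strsplit(S$plot_ids, "_", fixed = TRUE))
  gi <- match(lay[, 1], G$samples)
  j <- cfg$causal_bands[1]
  slope <- coef(lm(S$reflectance[, j] ~ G$dosage[gi, cfg$causal_snps[1]]))[2]
  se <- summary(lm(S$reflectance[, j] ~
                     G$dosage[gi, cfg$causal_snps[1]]))$coefficients[2, 2]
  expect_lt(abs(slope - cfg$snp_band_effect[1]), 3 * se)
})

test_that("zero noise and zero genetic effect give the bare baseline", {
  cfg <- sim_config(n_genotypes = 10, n_markers = 30, n_chromosomes = 2,
                    causal_snps = integer(0), causal_bands = integer(0),
                    spectra_noise_sd = 0, spectra_env_sd = 0, seed = 2)
  G <- simulate_genotypes(cfg)
  S <- simulate_spectra(cfg, G)
  expect_equal(max(apply(S$reflectance, 2, function(col) diff(range(col)))), 0)
})

test_that("trial generation is deterministic, balanced, and planted", {
  cfg <- sim_config(n_genotypes = 50, n_markers = 60, n_chromosomes = 2,
                    seed = 13)
  G <- simulate_genotypes(cfg)
  P1 <- simulate_trial(cfg, G)
  P2 <- simulate_trial(cfg, G)
  expect_identical(P1$value, P2$value)
  expect_identical(nrow(P1), 50L * cfg$n_env * cfg$n_rep)
  truth <- attr(P1, "truth")
  expect_true(all(truth$causal_snps <= 60))
  expect_true(truth$realized_h2 > 0 && truth$realized_h2 < 1)
  # OLS of trait on the causal band value recovers the band->trait slope
  S <- simulate_spectra(cfg, G)
  j <- cfg$causal_bands[2]
  fit <- summary(lm(P1$value ~ S$reflectance[, j]))
  expect_lt(abs(fit$coefficients[2, 1] - cfg$band_trait_effect[2]),
            3 * fit$coefficients[2, 2])
})

test_that("no interaction or error variance collapses within-genotype spread", {
  cfg <- sim_config(n_genotypes = 30, n_markers = 40, n_chromosomes = 2,
                    var_int = 0, var_e = 0, seed = 3)
  G <- simulate_genotypes(cfg)
  P <- simulate_trial(cfg, G)
  envm <- tapply(P$value, P$environment, mean)
  dev <- P$value - envm[P$environment]
  wv <- tapply(dev, P$genotype, var)
  expect_lt(max(wv), 1e-20)
})

test_that("realized genotype-effect variance approaches var_g at large n", {
  cfg <- sim_config(n_genotypes = 2000, n_markers = 60, n_chromosomes = 2,
                    seed = 17)
  G <- simulate_genotypes(cfg)
  P <- simulate_trial(cfg, G)
  g <- attr(P, "truth")$genotype_effects
  expect_lt(abs(var(g) - cfg$var_g) / cfg$var_g, 0.1)
})

test_that("datasets round-trip to disk", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  paths <- write_sim_dataset(sim, dir)
  expect_true(all(file.exists(paths)))
  S <- read_spectra(paths[["spectra"]])
  expect_equal(S$wavelengths_nm, sim$spectra$wavelengths_nm)
  expect_equal(unname(S$reflectance), unname(sim$spectra$reflectance),
               tolerance = 1e-6)
  G <- read_hapmap(paths[["genotypes"]])
  expect_identical(G$dosage[sim$genotypes$samples, sim$genotypes$map$id],
                   sim$genotypes$dosage)
  P <- read_plot_table(paths[["plots"]])
  expect_equal(P$value, sim$plots$value, tolerance = 1e-9)
})
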