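test_that("HapMap calls map to alt-allele dosage, IUPAC included", {
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  write_hapmap_fixture(path)
  G <- read_hapmap(path)
  expect_identical(unname(G$dosage[, "m1"]), c(0L, 1L, 2L))
  # W at an A/T site is a heterozygote; N is missing
  expect_identical(unname(G$dosage[, "m2"]), c(1L, NA_integer_, 0L))
  expect_identical(G$map$pos, c(100L, 200L))
})

test_that("duplicated marker ids are rejected", {
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  write_hapmap_fixture(path)
  lines <- readLines(path)
  writeLines(c(lines, sub("^m2", "m1", lines[3])), path)
  expect_error(read_hapmap(path), "duplicated marker")
})

test_that("HapMap write/read round-trips dosages bit-exactly", {
  sim <- small_sim()
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  write_hapmap(sim$genotypes, path)
  G2 <- read_hapmap(path)
  expect_identical(G2$dosage[sim$genotypes$samples, sim$genotypes$map$id],
                   sim$genotypes$dosage)
})

test_that("VCF GT maps to dosage; multiallelic records are skipped", {
  skip_if_not_installed("VariantAnnotation")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path)
  expect_warning(G <- read_vcf(path), "1 multiallelic")
  expect_identical(unname(G$dosage[, "v1"]), c(0L, 1L, 2L))
  expect_identical(unname(G$dosage[, "v2"]), c(NA_integer_, 0L, 2L))
  expect_identical(ncol(G$dosage), 2L)
})

test_that("MAF filtering removes rare and monomorphic markers, idempotently", {
  dos <- cbind(a = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
               b = c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),  # maf 0.05
               c = c(2L, 2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L),  # maf 0.5
               d = c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))  # maf 0.10
  G <- genotype_matrix(paste0("s", 1:10),
                       data.frame(id = colnames(dos), chrom = "Chr1",
                                  pos = 1:4 * 100, ref = "A", alt = "T"),
                       dos)
  # alt frequency 0.04-equivalent (below threshold) and monomorphic go
  f <- filter_maf(G, 0.06)
  expect_identical(f$map$id, c("c", "d"))
  expect_identical(attr(f, "removed"), 2L)
  expect_identical(filter_maf(f, 0.06)$map$id, f$map$id)
  # frequency exactly 0.5 is retained
  expect_true("c" %in% filter_maf(G, 0.5)$map$id)
  expect_error(filter_maf(G, 0.7), "min_maf")
  expect_error(filter_maf(genotype_matrix("s1", G$map[1, ],
                                          matrix(0L, 1, 1)), 0.05),
               "all markers removed")
})

test_that("imputation fills by mode or rounded mean and enforces the cap", {
  dos <- cbind(a = c(0L, 0L, 0L, NA), b = c(2L, NA, NA, NA))
  G <- genotype_matrix(paste0("s", 1:4),
                       data.frame(id = c("a", "b"), chrom = "Chr1",
                                  pos = c(100, 200), ref = "A", alt = "T"),
                       dos)
  expect_error(impute_missing(G, max_missing = 0.5), "b")
  G1 <- genotype_matrix(G$samples, G$map[1, , drop = FALSE],
                        dos[, 1, drop = FALSE])
  expect_identical(unname(impute_missing(G1)$dosage[4, 1]), 0L)
  expect_identical(unname(impute_missing(G1, "mean-round")$dosage[4, 1]), 0L)
  # complete input is the identity
  sim <- small_sim()
  expect_identical(impute_missing(sim$genotypes), sim$genotypes)
})

test_that("VanRaden kinship has the documented algebra", {
  sim <- small_sim()
  G <- sim$genotypes
  K <- kinship_vanraden(G)
  expect_lt(max(abs(K - t(K))), 1e-12)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # marker-order invariance
  perm <- sample(ncol(G$dosage))
  ord <- order(G$map$chrom[perm], G$map$pos[perm])
  G2 <- genotype_matrix(G$samples, G$map[perm, ][ord, ],
                        G$dosage[, perm][, ord])
  expect_equal(kinship_vanraden(G2), K, tolerance = 1e-12)
  # duplicated sample: off-diagonal equals the diagonal
  dup <- genotype_matrix(c(G$samples, "dup"), G$map,
                         rbind(G$dosage, G$dosage[1, ]))
  Kd <- kinship_vanraden(dup)
  expect_equal(Kd["G0001", "dup"], Kd["dup", "dup"], tolerance = 1e-12)
})

test_that("kinship off-diagonals vanish for unrelated samples", {
  G <- simulate_genotypes(sim_config(n_genotypes = 100, n_markers = 5000,
                                     n_chromosomes = 10, ld_decay_rho = 0,
                                     seed = 77))
  K <- kinship_vanraden(G)
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.02)
})

test_that("structure PCs separate diverged subpopulations", {
  set.seed(88)
  p1 <- runif(300, 0.2, 0.8)
  p2 <- pmin(pmax(p1 + sample(c(-0.3, 0.3), 300, TRUE), 0.05), 0.95)
  d1 <- sapply(p1, function(p) rbinom(60, 2, p))
  d2 <- sapply(p2, function(p) rbinom(60, 2, p))
  G <- genotype_matrix(paste0("s", 1:120),
                       data.frame(id = paste0("m", 1:300), chrom = "Chr1",
                                  pos = 1:300 * 1000, ref = "A", alt = "T"),
                       rbind(d1, d2))
  pcs <- structure_pcs(G, 2)
  a <- pcs[1:60, 1]; b <- pcs[61:120, 1]
  expect_true(max(a) < min(b) || min(a) > max(b))
  expect_lt(abs(sum(pcs[, 1] * pcs[, 2])), 1e-8)
  expect_identical(ncol(structure_pcs(G, 0)), 0L)
  expect_error(structure_pcs(G, 120), "k must be")
})

test_that("hapmap accounting reports counts per chromosome", {
  sim <- small_sim()
  s <- summarize_hapmap(sim$genotypes)
  expect_identical(s$n_markers, 120L)
  expect_identical(s$n_samples, 60L)
  expect_identical(sum(s$per_chrom), 120L)
  expect_identical(s$mean_per_chrom, 40)
})
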