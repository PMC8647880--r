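test_that("BH step-up matches hand arithmetic and p.adjust", {
  r <- bh_fdr(c(0.001, 0.02, 0.9), 0.05)
  expect_identical(r$significant, c(TRUE, TRUE, FALSE))
  expect_equal(r$p_cutoff, 0.02)
  expect_equal(r$q, p.adjust(c(0.001, 0.02, 0.9), "BH"))
  expect_false(any(bh_fdr(rep(1, 5), 0.05)$significant))
  expect_true(all(bh_fdr(rep(1e-10, 5), 0.05)$significant))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  # NA handling and monotone flags
  set.seed(1)
  p <- c(runif(50), NA)
  r2 <- bh_fdr(p, 0.2)
  expect_true(is.na(r2$significant[51]))
  sig_p <- p[which(r2$significant)]
  non_p <- p[which(!r2$significant)]
  if (length(sig_p) && length(non_p)) expect_lt(max(sig_p), min(non_p))
  expect_equal(r2$q[-51], p.adjust(p[-51], "BH"))
})

test_that("flanking regions follow the 150-kb convention with clipping", {
  fr <- flanking_region("Chr2", 858458, 150000, peak_id = "Chr2_858458")
  expect_identical(c(fr$start, fr$end), c(708458, 1008458))
  fr2 <- flanking_region("Chr1", 100000, 150000)
  expect_identical(c(fr2$start, fr2$end), c(1, 250000))
  fr3 <- flanking_region("Chr1", 500, 0)
  expect_identical(c(fr3$start, fr3$end), c(500, 500))
  expect_identical(fr3$end - fr3$start + 1, 1)
  fr4 <- flanking_region("Chr1", 900, 150000,
                         chrom_lengths = c(Chr1 = 1000))
  expect_identical(fr4$end, 1000)
  expect_error(flanking_region("ChrX", 1, 10, chrom_lengths = c(Chr1 = 10)),
               "unknown chromosome")
  expect_error(flanking_region("Chr1", 1, -5), "window")
  # unclipped width is 2 * window + 1
  fr5 <- flanking_region("Chr1", 1e6, 150000)
  expect_identical(fr5$end - fr5$start + 1, 300001)
})

test_that("significant markers merge into peak-labelled regions", {
  map <- data.frame(id = paste0("m", 1:4), chrom = c("Chr1", "Chr1", "Chr1", "Chr2"),
                    pos = c(100000, 150000, 900000, 500000))
  stats <- data.frame(effect = 1, se = 1, stat = 1,
                      p = c(1e-8, 1e-6, 1e-7, 0.5),
                      significant = c(TRUE, TRUE, TRUE, FALSE))
  res <- gwas_result(map, stats, "mlm",
                     list(type = "fdr", level = 0.05, value = 1e-5))
  reg <- extract_regions(res, window_bp = 150000)
  expect_identical(nrow(reg), 2L)
  # overlapping windows of m1 and m2 merged; peak is the smaller p (m1)
  expect_identical(reg$peak_id[1], "m1")
  expect_identical(reg$n_markers[1], 2L)
  expect_equal(c(reg$start[1], reg$end[1]), c(1, 300000))
  expect_identical(reg$peak_id[2], "m3")
  # nothing significant: zero rows
  stats$significant <- FALSE
  expect_identical(nrow(extract_regions(
    gwas_result(map, stats, "mlm",
                list(type = "fdr", level = 0.05, value = NA)))), 0L)
})

test_that("LD decay summaries behave across LD regimes", {
  half <- function(rho) {
    G <- simulate_genotypes(sim_config(n_genotypes = 200, n_markers = 150,
                                       n_chromosomes = 1, ld_decay_rho = rho,
                                       seed = 41))
    ld_decay(G, max_dist_bp = 5e5, bin_bp = 2e4)$half_decay_bp
  }
  h95 <- half(0.95)
  h50 <- half(0.5)
  expect_gt(h95, h50)
  # independent markers: flat curve, half-max never reached
  G0 <- simulate_genotypes(sim_config(n_genotypes = 200, n_markers = 150,
                                      n_chromosomes = 1, ld_decay_rho = 0,
                                      seed = 42))
  ld0 <- ld_decay(G0, 5e5, 1e5)
  expect_true(is.na(ld0$half_decay_bp))
  expect_lt(diff(range(ld0$bins$mean_r2)) / mean(ld0$bins$mean_r2), 0.5)
  # duplicated marker at distance zero: r2 = 1 in the zero bin
  dos <- cbind(G0$dosage[, 1:5], dupX = G0$dosage[, 3])
  map <- rbind(G0$map[1:5, ],
               transform(G0$map[3, ], id = "dupX"))
  ord <- order(map$pos)
  Gd <- genotype_matrix(G0$samples, map[ord, ], dos[, ord])
  ldd <- ld_decay(Gd, 1e5, 1e4)
  expect_equal(ldd$bins$mean_r2[1], 1)
  # monomorphic markers excluded with a warning
  dos2 <- cbind(G0$dosage[, 1:4], mono = rep(0L, 200))
  map2 <- rbind(G0$map[1:4, ], transform(G0$map[5, ], id = "mono"))
  Gm <- genotype_matrix(G0$samples, map2, dos2)
  expect_warning(ld_decay(Gm, 1e5, 1e4), "monomorphic")
})

test_that("allelic effects are homozygote-class means", {
  G <- genotype_matrix(paste0("s", 1:4),
                       data.frame(id = "m1", chrom = "Chr1", pos = 100,
                                  ref = "A", alt = "T"),
                       matrix(c(0L, 0L, 2L, 2L), 4, 1))
  ae <- allelic_effect(c(1, 1, 3, 3), G, "m1")
  expect_equal(ae$ref_mean, 1)
  expect_equal(ae$alt_mean, 3)
  expect_equal(ae$difference, 2)
  expect_identical(unname(ae$n), c(2L, 0L, 2L))
  # identical phenotype: zero difference
  expect_equal(allelic_effect(rep(2, 4), G, "m1")$difference, 0)
  # empty homozygote class: missing with warning
  G2 <- genotype_matrix(paste0("s", 1:4), G$map,
                        matrix(c(0L, 0L, 1L, 1L), 4, 1))
  expect_warning(ae2 <- allelic_effect(c(1, 2, 3, 4), G2, "m1"), "empty")
  expect_true(is.na(ae2$alt_mean))
  expect_error(allelic_effect(1:4, G, "nope"), "not found")
})

test_that("gene overlap uses the any-overlap inclusive convention", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff_fixture(path)
  genes <- read_gff3(path)
  expect_identical(nrow(genes), 4L)
  region <- data.frame(chrom = "Chr2", start = 708458, end = 1008458,
                       peak_id = "Chr2_858458")
  ov <- overlap_genes(region, genes)
  # GeneA fully inside (10001 bp); GeneB ends at start - 1 (excluded);
  # GeneC straddles the region end (included)
  expect_identical(sort(ov$gene_id), c("GeneA", "GeneC"))
  expect_identical(ov$overlap_bp[ov$gene_id == "GeneA"], 10001)
  expect_identical(ov$overlap_bp[ov$gene_id == "GeneC"], 8459)
  # symmetry of the interval predicate
  ov_sw <- overlap_genes(
    data.frame(chrom = genes$chrom, start = genes$start, end = genes$end),
    data.frame(gene_id = "region", chrom = region$chrom,
               start = region$start, end = region$end))
  expect_identical(nrow(ov_sw), nrow(ov))
  expect_error(
    overlap_genes(data.frame(chrom = "17", start = 1, end = 10),
                  genes),
    "rename")
})
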