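fast_cfg <- function(...) {
  svr_config(repeats = 2L, n_repetitions = 2L, n_permutations = 40L,
             perm_repeats = 1L, ...)
}

test_that("svr_fit matches an independent quadratic-programming oracle", {
  # frozen from scikit-learn SVR(kernel="linear", C=1, epsilon=0.1) on the
  # same 40 x 5 fixture (solver-independent solution of the same dual)
  set.seed(1)
  X <- matrix(rnorm(40 * 5), 40)
  y <- drop(X %*% c(2, -1, 0, 0, 0.5)) + rnorm(40, 0, 0.2)
  f <- svr_fit(X, y, C = 1, epsilon = 0.1, max_sweeps = 5000, tol = 1e-7)
  sk_w <- c(1.9392, -0.9164, 0.0601, 0.0174, 0.5729)
  expect_lt(max(abs(f$w - sk_w)), 5e-3)
  expect_lt(abs(f$b - (-0.0111)), 5e-3)
  expect_gt(cor(predict(f, X), y), 0.99)
  expect_error(svr_fit(X, rep(1, 40)), "constant")
})

test_that("rbf kernel fits a nonlinear response better than linear", {
  set.seed(2)
  x <- matrix(seq(-2, 2, length.out = 60))
  y <- sin(2 * x[, 1]) + rnorm(60, 0, 0.05)
  lin <- svr_fit(x, y, kernel = "linear")
  rbf <- svr_fit(x, y, kernel = "rbf", gamma = 2)
  expect_gt(cor(predict(rbf, x), y), 0.95)
  expect_gt(mean((predict(lin, x) - y)^2), mean((predict(rbf, x) - y)^2))
})

test_that("an exact marker copy of y gets importance 100, strictly maximal", {
  G <- simulate_genotypes(sim_config(n_genotypes = 120, n_markers = 40,
                                     n_chromosomes = 2, ld_decay_rho = 0,
                                     seed = 21))
  j <- 17
  y <- as.numeric(G$dosage[, j])
  imp <- svr_importance(y, G, fast_cfg(seed = 3))
  expect_equal(unname(imp[j]), 100)
  expect_lt(max(imp[-j]), 50)
})

test_that("null phenotypes give unstable top ranks across reseeds", {
  G <- simulate_genotypes(sim_config(n_genotypes = 100, n_markers = 50,
                                     n_chromosomes = 2, ld_decay_rho = 0,
                                     seed = 22))
  tops <- vapply(1:10, function(s) {
    set.seed(400 + s)
    y <- rnorm(100)
    which.max(svr_importance(y, G, svr_config(repeats = 1, seed = s)))
  }, 0L)
  expect_gte(length(unique(tops)), 5)
})

test_that("duplicated causal columns share credit", {
  G <- simulate_genotypes(sim_config(n_genotypes = 120, n_markers = 40,
                                     n_chromosomes = 2, ld_decay_rho = 0,
                                     seed = 23))
  j <- 11
  dos <- cbind(G$dosage, G$dosage[, j])
  map <- rbind(G$map, data.frame(id = "dup", chrom = "Chr2",
                                 pos = max(G$map$pos) + 1e4,
                                 ref = "A", alt = "T"))
  G2 <- genotype_matrix(G$samples, map, dos)
  set.seed(24)
  y <- as.numeric(G$dosage[, j]) + rnorm(120, 0, 0.5)
  imp <- svr_importance(y, G2, svr_config(repeats = 4, seed = 5))
  expect_lt(abs(imp[j] - imp[41]), 10)
})

test_that("weight and permutation importance agree on noise-free top-1", {
  # planted at common markers (the package's documented validation
  # convention) so single-pass estimates are not dominated by fold noise
  agree <- vapply(1:20, function(r) {
    G <- simulate_genotypes(sim_config(n_genotypes = 80, n_markers = 30,
                                       n_chromosomes = 2, ld_decay_rho = 0,
                                       seed = 900 + r))
    maf <- pmin(colMeans(G$dosage) / 2, 1 - colMeans(G$dosage) / 2)
    common <- which(maf >= 0.2)
    j <- common[1 + (r %% length(common))]
    y <- as.numeric(G$dosage[, j])
    ip <- svr_importance(y, G, svr_config(repeats = 2, seed = r))
    iw <- svr_importance(y, G, svr_config(repeats = 2, metric = "weight",
                                          seed = r))
    which.max(ip) == j && which.max(iw) == j
  }, TRUE)
  expect_identical(mean(agree), 1)
})

test_that("importance is invariant to marker column order", {
  G <- simulate_genotypes(sim_config(n_genotypes = 90, n_markers = 30,
                                     n_chromosomes = 1, ld_decay_rho = 0,
                                     seed = 25))
  set.seed(26)
  y <- as.numeric(G$dosage[, 4]) + rnorm(90, 0, 0.3)
  imp <- svr_importance(y, G$dosage, fast_cfg(seed = 6))
  perm <- c(10:1, 11:30)
  imp_p <- svr_importance(y, G$dosage[, perm], fast_cfg(seed = 6))
  expect_equal(as.numeric(imp_p), as.numeric(imp[perm]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("empirical threshold follows the order-statistic convention", {
  G <- simulate_genotypes(sim_config(n_genotypes = 80, n_markers = 30,
                                     n_chromosomes = 2, ld_decay_rho = 0,
                                     seed = 27))
  set.seed(28)
  y <- rnorm(80)
  cfg95 <- fast_cfg(alpha = 0.05, seed = 7)
  th <- empirical_threshold(y, G, cfg95)
  mx <- attr(th, "maxima")
  expect_equal(attr(th, "raw"), sort(mx)[ceiling(0.95 * 40)])
  # alpha near 1: threshold collapses to the minimum of the maxima
  th1 <- empirical_threshold(y, G, fast_cfg(alpha = 0.99, seed = 7))
  expect_equal(attr(th1, "raw"), min(attr(th1, "maxima")))
  # monotone non-increasing in alpha
  th2 <- empirical_threshold(y, G, fast_cfg(alpha = 0.5, seed = 7))
  expect_lte(attr(th1, "raw"), attr(th2, "raw"))
  expect_lte(attr(th2, "raw"), attr(th, "raw"))
  expect_error(empirical_threshold(y, G, fast_cfg(n_permutations = 10L)),
               "n_permutations")
  expect_error(empirical_threshold(y, G,
                                   fast_cfg(alpha = 0.01, seed = 1)),
               "unattainable")
})

test_that("svr_gwas is deterministic and controls family-wise error", {
  G <- simulate_genotypes(sim_config(n_genotypes = 100, n_markers = 60,
                                     n_chromosomes = 2, ld_decay_rho = 0,
                                     seed = 29))
  set.seed(30)
  y <- rnorm(100)
  cfg <- fast_cfg(seed = 8)
  a <- svr_gwas(y, G, cfg)
  b <- svr_gwas(y, G, cfg)
  expect_identical(a$significant, b$significant)
  expect_identical(attr(a, "threshold")$value, attr(b, "threshold")$value)
  expect_s3_class(a, "gwas_result")
  expect_identical(a$engine[1], "svr")
  expect_identical(attr(a, "threshold")$type, "empirical")
  # null family-wise control: few significant markers across 10 null runs
  counts <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    yy <- rnorm(100)
    sum(svr_gwas(yy, G, fast_cfg(seed = 100 + s))$significant)
  }, 0L)
  expect_gte(mean(counts <= 1), 0.9)
})
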