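#' Mixed-linear-model association scan
#'
#' Single-marker kinship mixed model: `y = X b + marker + u + e`,
#' `u ~ N(0, var_u K)`. Variance components are estimated once on the null
#' model ([fit_null_reml()]) and reused for every marker (P3D); each marker
#' is then tested by generalized least squares in the eigenbasis of `K`,
#' with the residual scale re-estimated per marker so the test reduces
#' exactly to the ordinary-regression t-test when `K` is the identity. An
#' optional exact mode refits the variance components per marker.
#'
#' @param y named (or `G`-aligned) complete phenotype vector.
#' @param G a `genotype_matrix` (complete dosages).
#' @param K kinship matrix; computed by [kinship_vanraden()] when NULL.
#' @param X optional covariate matrix (structure covariates etc.).
#' @param fdr_level Benjamini-Hochberg FDR level for the significance flag.
#' @param exact when TRUE, refit REML per marker (slow; likelihood-ratio
#'   style) instead of reusing the null-model components.
#' @param null optional pre-computed [fit_null_reml()] object.
#' @return a `gwas_result` with columns effect, se, stat, p, fdr_q,
#'   significant. Constant markers get NA statistics with a warning.
#' @export
mlm_scan <- function(y, G, K = NULL, X = NULL, fdr_level = 0.05,
                     exact = FALSE, null = NULL) {
  y <- align_phenotype(y, G)
  if (is.null(K)) K <- kinship_vanraden(G)
  if (!is.null(rownames(K))) K <- K[G$samples, G$samples]
  if (is.null(null)) null <- fit_null_reml(y, X, K)
  Xc <- null$X
  w <- 1 / (null$lambda * null$d + 1)
  Gtil <- crossprod(null$U, G$dosage)
  if (exact) {
    stats <- exact_marker_scan(y, Xc, null, G$dosage)
  } else {
    stats <- weighted_marker_scan(null$Uty, null$UtX, Gtil, w)
  }
  const <- apply(G$dosage, 2, function(g) all(g == g[1]))
  if (any(const)) {
    warning(sprintf("%d constant marker(s): p reported missing", sum(const)))
    stats[const, ] <- NA_real_
  }
  fdr <- bh_fdr(stats$p, fdr_level)
  stats$fdr_q <- fdr$q
  stats$significant <- fdr$significant
  gwas_result(G$map, stats, "mlm",
              list(type = "fdr", level = fdr_level,
                   value = fdr$p_cutoff),
              extra = list(null = null[c("var_u", "var_e", "lambda", "logREML")]))
}

align_phenotype <- function(y, G) {
  if (!is.null(names(y))) {
    if (!all(G$samples %in% names(y)))
      stop_config("phenotype names do not cover all samples")
    y <- y[G$samples]
  } else if (length(y) != length(G$samples)) {
    stop_config("phenotype length != sample count")
  }
  if (anyNA(y)) stop_config("phenotype must be complete")
  as.numeric(y)
}

exact_marker_scan <- function(y, X, null, dosage) {
  m <- ncol(dosage)
  out <- data.frame(effect = rep(NA_real_, m), se = NA_real_,
                    stat = NA_real_, p = NA_real_)
  for (j in seq_len(m)) {
    g <- dosage[, j]
    if (all(g == g[1])) next
    Xj <- cbind(X, marker = g)
    Utg <- crossprod(null$U, g)
    ll <- reml_profile(y, Xj, null$d, null$Uty, cbind(null$UtX, Utg))
    opt <- reml_optimize(ll)
    lam <- exp(opt$maximum)
    w <- 1 / (lam * null$d + 1)
    st <- weighted_marker_scan(null$Uty, null$UtX, matrix(Utg), w)
    out[j, ] <- st[1, ]
  }
  out
}

#' Genomic inflation factor
#'
#' Median chi-square statistic implied by the p-values divided by the null
#' median; ~1 for a calibrated scan.
#'
#' @param p numeric vector of p-values.
#' @return lambda_GC.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}
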