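# Iterative fixed/random-effect scan with pseudo-QTN covariates.
#
# FEM: every marker is tested in a fixed-effect model containing the
# covariates and the current pseudo-QTNs. Binning: markers are ranked by p
# within genomic bins and one representative per bin may become a pseudo-QTN.
# REM: the pseudo-QTN set and bin size are chosen by maximizing the
# restricted likelihood of y = U + e where the total genetic value U has
# covariance built from the candidate pseudo-QTN dosages. The loop stops
# when the set repeats or max_iter is reached.

# Low-rank spectral REML profile: K = Ut diag(d) Ut' with rank t << n.
reml_profile_lowrank <- function(y, X, Ut, d) {
  n <- length(y)
  q <- ncol(X)
  yy <- sum(y^2); Xy <- crossprod(X, y); XX <- crossprod(X)
  Uy <- crossprod(Ut, y); UX <- crossprod(Ut, X)
  function(loglam) {
    lam <- exp(loglam)
    cvec <- lam * d / (lam * d + 1)
    XtVX <- XX - crossprod(UX, UX * cvec)
    XtVy <- Xy - crossprod(UX, Uy * cvec)
    ytVy <- yy - sum(cvec * Uy^2)
    beta <- solve(XtVX, XtVy)
    rss <- ytVy - 2 * sum(beta * XtVy) + sum(beta * (XtVX %*% beta))
    sigma2 <- rss / (n - q)
    ldetV <- sum(log(lam * d + 1))
    ldetX <- as.numeric(determinant(XtVX, logarithm = TRUE)$modulus)
    -0.5 * ((n - q) * log(2 * pi * sigma2) + ldetV + ldetX + (n - q))
  }
}

# Restricted log-likelihood of the plain fixed-effect model (t = 0 limit).
reml_loglik_fixed <- function(y, X) {
  n <- length(y); q <- ncol(X)
  r <- qr.resid(qr(X), y)
  sigma2 <- sum(r^2) / (n - q)
  ldetX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  -0.5 * ((n - q) * log(2 * pi * sigma2) + ldetX + (n - q))
}

# FEM scan: OLS t-tests of every marker given covariates (incl. pseudo-QTNs).
fem_scan <- function(y, Xc, dosage) {
  weighted_marker_scan(y, Xc, dosage, rep(1, length(y)))
}

# p-values of the pseudo-QTN columns inside the joint covariate model.
pseudo_qtn_p <- function(y, X, S) {
  colnames(S) <- paste0("s", seq_len(ncol(S)))
  XS <- cbind(X, S)
  fit <- stats::lm(y ~ 0 + XS)
  sm <- stats::summary.lm(fit)$coefficients
  want <- paste0("XS", colnames(S))
  i <- match(want, rownames(sm))
  list(p = sm[i, 4], effect = sm[i, 1], se = sm[i, 2])
}

#' FarmCPU-style iterative GWAS scan
#'
#' Alternates a fixed-effect model testing every marker with the current
#' pseudo-QTNs as covariates, and a random-effect model selecting the
#' pseudo-QTN set: for each candidate bin size, one representative marker
#' (smallest p) per genomic bin is ranked, and the set size and bin size are
#' chosen to maximize the restricted likelihood of the total-genetic-effect
#' model whose covariance is the cross-product of the candidate pseudo-QTN
#' dosages. Ties prefer fewer pseudo-QTNs; an empty set is always a
#' candidate, so null phenotypes stay calibrated. Final p-values come from
#' the last fixed-effect scan; pseudo-QTNs receive their covariate p from
#' the joint model.
#'
#' @param y phenotype (named or aligned to `G$samples`), complete.
#' @param G a `genotype_matrix`, complete dosages.
#' @param X optional covariate matrix.
#' @param bins candidate bin sizes in bp (default 50 kb, 500 kb, 5 Mb).
#' @param max_qtn maximum pseudo-QTN count (default `ceiling(sqrt(n))`);
#'   0 reduces the scan to a plain fixed-effect GLM scan.
#' @param p_gate only markers with current p at or below this enter
#'   pseudo-QTN candidacy (keeps null scans from accreting covariates).
#'   Default `0.01 / sqrt(n_markers)`, which admits well under one chance
#'   marker per scan while passing any marker of practical effect size.
#' @param ll_margin minimum restricted-log-likelihood gain required to
#'   justify each additional pseudo-QTN (parsimony guard, AIC-like).
#' @param max_iter iteration cap.
#' @param fdr_level Benjamini-Hochberg level for the significance flag.
#' @return a `gwas_result` (engine `"farmcpu"`) with attributes
#'   `pseudo_qtns` (final marker ids), `converged`, `iterations`, and
#'   `history` (per-iteration pseudo-QTN sets and chosen bin size).
#' @export
farmcpu_scan <- function(y, G, X = NULL, bins = c(5e4, 5e5, 5e6),
                         max_qtn = NULL, p_gate = NULL, ll_margin = 2,
                         max_iter = 10L, fdr_level = 0.05) {
  y <- align_phenotype(y, G)
  n <- length(y)
  if (anyNA(G$dosage)) stop_config("impute genotypes before scanning")
  if (is.null(max_qtn)) max_qtn <- ceiling(sqrt(n))
  if (is.null(p_gate)) p_gate <- 0.01 / sqrt(ncol(G$dosage))
  Xc <- build_covariates(X, n)
  dos <- G$dosage
  map <- G$map
  m <- ncol(dos)

  S_idx <- integer(0)
  history <- list()
  converged <- FALSE
  iter <- 0L
  stats <- NULL
  repeat {
    iter <- iter + 1L
    Xfem <- if (length(S_idx)) cbind(Xc, dos[, S_idx, drop = FALSE]) else Xc
    stats <- fem_scan(y, Xfem, dos)
    if (length(S_idx)) {
      pq <- pseudo_qtn_p(y, Xc, dos[, S_idx, drop = FALSE])
      stats$p[S_idx] <- pq$p
      stats$effect[S_idx] <- pq$effect
      stats$se[S_idx] <- pq$se
      stats$stat[S_idx] <- pq$effect / pq$se
    }
    if (max_qtn == 0L || iter >= max_iter) break

    sel <- select_pseudo_qtns(stats$p, map, dos, y, Xc, bins, max_qtn,
                              p_gate, ll_margin)
    history[[iter]] <- list(iteration = iter, pseudo_qtns = map$id[sel$idx],
                            bin_bp = sel$bin_bp)
    if (length(sel$idx) == length(S_idx) &&
        setequal(sel$idx, S_idx)) {
      converged <- TRUE
      break
    }
    S_idx <- sel$idx
  }
  if (max_qtn == 0L) converged <- TRUE

  fdr <- bh_fdr(stats$p, fdr_level)
  stats$fdr_q <- fdr$q
  stats$significant <- fdr$significant
  gwas_result(map, stats, "farmcpu",
              list(type = "fdr", level = fdr_level, value = fdr$p_cutoff),
              extra = list(pseudo_qtns = map$id[S_idx], converged = converged,
                           iterations = iter, history = history))
}

# Choose pseudo-QTNs: for each bin size take bin representatives ordered by
# p (ties by chrom, pos) among markers passing the p gate, then pick the
# (bin size, set size) maximizing the low-rank REM restricted likelihood.
# The empty set competes too, and every added pseudo-QTN must buy at least
# ll_margin log-likelihood units, so the selection stays parsimonious and a
# null phenotype keeps an empty set.
select_pseudo_qtns <- function(p, map, dos, y, Xc, bins, max_qtn,
                               p_gate, ll_margin) {
  n <- length(y)
  ll0 <- reml_loglik_fixed(y, Xc)
  best <- list(idx = integer(0), bin_bp = NA_real_, ll = ll0, t = 0L)
  ord_all <- order(p, map$chrom, map$pos, na.last = TRUE)
  for (b in bins) {
    bin_id <- paste(map$chrom, map$pos %/% b)
    seen <- !duplicated(bin_id[ord_all])
    reps <- ord_all[seen]
    reps <- reps[!is.na(p[reps]) & p[reps] <= p_gate]
    tmax <- min(max_qtn, length(reps))
    if (tmax == 0) next
    for (t in seq_len(tmax)) {
      idx <- reps[seq_len(t)]
      S <- dos[, idx, drop = FALSE]
      S <- scale(S, center = TRUE, scale = FALSE)
      sv <- svd(S, nu = min(t, n), nv = 0)
      keep <- sv$d > 1e-8
      if (!any(keep)) next
      Ut <- sv$u[, keep, drop = FALSE]
      d <- sv$d[keep]^2 / t
      ll <- reml_optimize(reml_profile_lowrank(y, Xc, Ut, d))$objective
      if (ll > best$ll + ll_margin * (t - best$t))
        best <- list(idx = idx, bin_bp = b, ll = ll, t = t)
    }
  }
  best
}
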