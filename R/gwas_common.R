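# Shared machinery for the GWAS engines: spectral (EMMA-style) REML for
# y = Xb + u + e with u ~ N(0, var_u * K), and fast per-marker weighted
# least-squares scans via Frisch-Waugh residualization.

# REML log-likelihood profile over lambda = var_u / var_e given the spectrum
# of K. Returns function(log_lambda) -> restricted log-likelihood.
reml_profile <- function(y, X, d, Uty, UtX) {
  n <- length(y)
  q <- ncol(X)
  function(loglam) {
    lam <- exp(loglam)
    v <- lam * d + 1
    w <- 1 / v
    XtVX <- crossprod(UtX, UtX * w)
    XtVy <- crossprod(UtX, Uty * w)
    beta <- solve(XtVX, XtVy)
    r <- Uty - UtX %*% beta
    rss <- sum(w * r^2)
    sigma2 <- rss / (n - q)
    ldetV <- sum(log(v))
    ldetX <- as.numeric(determinant(XtVX, logarithm = TRUE)$modulus)
    -0.5 * ((n - q) * log(2 * pi * sigma2) + ldetV + ldetX + (n - q))
  }
}

# Maximize the REML profile with a flat-likelihood tie-break toward the
# smallest lambda (so an uninformative K, e.g. the identity, yields a
# polygenic ratio near zero instead of an arbitrary interior point).
reml_optimize <- function(ll_fun, lower = -12, upper = 12, tol = 1e-8) {
  grid <- seq(lower, upper, length.out = 61)
  vals <- vapply(grid, ll_fun, 0)
  best <- max(vals)
  i <- which(vals >= best - 1e-6)[1]
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(ll_fun, c(lo, hi), maximum = TRUE, tol = tol)
  if (ll_fun(lo) >= opt$objective - 1e-9) {
    # flat within bracket: prefer the lower end
    list(maximum = lo, objective = ll_fun(lo))
  } else opt
}

#' Fit the polygenic null model by spectral REML
#'
#' Eigendecomposes the kinship matrix once, profiles the restricted
#' likelihood over the polygenic-to-residual variance ratio, and caches the
#' rotated phenotype and covariates so each subsequent marker test is a
#' weighted regression (the population-parameters-previously-determined,
#' P3D, strategy).
#'
#' @param y complete numeric phenotype vector.
#' @param X covariate matrix (an intercept column is added when absent).
#' @param K kinship matrix aligned to `y`.
#' @return an object of class `mlm_null`: list with `var_u`, `var_e`,
#'   `lambda` (ratio), `logREML`, and the spectral cache.
#' @export
fit_null_reml <- function(y, X = NULL, K) {
  n <- length(y)
  if (anyNA(y)) stop_config("phenotype must be complete")
  if (nrow(K) != n) stop_config("K not aligned to y")
  if (max(abs(K - t(K))) > 1e-8) stop_config("K not symmetric")
  X <- build_covariates(X, n)
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values)))
    stop_config("K not positive semidefinite (min eigenvalue %g)",
                min(eig$values))
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  Uty <- crossprod(U, y)
  UtX <- crossprod(U, X)
  ll <- reml_profile(y, X, d, Uty, UtX)
  opt <- reml_optimize(ll)
  lam <- exp(opt$maximum)
  v <- lam * d + 1
  w <- 1 / v
  beta <- solve(crossprod(UtX, UtX * w), crossprod(UtX, Uty * w))
  r <- Uty - UtX %*% beta
  sigma2e <- sum(w * r^2) / (n - ncol(X))
  structure(list(var_u = lam * sigma2e, var_e = sigma2e, lambda = lam,
                 logREML = opt$objective,
                 U = U, d = d, Uty = drop(Uty), UtX = UtX, X = X, n = n),
            class = "mlm_null")
}

build_covariates <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  X <- as.matrix(X)
  if (nrow(X) != n) stop_config("covariates not aligned to phenotype")
  if (!any(apply(X, 2, function(c) all(c == c[1]))))
    X <- cbind(intercept = 1, X)
  X
}

# Weighted per-marker scan: y, covariates and markers already rotated into
# the eigenbasis; weights w. Residualizes y and every marker against the
# covariates under w, then performs a per-marker t-test with the residual
# variance re-estimated per marker (df = n - q - 1). With unit weights this
# is exactly the OLS t-test.
weighted_marker_scan <- function(ytil, Xtil, Gtil, w) {
  n <- length(ytil)
  q <- ncol(Xtil)
  sw <- sqrt(w)
  A <- Xtil * sw
  ys <- ytil * sw
  Gs <- Gtil * sw
  qrA <- qr(A)
  yr <- qr.resid(qrA, ys)
  Gr <- qr.resid(qrA, Gs)
  gg <- colSums(Gr^2)
  gy <- as.vector(crossprod(Gr, yr))
  yy <- sum(yr^2)
  df <- n - q - 1
  beta <- ifelse(gg > 1e-10, gy / gg, NA_real_)
  rss <- yy - beta^2 * gg
  rss[!is.na(rss) & rss < 0] <- 0
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gg)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  data.frame(effect = beta, se = se, stat = tstat, p = p)
}

#' Assemble a GWAS result table
#'
#' One row per tested marker with the engine tag and threshold record shared
#' by all engines.
#'
#' @param map marker map (id, chrom, pos).
#' @param stats data.frame with per-marker columns (effect, se, stat, p or
#'   importance, ...).
#' @param engine one of `"mlm"`, `"farmcpu"`, `"svr"`.
#' @param threshold list with `type` (`"fdr"`, `"bonferroni"`, `"empirical"`),
#'   `level`, `value`.
#' @param extra optional named list carried as attributes.
#' @return a `gwas_result` data.frame.
#' @export
gwas_result <- function(map, stats, engine, threshold, extra = list()) {
  stopifnot(engine %in% c("mlm", "farmcpu", "svr"))
  stopifnot(threshold$type %in% c("fdr", "bonferroni", "empirical"))
  out <- cbind(data.frame(marker = map$id, chrom = map$chrom, pos = map$pos,
                          stringsAsFactors = FALSE),
               stats)
  out$engine <- engine
  attr(out, "threshold") <- threshold
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' @export
print.gwas_result <- function(x, ...) {
  th <- attr(x, "threshold")
  cat(sprintf("gwas_result [%s]: %d markers, %d significant (%s %s = %s)\n",
              x$engine[1], nrow(x), sum(x$significant, na.rm = TRUE),
              th$type, format(th$level), format(th$value)))
  invisible(x)
}

#' Write a GWAS result as TSV
#'
#' @param res a `gwas_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gwas_result <- function(res, path) {
  data.table::fwrite(as.data.frame(res), path, sep = "\t")
  invisible(path)
}
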