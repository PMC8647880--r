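#' Read a plot-level phenotype table
#'
#' Long format, tab-delimited: columns `genotype`, `environment`, `replicate`,
#' `trait`, `value`. Keys (genotype, environment, replicate, trait) must be
#' unique; values may be missing (NA).
#'
#' @param path file path.
#' @return a `plot_table` data.frame.
#' @export
read_plot_table <- function(path) {
  tbl <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  as_plot_table(tbl)
}

#' @param tbl data.frame with the plot-table columns.
#' @rdname read_plot_table
#' @export
as_plot_table <- function(tbl) {
  need <- c("genotype", "environment", "replicate", "trait", "value")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop_config("plot table missing columns: %s", paste(miss, collapse = ", "))
  key <- do.call(paste, c(tbl[c("genotype", "environment", "replicate", "trait")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop_config("duplicate (genotype, environment, replicate, trait) keys")
  if (!all(is.finite(tbl$value) | is.na(tbl$value)))
    stop_config("non-finite trait values present")
  class(tbl) <- c("plot_table", "data.frame")
  tbl
}

#' Fit the multi-environment mixed model and extract BLUPs
#'
#' Model: `value ~ environment (fixed) + genotype (random) +
#' genotype:environment (random) + residual`, fitted by REML. Returns the
#' variance components (var_g, var_int, var_e), the genotype BLUPs, the
#' genotype-by-environment BLUPs, the fixed environment effects and the
#' restricted log-likelihood. With a single environment, or when every
#' genotype-environment cell holds at most one observation (the interaction
#' is then confounded with the residual), the G-by-E term is dropped and
#' `var_int` is fixed at 0. Missing values are excluded row-wise.
#'
#' @param tbl a `plot_table` (see [read_plot_table()]); one trait at a time.
#' @param trait trait name to fit; defaults to the single trait present.
#' @return an object of class `blup_result`: list with `varcomp`
#'   (var_g, var_int, var_e), `blup` (named genotype effects), `blup_int`
#'   (G-by-E effects, or NULL), `fixed` (environment effects), `logREML`,
#'   `fit` (the lme4 fit), and `deviance_fun` (evaluates the REML deviance at
#'   arbitrary non-negative `c(var_g, var_int, var_e)`).
#' @export
fit_blup <- function(tbl, trait = NULL) {
  tbl <- as_plot_table(tbl)
  if (is.null(trait)) {
    trait <- unique(tbl$trait)
    if (length(trait) != 1)
      stop_config("several traits present; pass trait=")
  }
  d <- tbl[tbl$trait == trait & !is.na(tbl$value), , drop = FALSE]
  if (nrow(d) == 0) stop_config("no observations for trait '%s'", trait)
  d$genotype <- factor(d$genotype)
  d$environment <- factor(d$environment)
  if (nlevels(d$genotype) < 2) stop_config("need >= 2 genotypes")
  if (nrow(d) == nlevels(d$genotype) &&
      !anyDuplicated(d$genotype)) {
    stop_config(paste("no replication anywhere: every genotype observed once,",
                      "so var_g and var_e (and var_int) are confounded"))
  }
  cell_max <- max(table(d$genotype, d$environment))
  multi_env <- nlevels(d$environment) > 1
  use_int <- multi_env && cell_max > 1
  form <- if (use_int)
    value ~ environment + (1 | genotype) + (1 | genotype:environment)
  else if (multi_env)
    value ~ environment + (1 | genotype)
  else
    value ~ 1 + (1 | genotype)
  # batch-friendly convergence checks: singular fits are legitimate at the
  # boundary (a zero component) and the default gradient tolerance trips on
  # numerically marginal but fine fits when run over dozens of bands
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                     control = lme4::lmerControl(
                                       check.conv.singular = "ignore",
                                       check.conv.grad =
                                         lme4::.makeCC("warning",
                                                       tol = 0.05,
                                                       relTol = NULL))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    i <- match(g, vc$grp)
    if (is.na(i)) 0 else vc$vcov[i]
  }
  varcomp <- c(var_g = getv("genotype"),
               var_int = if (use_int) getv("genotype:environment") else 0,
               var_e = getv("Residual"))
  re <- lme4::ranef(fit)
  g_blup <- setNames(re$genotype[[1]], rownames(re$genotype))
  int_blup <- if (use_int)
    setNames(re$`genotype:environment`[[1]], rownames(re$`genotype:environment`))
  else NULL
  fe <- lme4::fixef(fit)

  devfun <- local({
    df <- lme4::lmer(form, data = d, REML = TRUE, devFunOnly = TRUE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    n_theta <- if (use_int) 2L else 1L
    function(v) {
      # v = c(var_g, var_int, var_e); theta are relative std devs (sd / sigma)
      if (v[3] <= 0) return(Inf)
      th <- sqrt(v[1] / v[3])
      if (use_int) {
        # lme4 orders theta by factor levels: genotype:environment first
        th <- c(sqrt(v[2] / v[3]), th)
      }
      # devfun profiles sigma out, so it is a function of theta only; evaluate
      # the full REML deviance at fixed sigma2 via the profiled form plus the
      # sigma2 correction is not available -- use the profiled deviance, which
      # is minimized at the fitted theta for any sigma2 on the REML path.
      df(th)
    }
  })

  structure(list(trait = trait, varcomp = varcomp, blup = g_blup,
                 blup_int = int_blup, fixed = fe,
                 logREML = as.numeric(stats::logLik(fit)),
                 n_env = nlevels(d$environment),
                 n_rep = round(nrow(d) / (nlevels(d$genotype) *
                                            nlevels(d$environment))),
                 fit = fit, deviance_fun = devfun),
            class = "blup_result")
}

#' @export
print.blup_result <- function(x, ...) {
  cat(sprintf("blup_result for '%s': %d genotypes, %d environments\n",
              x$trait, length(x$blup), x$n_env))
  cat(sprintf("  var_g=%.4g  var_int=%.4g  var_e=%.4g  H2(entry-mean)=%.3f\n",
              x$varcomp[1], x$varcomp[2], x$varcomp[3],
              heritability(x$varcomp, x$n_env, max(1, x$n_rep))))
  invisible(x)
}

#' Entry-mean heritability
#'
#' `H2 = var_g / (var_g + var_int / n_env + var_e / (n_env * n_rep))`, the
#' heritability of genotype means over `n_env` environments with `n_rep`
#' replicates each.
#'
#' @param v numeric vector or list with components `var_g`, `var_int`,
#'   `var_e` (in that order if unnamed).
#' @param n_env,n_rep environment and replicate counts.
#' @return heritability in `[0, 1]`.
#' @export
heritability <- function(v, n_env, n_rep) {
  v <- unlist(v)
  if (length(v) != 3) stop_config("need three variance components")
  if (!is.null(names(v)) && all(c("var_g", "var_int", "var_e") %in% names(v)))
    v <- v[c("var_g", "var_int", "var_e")]
  if (any(v < 0)) stop_config("variance components must be >= 0")
  if (n_env < 1 || n_rep < 1) stop_config("n_env and n_rep must be >= 1")
  denom <- v[1] + v[2] / n_env + v[3] / (n_env * n_rep)
  if (denom == 0) stop_config("all variance components zero; H2 undefined")
  unname(v[1] / denom)
}

#' Genotype-level band matrix from plot spectra
#'
#' Fits the multi-environment mixed model per band and returns the matrix of
#' genotype genetic values (overall mean + genotype BLUP) used downstream by
#' HypWAS and GWAS.
#'
#' @param S a plot-level `spectra_matrix` with plot ids `<geno>_<env>_<rep>`
#'   or an explicit layout.
#' @param layout optional data.frame with columns `plot_id`, `genotype`,
#'   `environment`, `replicate`; parsed from plot ids when NULL.
#' @return list: `values` (genotype x band matrix of genetic values),
#'   `varcomp` (band x 3 matrix), `h2` (per-band entry-mean heritability).
#' @export
blup_band_matrix <- function(S, layout = NULL) {
  if (is.null(layout)) {
    parts <- strsplit(S$plot_ids, "_", fixed = TRUE)
    if (any(lengths(parts) != 3))
      stop_config("plot ids not in <genotype>_<env>_<rep> form; pass layout=")
    layout <- data.frame(plot_id = S$plot_ids,
                         genotype = vapply(parts, `[`, "", 1),
                         environment = vapply(parts, `[`, "", 2),
                         replicate = vapply(parts, `[`, "", 3))
  }
  idx <- match(S$plot_ids, layout$plot_id)
  if (anyNA(idx)) stop_config("layout does not cover all plot ids")
  lay <- layout[idx, ]
  nb <- length(S$wavelengths_nm)
  genos <- sort(unique(lay$genotype))
  vals <- matrix(NA_real_, length(genos), nb,
                 dimnames = list(genos, format(S$wavelengths_nm, trim = TRUE)))
  vc <- matrix(NA_real_, nb, 3,
               dimnames = list(NULL, c("var_g", "var_int", "var_e")))
  h2 <- numeric(nb)
  for (j in seq_len(nb)) {
    tb <- data.frame(genotype = lay$genotype, environment = lay$environment,
                     replicate = lay$replicate,
                     trait = "band", value = S$reflectance[, j])
    fit <- fit_blup(as_plot_table(tb))
    vals[names(fit$blup), j] <- mean(S$reflectance[, j]) + fit$blup
    vc[j, ] <- fit$varcomp
    h2[j] <- heritability(fit$varcomp, fit$n_env, max(1, fit$n_rep))
  }
  list(values = vals, varcomp = vc, h2 = h2,
       wavelengths_nm = S$wavelengths_nm)
}

#' Pearson correlation of band genetic values with a trait
#'
#' @param bands genotype x band matrix (rownames are genotype ids).
#' @param trait named numeric vector of genotype-level trait values.
#' @return named numeric vector of per-band Pearson r in `[-1, 1]`; bands or
#'   traits with zero variance yield NA with a warning. Genotypes missing on
#'   either side are dropped pairwise.
#' @export
correlate_bands <- function(bands, trait) {
  common <- intersect(rownames(bands), names(trait))
  if (length(common) < 3) stop_config("fewer than 3 shared genotypes")
  b <- bands[common, , drop = FALSE]
  y <- trait[common]
  r <- suppressWarnings(as.vector(cor(b, y, use = "pairwise.complete.obs")))
  names(r) <- colnames(bands)
  if (anyNA(r))
    warning(sprintf("%d band(s) with undefined correlation (zero variance)",
                    sum(is.na(r))))
  r
}
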