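#' Construct a spectra matrix
#'
#' Container for plot-by-band hyperspectral reflectance with its wavelength
#' grid (nm). Reflectance is a unitless fraction.
#'
#' @param plot_ids character vector of plot identifiers.
#' @param wavelengths_nm strictly increasing band centers in nm.
#' @param reflectance numeric matrix, `length(plot_ids)` x
#'   `length(wavelengths_nm)`.
#' @param band_width_nm nominal band width in nm.
#' @return an object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(plot_ids, wavelengths_nm, reflectance,
                           band_width_nm = NA_real_) {
  reflectance <- as.matrix(reflectance)
  if (anyDuplicated(wavelengths_nm))
    stop_config("duplicate wavelengths in grid")
  if (is.unsorted(wavelengths_nm, strictly = TRUE))
    stop_config("wavelengths must be strictly increasing")
  if (ncol(reflectance) != length(wavelengths_nm))
    stop_config("grid length (%d) != value columns (%d)",
                length(wavelengths_nm), ncol(reflectance))
  if (nrow(reflectance) != length(plot_ids))
    stop_config("plot id count != spectra rows")
  if (!all(is.finite(reflectance)))
    stop_config("reflectance must be finite")
  dimnames(reflectance) <- list(plot_ids, format(wavelengths_nm, trim = TRUE))
  structure(list(plot_ids = as.character(plot_ids),
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 reflectance = reflectance,
                 band_width_nm = band_width_nm),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("spectra_matrix: %d plots x %d bands (%.0f-%.0f nm, width %s nm)\n",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$wavelengths_nm), max(x$wavelengths_nm),
              format(x$band_width_nm)))
  invisible(x)
}

#' Read / write tab-delimited spectra
#'
#' File contract: first column is the plot id, remaining columns are named by
#' their wavelength center in nm.
#'
#' @param path file path.
#' @param band_width_nm nominal width recorded on the object (read side);
#'   inferred from the grid spacing when `NA`.
#' @return `read_spectra`: a `spectra_matrix`. `write_spectra`: invisibly,
#'   `path`.
#' @export
read_spectra <- function(path, band_width_nm = NA_real_) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  wl <- suppressWarnings(as.numeric(names(dt)[-1]))
  if (anyNA(wl))
    stop_config("non-numeric wavelength column name in %s", path)
  if (is.na(band_width_nm) && length(wl) > 1)
    band_width_nm <- stats::median(diff(wl))
  spectra_matrix(dt[[1]], wl, as.matrix(dt[-1]), band_width_nm)
}

#' @param S a `spectra_matrix`.
#' @rdname read_spectra
#' @export
write_spectra <- function(S, path) {
  df <- data.frame(plot_id = S$plot_ids, check.names = FALSE)
  m <- as.data.frame(S$reflectance)
  names(m) <- format(S$wavelengths_nm, trim = TRUE)
  data.table::fwrite(cbind(df, m), path, sep = "\t")
  invisible(path)
}

#' Trim a spectra matrix to a wavelength range
#'
#' Retains only bands whose centers fall in `[keep_min_nm, keep_max_nm]`,
#' preserving order. Used to drop detector-edge artifact regions (for the
#' emulated instrument, below 395 and above 1005 nm).
#'
#' @param S a `spectra_matrix`.
#' @param keep_min_nm,keep_max_nm inclusive retention range in nm.
#' @return the trimmed `spectra_matrix`.
#' @export
trim_bands <- function(S, keep_min_nm, keep_max_nm) {
  if (keep_min_nm >= keep_max_nm)
    stop_config("keep_min_nm must be < keep_max_nm")
  keep <- S$wavelengths_nm >= keep_min_nm & S$wavelengths_nm <= keep_max_nm
  if (!any(keep))
    stop_config("no bands remain in [%g, %g] nm", keep_min_nm, keep_max_nm)
  spectra_matrix(S$plot_ids, S$wavelengths_nm[keep],
                 S$reflectance[, keep, drop = FALSE], S$band_width_nm)
}

#' Rebin spectra to a coarser bandwidth
#'
#' New centers are placed at the first retained center plus multiples of
#' `target_width_nm`, with the last retained center appended when it is not
#' already on that step grid (this anchoring is what maps a trimmed 3-nm,
#' 395-1004 nm grid onto exactly 62 bands at 10 nm). Each rebinned value is
#' the mean of native bands whose centers fall within `target_width_nm / 2`
#' of the new center, half-open on the upper side.
#'
#' @param S a `spectra_matrix`.
#' @param target_width_nm new nominal bandwidth; must be at least the native
#'   spacing.
#' @return the rebinned `spectra_matrix`.
#' @export
rebin_bands <- function(S, target_width_nm) {
  wl <- S$wavelengths_nm
  native <- if (length(wl) > 1) stats::median(diff(wl)) else S$band_width_nm
  if (!is.na(native) && target_width_nm < native)
    stop_config("target width %g nm below native spacing %g nm",
                target_width_nm, native)
  centers <- seq(wl[1], wl[length(wl)], by = target_width_nm)
  if (max(centers) < wl[length(wl)]) centers <- c(centers, wl[length(wl)])
  half <- target_width_nm / 2
  vals <- vapply(centers, function(cn) {
    inwin <- wl >= cn - half & wl < cn + half
    if (!any(inwin)) inwin[which.min(abs(wl - cn))] <- TRUE
    rowMeans(S$reflectance[, inwin, drop = FALSE])
  }, numeric(length(S$plot_ids)))
  if (length(S$plot_ids) == 1L) vals <- matrix(vals, nrow = 1L)
  spectra_matrix(S$plot_ids, centers, vals, target_width_nm)
}

# Savitzky-Golay smoothing matrix with truncated-window polynomial fits at the
# edges: row i holds the weights producing the degree-`polyorder` local
# least-squares fit evaluated at band i.
savgol_matrix <- function(n, window, polyorder) {
  h <- (window - 1L) %/% 2L
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    x <- (lo:hi) - i
    A <- outer(x, 0:polyorder, `^`)
    # first row of (A'A)^-1 A' = weights for the fitted value at offset 0
    W[i, lo:hi] <- solve(crossprod(A), t(A))[1, ]
  }
  W
}

#' Savitzky-Golay smoothing of spectra
#'
#' Each spectrum is replaced by its moving local polynomial least-squares fit.
#' Interior bands use the full window; edges fall back to polynomial fits on
#' the truncated window, so exact polynomials of degree `polyorder` or less
#' are reproduced everywhere.
#'
#' @param S a `spectra_matrix`.
#' @param window odd window length in bands.
#' @param polyorder polynomial order, `< window`.
#' @return the smoothed `spectra_matrix`.
#' @export
savgol_smooth <- function(S, window = 11L, polyorder = 2L) {
  nb <- length(S$wavelengths_nm)
  if (window %% 2L == 0L) stop_config("window must be odd")
  if (polyorder >= window) stop_config("polyorder must be < window")
  if (window > nb) stop_config("window (%d) exceeds band count (%d)", window, nb)
  W <- savgol_matrix(nb, as.integer(window), as.integer(polyorder))
  spectra_matrix(S$plot_ids, S$wavelengths_nm,
                 S$reflectance %*% t(W), S$band_width_nm)
}

#' PCA outlier screen for spectra
#'
#' Plots are scored on the first `n_components` principal components of the
#' centered and scaled reflectance matrix; a plot is flagged when any of its
#' scores sits more than `z_threshold` robust standard deviations
#' (median/MAD) from that component's median. Flagged plots are reported,
#' never removed.
#'
#' @param S a `spectra_matrix`.
#' @param n_components number of leading components to screen.
#' @param z_threshold robust z-score cutoff.
#' @return character vector of flagged plot ids (possibly empty).
#' @export
detect_outliers_pca <- function(S, n_components = 2L, z_threshold = 4) {
  X <- S$reflectance
  if (n_components >= min(dim(X)))
    stop_config("n_components must be < min(plots, bands)")
  sds <- apply(X, 2, sd)
  if (all(sds < .Machine$double.eps * 100)) {
    warning("degenerate spectra matrix (all plots identical); no outliers flagged")
    return(character(0))
  }
  keep <- sds > 0
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  flagged <- rep(FALSE, nrow(X))
  for (j in seq_len(k)) {
    s <- pc$x[, j]
    scale_j <- mad(s)
    if (scale_j == 0) next
    flagged <- flagged | abs(s - median(s)) / scale_j > z_threshold
  }
  S$plot_ids[flagged]
}

#' Canonical preprocessing pipeline: trim, rebin, smooth
#'
#' Applies the stages in the fixed order trim -> rebin -> Savitzky-Golay,
#' and runs the PCA outlier screen on the result.
#'
#' @param S a `spectra_matrix`.
#' @param keep_min_nm,keep_max_nm trim range (defaults drop detector-edge
#'   artifact regions below 395 and above 1005 nm).
#' @param target_width_nm rebinned bandwidth (default 10 nm).
#' @param window,polyorder Savitzky-Golay parameters; `window = NULL` skips
#'   smoothing.
#' @param n_components,z_threshold outlier-screen parameters.
#' @return list: `spectra` (processed `spectra_matrix`), `outliers`
#'   (flagged plot ids).
#' @export
preprocess_spectra <- function(S, keep_min_nm = 395, keep_max_nm = 1005,
                               target_width_nm = 10,
                               window = 11L, polyorder = 2L,
                               n_components = 2L, z_threshold = 4) {
  out <- trim_bands(S, keep_min_nm, keep_max_nm)
  out <- rebin_bands(out, target_width_nm)
  if (!is.null(window)) {
    w <- min(as.integer(window), length(out$wavelengths_nm))
    if (w %% 2L == 0L) w <- w - 1L
    out <- savgol_smooth(out, w, min(polyorder, w - 1L))
  }
  flagged <- detect_outliers_pca(out, n_components, z_threshold)
  list(spectra = out, outliers = flagged)
}
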