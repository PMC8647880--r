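# Recursive feature elimination of reflectance bands against a response
# trait: backward elimination ranked by learner importance, scored by
# repeated outer cross-validation over candidate subset sizes.

rfe_learners <- list(
  svr = list(
    # bands and response both standardized inside the fit so |w| is
    # comparable across bands and the tube width is on response-sd units
    fit = function(X, y, C, epsilon) {
      mu <- colMeans(X); sdev <- apply(X, 2, sd)
      sdev[sdev == 0] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sdev, `/`)
      my <- mean(y); sy <- sd(y)
      fit <- svr_fit(Xs, (y - my) / sy, kernel = "linear", C = C,
                     epsilon = epsilon)
      list(importance = abs(fit$w),
           predict = function(Xn) {
             Xn <- sweep(sweep(as.matrix(Xn), 2, mu), 2, sdev, `/`)
             drop(Xn %*% fit$w + fit$b) * sy + my
           })
    }),
  lm = list(
    fit = function(X, y, C, epsilon) {
      df <- as.data.frame(X)
      names(df) <- paste0("b", seq_len(ncol(X)))
      fit <- stats::lm(y ~ ., data = cbind(y = y, df))
      sm <- stats::summary.lm(fit)$coefficients
      imp <- setNames(rep(0, ncol(X)), names(df))
      hit <- intersect(rownames(sm), names(df))
      imp[hit] <- abs(sm[hit, 3])
      list(importance = unname(imp),
           predict = function(Xn) {
             dn <- as.data.frame(Xn)
             names(dn) <- names(df)
             unname(stats::predict(fit, dn))
           })
    })
)

# Backward elimination on (X, y): returns the band index sets visited at
# each candidate size (descending) and the elimination order.
rfe_path <- function(X, y, learner, sizes, C, epsilon) {
  p <- ncol(X)
  sizes <- sort(unique(as.integer(sizes)), decreasing = TRUE)
  current <- seq_len(p)
  path <- list()
  elim_order <- integer(0)
  for (s in sizes) {
    if (length(current) > s) {
      fit <- learner$fit(X[, current, drop = FALSE], y, C, epsilon)
      ord <- order(fit$importance, decreasing = FALSE)
      drop_n <- length(current) - s
      dropped <- current[ord[seq_len(drop_n)]]
      elim_order <- c(elim_order, dropped)
      current <- setdiff(current, dropped)
    }
    path[[as.character(s)]] <- current
  }
  list(path = path, elim_order = elim_order, sizes = sizes)
}

#' Recursive feature elimination of bands (HypWAS selection)
#'
#' Backward elimination: fit the learner on the current band set, rank bands
#' by learner importance, drop the weakest down to the next candidate size,
#' repeat. An outer repeated cross-validation scores every candidate size
#' (RMSE and R-squared on held-out genotypes); the optimal size maximizes
#' mean CV R-squared with a one-standard-error tie-break toward fewer
#' bands. The final model is refit on the full data; reported importances
#' (0-100) come from the full-data fit on all bands, and "significant"
#' bands are the members of the CV-optimal subset.
#'
#' @param X genotype x band matrix of genetic values (no missing).
#' @param y genotype-level trait vector (named or aligned to `rownames(X)`).
#' @param learner `"svr"` (linear ε-SVR on standardized bands and response,
#'   |w| importance; default) or `"lm"` (|t| importance).
#' @param subset_sizes candidate sizes (default `1..min(20, n_bands)` plus
#'   all bands).
#' @param folds,repeats outer CV layout.
#' @param seed integer seed.
#' @param C,epsilon SVR learner parameters.
#' @param r2_floor best mean CV R-squared at or below this marks the whole
#'   selection non-significant (null-response guard).
#' @return an `rfe_profile`: list with `importance` (0-100 per band),
#'   `cv_profile` (size, mean/sd RMSE and R2), `optimal_size`,
#'   `selected` (band indices), `selected_names`, `elimination_order`,
#'   `learner`, `significant`.
#' @export
rfe_select <- function(X, y, learner = c("svr", "lm"), subset_sizes = NULL,
                       folds = 5L, repeats = 5L, seed = 1L,
                       C = 1, epsilon = 0.01, r2_floor = 0.1) {
  learner <- match.arg(learner)
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1) stop_config("need at least one band")
  if (anyNA(X) || anyNA(y)) stop_config("missing values not allowed")
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    if (!all(rownames(X) %in% names(y)))
      stop_config("y does not cover all rows of X")
    y <- y[rownames(X)]
  }
  if (sd(y) == 0) stop_config("constant response")
  if (is.null(subset_sizes)) subset_sizes <- unique(c(seq_len(min(20L, p)), p))
  subset_sizes <- sort(unique(as.integer(subset_sizes)))
  if (any(subset_sizes < 1 | subset_sizes > p))
    stop_config("subset sizes must lie in 1..%d", p)
  L <- rfe_learners[[learner]]
  n <- nrow(X)

  set.seed(substream_seed(seed, 301L))
  perf <- array(NA_real_, c(length(subset_sizes), folds * repeats, 2),
                dimnames = list(size = subset_sizes, NULL, c("rmse", "r2")))
  col <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      col <- col + 1L
      test <- fold_id == f
      if (sum(test) < 2 || sd(y[!test]) == 0) next
      pp <- rfe_path(X[!test, , drop = FALSE], y[!test], L, subset_sizes,
                     C, epsilon)
      for (s in subset_sizes) {
        idx <- pp$path[[as.character(s)]]
        fit <- L$fit(X[!test, idx, drop = FALSE], y[!test], C, epsilon)
        pred <- fit$predict(X[test, idx, drop = FALSE])
        err <- y[test] - pred
        perf[as.character(s), col, "rmse"] <- sqrt(mean(err^2))
        perf[as.character(s), col, "r2"] <-
          1 - mean(err^2) / mean((y[test] - mean(y[!test]))^2)
      }
    }
  }
  mean_r2 <- apply(perf[, , "r2", drop = FALSE], 1, mean, na.rm = TRUE)
  sd_r2 <- apply(perf[, , "r2", drop = FALSE], 1, sd, na.rm = TRUE)
  nruns <- apply(!is.na(perf[, , "r2", drop = FALSE]), 1, sum)
  best_i <- which.max(mean_r2)
  se_best <- sd_r2[best_i] / sqrt(max(1, nruns[best_i]))
  ok <- mean_r2 >= mean_r2[best_i] - se_best
  optimal_size <- subset_sizes[which(ok)[1]]

  full_path <- rfe_path(X, y, L, subset_sizes, C, epsilon)
  selected <- sort(full_path$path[[as.character(optimal_size)]])
  full_fit <- L$fit(X, y, C, epsilon)
  importance <- scale_importance(setNames(full_fit$importance,
                                          colnames(X) %||%
                                            paste0("band", seq_len(p))))
  cv_profile <- data.frame(
    size = subset_sizes,
    mean_rmse = apply(perf[, , "rmse", drop = FALSE], 1, mean, na.rm = TRUE),
    mean_r2 = mean_r2, sd_r2 = sd_r2)
  structure(list(importance = importance, cv_profile = cv_profile,
                 optimal_size = optimal_size, selected = selected,
                 selected_names = names(importance)[selected],
                 elimination_order = full_path$elim_order,
                 learner = learner,
                 significant = unname(mean_r2[best_i] > r2_floor)),
            class = "rfe_profile")
}

#' @export
print.rfe_profile <- function(x, ...) {
  cat(sprintf("rfe_profile (%s): optimal size %d of %d bands; best CV R2 %.3f%s\n",
              x$learner, x$optimal_size, length(x$importance),
              max(x$cv_profile$mean_r2, na.rm = TRUE),
              if (x$significant) "" else " (selection not significant)"))
  cat("selected:", paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}

#' Write an RFE profile as TSV + JSON
#'
#' @param profile an `rfe_profile`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_rfe_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bands <- data.frame(band = names(profile$importance),
                      importance = as.numeric(profile$importance),
                      selected = seq_along(profile$importance) %in%
                        profile$selected)
  p1 <- file.path(dir, "bands.tsv")
  p2 <- file.path(dir, "cv_profile.json")
  data.table::fwrite(bands, p1, sep = "\t")
  jsonlite::write_json(list(cv_profile = profile$cv_profile,
                            optimal_size = profile$optimal_size,
                            significant = profile$significant),
                       p2, auto_unbox = TRUE, digits = NA)
  invisible(c(bands = p1, profile = p2))
}
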