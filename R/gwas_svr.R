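#' Configuration for the SVR-mediated GWAS
#'
#' @param kernel `"linear"` (default; appropriate for p >> n marker panels)
#'   or `"rbf"`.
#' @param C,epsilon SVR regularization and tube half-width.
#' @param folds,repeats cross-validation layout used to estimate variable
#'   importance (default 5-fold, 10 repetitions).
#' @param n_repetitions number of reseeded importance runs aggregated by
#'   [svr_gwas()] (default 1000; scale down for desk-size problems).
#' @param n_permutations phenotype permutations building the global
#'   empirical null (default 1000, minimum 20).
#' @param perm_repeats CV repetitions used inside each permutation (reduced
#'   relative to `repeats` for speed; match them when calibrating).
#' @param n_shuffles independent column shuffles averaged per marker, fold
#'   and repeat when estimating permutation importance.
#' @param max_sweeps coordinate-descent sweep cap for the inner SVR fits
#'   (early stopping; ranking stabilizes well before full convergence).
#' @param alpha family-wise significance level for the empirical threshold.
#' @param metric `"permutation"` (CV score drop when a marker is shuffled)
#'   or `"weight"` (linear-kernel |w|).
#' @param seed integer seed; every random draw derives from it.
#' @return an `svr_config` list.
#' @export
svr_config <- function(kernel = c("linear", "rbf"), C = 1, epsilon = 0.1,
                       folds = 5L, repeats = 10L, n_repetitions = 1000L,
                       n_permutations = 1000L, perm_repeats = 2L,
                       n_shuffles = 2L, max_sweeps = 80L,
                       alpha = 0.05, metric = c("permutation", "weight"),
                       seed = 1L) {
  kernel <- match.arg(kernel)
  metric <- match.arg(metric)
  if (folds < 2) stop_config("folds must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0,1)")
  if (epsilon < 0) stop_config("epsilon must be >= 0")
  if (metric == "weight" && kernel != "linear")
    stop_config("weight importance requires the linear kernel")
  structure(list(kernel = kernel, C = C, epsilon = epsilon,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 n_repetitions = as.integer(n_repetitions),
                 n_permutations = as.integer(n_permutations),
                 perm_repeats = as.integer(perm_repeats),
                 n_shuffles = as.integer(n_shuffles),
                 max_sweeps = as.integer(max_sweeps),
                 alpha = alpha, metric = metric, seed = as.integer(seed)),
            class = "svr_config")
}

#' Min-max scale importances to the 0-100 scale
#'
#' Linear map sending the minimum to 0 and the maximum to 100. A constant
#' vector maps to all 100 with a warning; a single value maps to 100.
#'
#' @param x numeric vector of raw importances (finite).
#' @return numeric vector in `[0, 100]`.
#' @export
scale_importance <- function(x) {
  if (length(x) == 0) stop_config("empty importance vector")
  if (!all(is.finite(x))) stop_config("importances must be finite")
  rng <- range(x)
  if (length(x) == 1L) return(setNames(100, names(x)))
  if (diff(rng) == 0) {
    warning("constant importances; all scaled to 100")
    return(setNames(rep(100, length(x)), names(x)))
  }
  setNames((x - rng[1]) / diff(rng) * 100, names(x))
}

dosage_matrix <- function(G) {
  if (inherits(G, "genotype_matrix")) G$dosage else as.matrix(G)
}

# One CV pass of raw importance estimation. For the linear kernel the
# shuffled-column prediction is updated in O(n) per marker; for rbf the test
# kernel matrix is recomputed against the perturbed column.
svr_importance_raw <- function(y, M, cfg, repeats, seed) {
  n <- nrow(M); m <- ncol(M)
  set.seed(seed)
  imp <- numeric(m)
  used <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(cfg$folds), n))
    for (f in seq_len(cfg$folds)) {
      test <- fold_id == f
      if (sum(test) < 2 || sd(y[!test]) == 0) next
      fit <- svr_fit(M[!test, , drop = FALSE], y[!test], kernel = cfg$kernel,
                     C = cfg$C, epsilon = cfg$epsilon,
                     max_sweeps = cfg$max_sweeps)
      Mt <- M[test, , drop = FALSE]
      pred <- predict(fit, Mt)
      if (cfg$metric == "weight") {
        imp <- imp + abs(fit$w)
      } else {
        base <- mse(y[test], pred)
        resid <- y[test] - pred
        drops <- numeric(m)
        for (sh in seq_len(cfg$n_shuffles)) {
          perm <- sample.int(sum(test))
          if (cfg$kernel == "linear") {
            # shuffling column j alone shifts predictions by delta[, j] * w[j];
            # all per-marker MSEs fall out of one matrix expression
            delta <- Mt[perm, , drop = FALSE] - Mt
            err <- resid - sweep(delta, 2, fit$w, `*`)
            drops <- drops + colMeans(err^2) - base
          } else {
            drops <- drops + vapply(seq_len(m), function(j) {
              Mp <- Mt
              Mp[, j] <- Mt[perm, j]
              mse(y[test], predict(fit, Mp)) - base
            }, 0)
          }
        }
        imp <- imp + (drops / cfg$n_shuffles) /
          max(var(y[test]), .Machine$double.eps)
      }
      used <- used + 1L
    }
  }
  if (used == 0L) stop_config("no usable CV fold")
  imp / used
}

mse <- function(y, pred) mean((y - pred)^2)

#' Per-marker SVR variable importance
#'
#' Fits an ε-SVR of the phenotype on all marker dosages within a repeated
#' cross-validation, scores each marker by permutation importance (the
#' held-out error increase when that marker's column is shuffled, in units
#' of the held-out phenotype variance) or by the linear-kernel weight
#' magnitude, averages over folds and repeats, and min-max scales the
#' result to `[0, 100]`.
#'
#' @param y phenotype (named or aligned), complete.
#' @param G `genotype_matrix` or dosage matrix, complete.
#' @param cfg an [svr_config()].
#' @return named numeric vector in `[0, 100]` with attribute `"raw"` (the
#'   unscaled importances, which [empirical_threshold()] and [svr_gwas()]
#'   compare against the permutation null).
#' @export
svr_importance <- function(y, G, cfg = svr_config()) {
  M <- dosage_matrix(G)
  if (inherits(G, "genotype_matrix")) y <- align_phenotype(y, G)
  if (anyNA(y) || anyNA(M)) stop_config("y and G must be complete")
  if (sd(y) == 0) stop_config("constant phenotype")
  raw <- svr_importance_raw(y, M, cfg, cfg$repeats,
                            substream_seed(cfg$seed, 101L))
  names(raw) <- colnames(M)
  out <- suppressWarnings(scale_importance(raw))
  attr(out, "raw") <- raw
  out
}

#' Global empirical significance threshold for SVR importance
#'
#' For each of `n_permutations` phenotype permutations the per-marker raw
#' importances are recomputed (with `perm_repeats` CV repetitions) and their
#' maximum is recorded; the threshold is the `ceiling((1 - alpha) * n)`-th
#' order statistic of these maxima, which controls family-wise error at
#' `alpha` for the max-importance statistic. The returned value is mapped
#' onto the original run's 0-100 scale (per-run min-max scaling would pin
#' every run's maximum at 100, so the test itself is performed on the raw
#' scale).
#'
#' @param y,G,cfg as in [svr_importance()].
#' @param anchor optional importance vector from [svr_importance()] on the
#'   unpermuted data, providing the 0-100 anchoring (recomputed when NULL).
#' @return threshold on the 0-100 scale, with attributes `"raw"` (raw-scale
#'   threshold) and `"maxima"` (the permutation maxima).
#' @export
empirical_threshold <- function(y, G, cfg = svr_config(), anchor = NULL) {
  if (cfg$n_permutations < 20) stop_config("need n_permutations >= 20")
  if (cfg$alpha < 1 / cfg$n_permutations)
    stop_config("alpha = %g unattainable with %d permutations",
                cfg$alpha, cfg$n_permutations)
  M <- dosage_matrix(G)
  if (inherits(G, "genotype_matrix")) y <- align_phenotype(y, G)
  if (is.null(anchor)) anchor <- svr_importance(y, G, cfg)
  raw_anchor <- attr(anchor, "raw")
  maxima <- vapply(seq_len(cfg$n_permutations), function(b) {
    seed_b <- substream_seed(cfg$seed, 1000L + b)
    set.seed(seed_b)
    yp <- sample(y)
    max(svr_importance_raw(yp, M, cfg, cfg$perm_repeats, seed_b + 7L))
  }, 0)
  k <- max(1L, as.integer(ceiling((1 - cfg$alpha) * cfg$n_permutations)))
  thr_raw <- sort(maxima)[k]
  rng <- range(raw_anchor)
  thr_scaled <- if (diff(rng) > 0) (thr_raw - rng[1]) / diff(rng) * 100 else 100
  structure(thr_scaled, raw = thr_raw, maxima = maxima)
}

#' SVR-mediated GWAS with a permutation-based global empirical threshold
#'
#' Aggregates `n_repetitions` reseeded importance runs, builds the
#' permutation null with [empirical_threshold()], and flags markers whose
#' aggregated raw importance exceeds the raw-scale threshold. The
#' significance test is family-wise (max statistic) at level `alpha`.
#'
#' @param y phenotype; `G` a `genotype_matrix`; `cfg` an [svr_config()].
#' @param G,cfg see above.
#' @return a `gwas_result` (engine `"svr"`) with columns `importance`
#'   (0-100 scale), `importance_raw`, `importance_sd` (over repetitions),
#'   `sel_freq` (fraction of repetitions exceeding the threshold) and
#'   `significant`; attribute `threshold` records
#'   `(type = "empirical", level = alpha, value)` on the 0-100 scale.
#' @export
svr_gwas <- function(y, G, cfg = svr_config()) {
  M <- dosage_matrix(G)
  y <- align_phenotype(y, G)
  reps <- vapply(seq_len(cfg$n_repetitions), function(r) {
    svr_importance_raw(y, M, cfg, cfg$repeats,
                       substream_seed(cfg$seed, 100L + r))
  }, numeric(ncol(M)))
  if (ncol(M) == 1L) reps <- matrix(reps, nrow = 1L)
  raw <- rowMeans(reps)
  raw_sd <- apply(reps, 1, sd)
  scaled <- suppressWarnings(scale_importance(setNames(raw, G$map$id)))
  anchor <- structure(scaled, raw = setNames(raw, G$map$id))
  thr <- empirical_threshold(y, G, cfg, anchor = anchor)
  thr_raw <- attr(thr, "raw")
  stats <- data.frame(importance = as.numeric(scaled),
                      importance_raw = raw,
                      importance_sd = raw_sd,
                      sel_freq = rowMeans(reps > thr_raw),
                      significant = raw > thr_raw)
  gwas_result(G$map, stats, "svr",
              list(type = "empirical", level = cfg$alpha,
                   value = as.numeric(thr)),
              extra = list(threshold_raw = thr_raw,
                           perm_maxima = attr(thr, "maxima")))
}
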