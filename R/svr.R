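#' Fit an epsilon-insensitive support vector regression
#'
#' In-package ε-SVR trained by deterministic dual coordinate descent
#' (L1-loss dual with box constraint `C`). The bias is absorbed into an
#' augmented constant feature, so it is mildly regularized like the weights;
#' for the over-determined, noisy settings this package targets the
#' difference from an unregularized bias is negligible. The `rbf` kernel
#' uses the Gaussian kernel `exp(-gamma * ||x - x'||^2)` with
#' `gamma = 1 / n_features` by default.
#'
#' @param X numeric feature matrix (rows = observations).
#' @param y numeric response.
#' @param kernel `"linear"` or `"rbf"`.
#' @param C box constraint (regularization, larger = less regularized).
#' @param epsilon half-width of the insensitive tube.
#' @param gamma RBF kernel width (NULL = `1/ncol(X)`).
#' @param tol,max_sweeps solver controls.
#' @return an `svr_fit` object with a `predict` method; linear fits expose
#'   `w` (feature weights) and `b` (bias).
#' @export
svr_fit <- function(X, y, kernel = c("linear", "rbf"), C = 1, epsilon = 0.1,
                    gamma = NULL, tol = 1e-4, max_sweeps = 200L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop_config("X rows != length(y)")
  if (sd(y) == 0) stop_config("constant response; SVR undefined")
  if (kernel == "linear") {
    fit <- .svr_cd_linear(rbind(t(X), 1), y, C, epsilon, tol, max_sweeps)
    w <- fit$w
    out <- list(kernel = "linear", w = w[-length(w)], b = w[length(w)],
                beta = fit$beta, sweeps = fit$sweeps, C = C,
                epsilon = epsilon)
  } else {
    if (is.null(gamma)) gamma <- 1 / ncol(X)
    Q <- rbf_kernel(X, X, gamma) + 1  # +1 absorbs the bias
    fit <- .svr_cd_kernel(Q, y, C, epsilon, tol, max_sweeps)
    out <- list(kernel = "rbf", beta = fit$beta, X_train = X, gamma = gamma,
                sweeps = fit$sweeps, C = C, epsilon = epsilon)
  }
  class(out) <- "svr_fit"
  out
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' @param object an `svr_fit`.
#' @param newdata feature matrix to predict for.
#' @param ... unused.
#' @rdname svr_fit
#' @export
predict.svr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$kernel == "linear") {
    drop(newdata %*% object$w + object$b)
  } else {
    drop((rbf_kernel(newdata, object$X_train, object$gamma) + 1) %*% object$beta)
  }
}
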