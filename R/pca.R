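#' Survey-weighted principal component analysis
#'
#' Eigendecomposition of the weighted correlation matrix
#' `Sigma_w = t(X) %*% diag(w / sum(w)) %*% X` of a matrix already
#' standardized to weighted mean 0 / variance 1 (see
#' [center_scale_weighted()]). Probability weights are normalized to sum
#' to one; no finite-population correction is applied. The number of
#' components equals the number of input columns. Eigenvector signs are
#' fixed deterministically: within each loading column the entry of
#' largest absolute value is made positive.
#'
#' @param x standardized numeric matrix, subjects x variables.
#' @param weights positive survey weights.
#' @param means,scales optional standardization parameters to store with
#'   the model (used by `predict` on raw-scale new data).
#' @return an object of class `weighted_pca`: list with `loadings`
#'   (N x N, column pc holds the loadings L_i of that component),
#'   `eigenvalues` (nonincreasing, nonnegative), `means`, `scales`,
#'   `n_variables`, `var_names`.
#' @export
#' @examples
#' x <- scale(matrix(rnorm(300), 100, 3))
#' fit <- fit_weighted_pca(x, rep(1, 100))
#' fit$eigenvalues
fit_weighted_pca <- function(x, weights, means = NULL, scales = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("input matrix contains non-finite entries")
  if (any(weights <= 0)) stop("weights must be positive")
  n <- nrow(x); p <- ncol(x)
  if (n < p) {
    warning("fewer subjects than variables: PCA becomes unstable")
  }
  wn <- weights / sum(weights)
  cw <- crossprod(x * sqrt(wn))          # t(x) %*% diag(wn) %*% x
  eig <- eigen(cw, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  L <- eig$vectors
  # deterministic sign: largest-|loading| entry positive in each column
  for (j in seq_len(p)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  var_names <- colnames(x)
  if (is.null(var_names)) var_names <- paste0("V", seq_len(p))
  dimnames(L) <- list(var_names, paste0("PC", seq_len(p)))
  structure(list(loadings = L, eigenvalues = lam,
                 means = means, scales = scales,
                 n_variables = p, var_names = var_names),
            class = "weighted_pca")
}

#' Predict per-subject principal component scores
#'
#' Scores are `x %*% loadings`: score column pc for subject s is
#' `sum_i L_i * x_si`, the weighted sum of the standardized variables.
#'
#' @param object a `weighted_pca`.
#' @param newdata matrix with the model's columns. If `standardized =
#'   FALSE` the model's stored means/scales are applied first.
#' @param standardized is `newdata` already standardized? (default TRUE)
#' @param ... unused.
#' @return subjects x N score matrix.
#' @export
predict.weighted_pca <- function(object, newdata, standardized = TRUE, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_variables) {
    stop(sprintf("newdata has %d columns, model expects %d",
                 ncol(newdata), object$n_variables))
  }
  if (!standardized) {
    if (is.null(object$means)) {
      stop("model stores no standardization parameters; pass standardized data")
    }
    newdata <- sweep(sweep(newdata, 2, object$means), 2, object$scales, `/`)
  }
  newdata %*% object$loadings
}

#' @rdname predict.weighted_pca
#' @param model a `weighted_pca`.
#' @param x standardized matrix.
#' @export
predict_scores <- function(model, x) predict(model, x, standardized = TRUE)

#' @export
print.weighted_pca <- function(x, ...) {
  cat(sprintf("weighted_pca: %d variables, %d components\n",
              x$n_variables, x$n_variables))
  k <- min(5L, x$n_variables)
  cat("  leading eigenvalues:",
      paste(sprintf("%.3f", x$eigenvalues[seq_len(k)]), collapse = ", "),
      if (x$n_variables > k) "..." else "", "\n")
  cat(sprintf("  total variance: %.3f\n", sum(x$eigenvalues)))
  invisible(x)
}
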