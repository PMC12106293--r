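rbf_kernel <- function(x1, x2, gamma) {
  # exp(-gamma * ||a - b||^2), computed via the expansion of the square
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit a radial-kernel soft-margin SVM
#'
#' Solves the dual with a sequential-minimal-optimisation solver (compiled;
#' maximal-violating-pair working set selection). The decision function is
#' f(x) = sum_i alpha_i y_i K(x_i, x) + b with the Gaussian kernel
#' K(a, b) = exp(-gamma ||a - b||^2).
#'
#' @param x samples x features numeric matrix.
#' @param y binary labels (0/1).
#' @param C soft-margin cost (default 1).
#' @param gamma kernel width (default 1/ncol(x)).
#' @param scale standardize columns internally (default TRUE); the means
#'   and SDs are stored and applied at prediction time.
#' @param tol SMO duality-gap tolerance.
#' @return a `radial_svm` object.
#' @export
svm_fit <- function(x, y, C = 1, gamma = 1 / ncol(x), scale = TRUE,
                    tol = 1e-6) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) != 2) {
    stop("y must be binary 0/1 with both classes present")
  }
  if (scale) {
    center <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0] <- 1
    xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  } else {
    center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
    xs <- x
  }
  yf <- ifelse(y == 1L, 1L, -1L)
  K <- rbf_kernel(xs, xs, gamma)
  sol <- smo_solve(K, as.integer(yf), C = C, tol = tol)
  sv <- sol$alpha > 1e-8
  structure(list(sv_x = xs[sv, , drop = FALSE],
                 sv_coef = sol$alpha[sv] * yf[sv],
                 b = sol$b, C = C, gamma = gamma,
                 center = center, scale = scl,
                 features = colnames(x),
                 iterations = sol$iterations),
            class = "radial_svm")
}

#' Decision values of a fitted radial SVM
#'
#' @param fit a `radial_svm`.
#' @param newx samples x features matrix on the original scale used at fit
#'   time.
#' @return numeric decision values (positive = class 1 side).
#' @export
svm_decision <- function(fit, newx) {
  stopifnot(inherits(fit, "radial_svm"))
  if (!is.matrix(newx)) newx <- as.matrix(newx)
  if (!is.null(fit$features) && !is.null(colnames(newx))) {
    newx <- newx[, fit$features, drop = FALSE]
  }
  xs <- sweep(sweep(newx, 2, fit$center), 2, fit$scale, "/")
  drop(rbf_kernel(xs, fit$sv_x, fit$gamma) %*% fit$sv_coef) + fit$b
}
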