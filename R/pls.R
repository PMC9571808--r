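# Partial least squares regression core (univariate response, SIMPLS).
# Kept deliberately small and allocation-free: it sits inside the
# cross-validated criterion of the forward search, where tens of
# thousands of fits are made per run.

#' Fit a PLS1 regression (SIMPLS)
#'
#' Partial least squares regression of a single numeric response on a
#' feature matrix, via the SIMPLS deflation of the cross-covariance. With
#' `ncomp` equal to the rank of the centered predictor matrix the fitted
#' values coincide with ordinary least squares.
#'
#' @param x Numeric predictor matrix (observations x features).
#' @param y Numeric response vector.
#' @param ncomp Number of latent components (1 <= ncomp <= min(n-1, p)).
#' @return Object of class `"pls1"`: coefficient paths `coef` (p x ncomp,
#'   coefficients for models with 1..ncomp components on the original
#'   scale of `x`), centers `x_mean`, `y_mean`, and `ncomp`.
#' @seealso [predict.pls1()]
#' @export
pls1_fit <- function(x, y, ncomp) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("x and y sizes differ")
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    stop("ncomp must be in [1, min(n - 1, p)]")
  }
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  xc <- sweep(x, 2, x_mean)
  yc <- y - y_mean

  s <- crossprod(xc, yc)          # p x 1 cross-covariance
  w_mat <- matrix(0, p, ncomp)    # weights (x-space)
  q <- numeric(ncomp)             # y-loadings
  v_basis <- matrix(0, p, ncomp)  # orthonormal basis of x-loadings
  for (a in seq_len(ncomp)) {
    r <- s
    t_scores <- xc %*% r
    tnorm <- sqrt(sum(t_scores^2))
    if (tnorm < .Machine$double.eps^0.5) break  # response fully explained
    t_scores <- t_scores / tnorm
    r <- r / tnorm
    p_load <- crossprod(xc, t_scores)
    q[a] <- sum(yc * t_scores)
    v <- p_load
    if (a > 1) {
      prev <- v_basis[, seq_len(a - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, p_load)
    }
    v <- v / sqrt(sum(v^2))
    v_basis[, a] <- v
    w_mat[, a] <- r
    s <- s - v * sum(v * s)       # deflate the cross-covariance
  }
  beta <- apply(w_mat * rep(q, each = p), 1, cumsum)
  beta <- if (ncomp == 1) matrix(beta, p, 1) else t(beta)
  structure(list(coef = beta, x_mean = x_mean, y_mean = y_mean,
                 ncomp = ncomp),
            class = "pls1")
}

#' Predict from a PLS1 fit
#'
#' @param object A [pls1_fit()] object.
#' @param newdata Numeric matrix of predictors.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  b <- object$coef[, ncomp]
  drop(sweep(newdata, 2, object$x_mean) %*% b) + object$y_mean
}
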