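# Core generalized least squares machinery. All solves go through a single
# Cholesky factorization of the working covariance; the contract (and the
# test oracle) is the explicit-inverse formula beta = (X'V^-1 X)^-1 X'V^-1 y.

# Cholesky "whitening": returns L^-1 %*% A for V = L L'
whiten <- function(R, A) backsolve(R, A, transpose = TRUE)

chol_or_stop <- function(V) {
  out <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(out)) {
    stop("degenerate covariance: V is not positive definite on the data",
      call. = FALSE
    )
  }
  out
}

#' Generalized least squares solve
#'
#' Computes the GLS estimate minimizing `(y - X b)' V^-1 (y - X b)`, its
#' covariance `sigma2 * (X' V^-1 X)^-1`, and the residual-quadratic-form
#' variance estimate `sigma2 = r' V^-1 r / (n - p)`. Implemented by Cholesky
#' whitening; equivalent to the explicit normal-equations formula.
#'
#' @param X Design matrix (n x p, including the intercept column).
#' @param y Response vector (length n).
#' @param V Covariance matrix (n x n, positive definite), known up to the
#'   scale factor `sigma2`.
#' @return List with `beta` (named as X columns), `cov_beta`, `sigma2`,
#'   `rss_gls` (residual quadratic form), `n`, `p`.
#' @export
#' @examples
#' X <- cbind(1, 1:6)
#' y <- 2 + 0.5 * (1:6) + c(0.1, -0.2, 0, 0.2, -0.1, 0)
#' gls_solve(X, y, diag(6))$beta
gls_solve <- function(X, y, V) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) {
    stop("dimension mismatch between X, y and V", call. = FALSE)
  }
  if (n <= p) stop("need n > p observations", call. = FALSE)
  if (qr(X)$rank < p) {
    stop("singular design: columns of X are collinear", call. = FALSE)
  }
  R <- chol_or_stop(V)
  Xw <- whiten(R, X)
  yw <- whiten(R, y)
  qrx <- qr(Xw)
  beta <- qr.coef(qrx, yw)
  r <- yw - Xw %*% beta
  rss <- sum(r^2)
  sigma2 <- rss / (n - p)
  XtViX <- crossprod(Xw)
  cov_beta <- sigma2 * chol2inv(chol(XtViX))
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  list(
    beta = stats::setNames(as.numeric(beta), colnames(X)),
    cov_beta = cov_beta, sigma2 = sigma2, rss_gls = rss, n = n, p = p
  )
}

#' Restricted (REML) log-likelihood of a GLS model
#'
#' Restricted log-likelihood of `y ~ N(X b, sigma2 V)` with both `b` and
#' `sigma2` profiled out. The Harville normalization `+ 1/2 log|X'X|` is
#' included, which makes the value exactly invariant under full-rank
#' reparameterization of the design, and the criterion is likewise invariant
#' to rescaling `V` by a positive constant (the scale is absorbed into the
#' profiled `sigma2`).
#'
#' @inheritParams gls_solve
#' @return Scalar restricted log-likelihood.
#' @export
reml_loglik <- function(X, y, V) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  fit <- gls_solve(X, y, V)
  R <- chol_or_stop(V)
  logdetV <- 2 * sum(log(diag(R)))
  Xw <- whiten(R, X)
  logdet_XtViX <- determinant(crossprod(Xw), logarithm = TRUE)$modulus
  logdet_XtX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  df <- n - p
  sigma2_reml <- fit$rss_gls / df
  as.numeric(
    -0.5 * (df * log(2 * pi) + df * log(sigma2_reml) + df +
      logdetV + logdet_XtViX - logdet_XtX)
  )
}

#' Profiled maximum log-likelihood of a GLS model
#'
#' Full (unrestricted) log-likelihood with `b` set to the GLS estimate and
#' `sigma2` at its ML value `rss / n`. Used for AIC comparison across
#' covariance structures.
#'
#' @inheritParams gls_solve
#' @return Scalar log-likelihood.
#' @export
ml_loglik <- function(X, y, V) {
  n <- length(y)
  fit <- gls_solve(X, y, V)
  R <- chol_or_stop(V)
  logdetV <- 2 * sum(log(diag(R)))
  sigma2_ml <- fit$rss_gls / n
  if (sigma2_ml <= 0) sigma2_ml <- .Machine$double.xmin
  -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + n + logdetV)
}
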