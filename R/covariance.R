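#' Apply Pagel's lambda transform to a phylogenetic covariance matrix
#'
#' Pagel's lambda rescales the shared-history (off-diagonal) covariances while
#' leaving the per-species variances untouched: lambda = 1 recovers pure
#' Brownian motion, lambda = 0 the star phylogeny (phylogenetic independence).
#' For lambda in \[0, 1\] the result is a convex combination
#' `lambda * V + (1 - lambda) * diag(V)` and therefore stays positive
#' semi-definite.
#'
#' @param V A `phylo_vcv` object or symmetric matrix.
#' @param lambda Dimensionless scalar.
#' @param bounds Allowed interval for `lambda` (default `c(0, 1)`, within
#'   which positive semi-definiteness is guaranteed).
#' @return A `phylo_vcv` with model tag `"PagelLambda(<lambda>)"`.
#' @export
#' @examples
#' V <- phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
#' apply_lambda(V, 0.5)
apply_lambda <- function(V, lambda, bounds = c(0, 1)) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda)) {
    stop("`lambda` must be a finite scalar", call. = FALSE)
  }
  if (lambda < bounds[1] || lambda > bounds[2]) {
    stop(sprintf(
      "lambda = %g outside bounds [%g, %g]", lambda, bounds[1], bounds[2]
    ), call. = FALSE)
  }
  W <- unclass(V)
  d <- diag(W)
  W <- W * lambda
  diag(W) <- d
  new_phylo_vcv(W,
    model_tag = sprintf("PagelLambda(%g)", lambda),
    weights = attr(V, "weights")
  )
}

#' Fixed-variance weights from a phylogenetic covariance matrix
#'
#' For a non-ultrametric tree the Brownian variances differ between tips
#' (root-to-tip path lengths differ), so GLS needs per-taxon fixed variances.
#' These are the diagonal entries of the Brownian covariance matrix.
#'
#' @param V A `phylo_vcv` object or matrix with positive diagonal.
#' @return Named numeric vector of per-taxon variances.
#' @export
fixed_variance_weights <- function(V) {
  w <- diag(unclass(V))
  bad <- w <= 0
  if (any(bad)) {
    stop(
      "non-positive variance for taxa: ",
      paste(names(w)[bad], collapse = ", "),
      call. = FALSE
    )
  }
  w
}

#' Working covariance combining a lambda correlation with fixed variances
#'
#' Builds the covariance used inside the PGLS fit. With
#' `combine = "correlation"` (default) the Brownian matrix is decomposed into
#' its correlation `C` and variances `D`, lambda is applied to the
#' off-diagonal of `C`, and the result is re-scaled:
#' `W = D^{1/2} C_lambda D^{1/2}`. For ultrametric trees this coincides with
#' [apply_lambda()] applied to `V` directly. `combine = "weights-only"`
#' drops the correlation and returns the pure diagonal `D` (species treated
#' as independent, with unequal variances).
#'
#' @param V Brownian `phylo_vcv` matrix.
#' @param lambda Pagel's lambda.
#' @param combine `"correlation"` or `"weights-only"`.
#' @return A `phylo_vcv` with the fixed-variance weights attached.
#' @export
working_covariance <- function(V, lambda = 1, combine = c("correlation", "weights-only")) {
  combine <- match.arg(combine)
  w <- fixed_variance_weights(V)
  if (combine == "weights-only") {
    W <- diag(w)
    dimnames(W) <- dimnames(V)
    return(new_phylo_vcv(W, model_tag = "Star", weights = w))
  }
  s <- sqrt(w)
  C <- unclass(V) / tcrossprod(s)
  Cl <- unclass(apply_lambda(new_phylo_vcv(C, "BM"), lambda))
  W <- Cl * tcrossprod(s)
  new_phylo_vcv(W,
    model_tag = sprintf("PagelLambda(%g)", lambda),
    weights = w
  )
}

#' Read / write a covariance matrix as CSV with taxa headers
#'
#' @param V Matrix with taxa dimnames.
#' @param file Path to write to / read from.
#' @return `read_vcv_csv` returns a `phylo_vcv`; `write_vcv_csv` returns the
#'   path invisibly.
#' @export
write_vcv_csv <- function(V, file) {
  df <- as.data.frame(unclass(V))
  df <- cbind(taxon = rownames(V), df)
  readr::write_csv(df, file)
  invisible(file)
}

#' @rdname write_vcv_csv
#' @export
read_vcv_csv <- function(file) {
  df <- readr::read_csv(file, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_phylo_vcv(m, model_tag = "BM")
}
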