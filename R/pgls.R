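#' Fit a (phylogenetic) generalized least squares regression
#'
#' The workhorse fit. The response and predictors are taken from a data frame
#' whose rows are species; the error covariance encodes shared evolutionary
#' history through a Brownian-motion matrix derived from a tree, optionally
#' damped by Pagel's lambda. With `model = "lambda"` and `lambda = NULL`,
#' lambda is estimated by bounded scalar search maximizing the REML (or ML)
#' criterion over `lambda_bounds`. For non-ultrametric trees the diagonal of
#' the Brownian matrix supplies fixed per-taxon variance weights and lambda
#' acts on the correlation structure (see [working_covariance()]).
#'
#' @param data Data frame with one row per species, containing the model
#'   variables and a species identifier column.
#' @param formula Model formula, e.g. `log_trait ~ log_mass`.
#' @param tree A `phylo` covering the species (pruned internally), or `NULL`
#'   when `V` is supplied or `model = "star"`.
#' @param V Optional precomputed Brownian `phylo_vcv` (overrides `tree`).
#' @param model Covariance family: `"lambda"` (Pagel), `"BM"` (lambda fixed
#'   at 1), or `"star"` (identity correlation; ordinary least squares).
#' @param lambda Fixed lambda value; `NULL` (default) estimates it when
#'   `model = "lambda"`.
#' @param method `"REML"` (default; used for coefficient reporting) or
#'   `"ML"` (used for AIC comparison across covariance structures).
#' @param species_col Name of the species identifier column.
#' @param use_weights `"auto"` (fixed-variance weights iff the tree is not
#'   ultrametric), `TRUE` or `FALSE`.
#' @param combine How weights combine with the lambda structure; see
#'   [working_covariance()].
#' @param lambda_bounds Search interval for lambda (default `c(0, 1)`, where
#'   positive semi-definiteness is guaranteed).
#' @param ci_level Confidence level for the stored intervals.
#' @return A `pgls_fit` object; see [tidy.pgls_fit()] and
#'   [glance.pgls_fit()] for tidy accessors.
#' @export
#' @examples
#' tr <- simulate_pure_birth_tree(32, seed = 1)
#' dat <- simulate_allometric_dataset(sim_config(n_tips = 32, seed = 1), tree = tr)
#' fit <- fit_pgls(dat, log10(trait_value) ~ log10(adult_weight_g), tree = tr)
#' tidy(fit)
fit_pgls <- function(data, formula, tree = NULL, V = NULL,
                     model = c("lambda", "BM", "star"),
                     lambda = NULL, method = c("REML", "ML"),
                     species_col = "species",
                     use_weights = "auto",
                     combine = c("correlation", "weights-only"),
                     lambda_bounds = c(0, 1),
                     ci_level = 0.95) {
  model <- match.arg(model)
  method <- match.arg(method)
  combine <- match.arg(combine)
  data <- as.data.frame(data)
  if (!species_col %in% names(data)) {
    stop("species column `", species_col, "` not found in data", call. = FALSE)
  }
  taxa <- normalize_labels(as.character(data[[species_col]]))
  if (anyDuplicated(taxa)) {
    stop("duplicate species in data: ",
      paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
      call. = FALSE
    )
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  taxa <- taxa[keep]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(formula), mf)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2) {
    stop(sprintf("insufficient data: %d complete cases for %d coefficients", n, p),
      call. = FALSE
    )
  }

  # assemble the Brownian matrix aligned to the data rows
  if (model == "star") {
    Vbm <- diag(n)
    dimnames(Vbm) <- list(taxa, taxa)
    Vbm <- new_phylo_vcv(Vbm, "Star")
    weights_used <- FALSE
  } else {
    if (is.null(V)) {
      if (is.null(tree)) stop("supply `tree` or `V` for phylogenetic models", call. = FALSE)
      missing <- setdiff(taxa, normalize_labels(tree$tip.label))
      if (length(missing)) {
        stop("taxa absent from tree: ", paste(missing, collapse = ", "), call. = FALSE)
      }
      tree <- prune_to_taxa(tree, taxa)
      Vbm <- phylo_vcv(tree)
    } else {
      missing <- setdiff(taxa, rownames(V))
      if (length(missing)) {
        stop("taxa absent from covariance: ", paste(missing, collapse = ", "), call. = FALSE)
      }
      Vbm <- new_phylo_vcv(unclass(V)[taxa, taxa, drop = FALSE], attr(V, "model_tag"))
    }
    Vbm <- new_phylo_vcv(unclass(Vbm)[taxa, taxa, drop = FALSE], attr(Vbm, "model_tag"))
    ultra <- {
      d <- diag(unclass(Vbm))
      (max(d) - min(d)) <= 1e-8 * max(d)
    }
    weights_used <- isTRUE(use_weights) || (identical(use_weights, "auto") && !ultra)
  }

  cov_at <- function(lam) {
    if (model == "star") {
      return(unclass(Vbm))
    }
    if (weights_used) {
      unclass(working_covariance(Vbm, lambda = lam, combine = combine))
    } else {
      unclass(apply_lambda(Vbm, lam, bounds = lambda_bounds))
    }
  }
  crit <- if (method == "REML") reml_loglik else ml_loglik

  lambda_estimated <- FALSE
  if (model == "star") {
    lambda_hat <- NA_real_
    W <- cov_at(NA)
  } else if (model == "BM") {
    lambda_hat <- 1
    W <- cov_at(1)
  } else if (!is.null(lambda)) {
    if (lambda < lambda_bounds[1] || lambda > lambda_bounds[2]) {
      stop(sprintf(
        "lambda = %g outside bounds [%g, %g]",
        lambda, lambda_bounds[1], lambda_bounds[2]
      ), call. = FALSE)
    }
    lambda_hat <- lambda
    W <- cov_at(lambda)
  } else {
    opt <- stats::optimize(function(l) crit(X, y, cov_at(l)),
      interval = lambda_bounds, maximum = TRUE, tol = 1e-6
    )
    # the interior optimum can be beaten at the endpoints by the bracketing
    end_vals <- vapply(lambda_bounds, function(l) crit(X, y, cov_at(l)), 0)
    cand <- c(opt$maximum, lambda_bounds)
    vals <- c(opt$objective, end_vals)
    lambda_hat <- cand[which.max(vals)]
    lambda_estimated <- TRUE
    W <- cov_at(lambda_hat)
  }

  sol <- gls_solve(X, y, W)
  ll <- crit(X, y, W)
  k <- as.integer(p + 1L + lambda_estimated)
  aic <- -2 * ll + 2 * k
  se <- sqrt(diag(sol$cov_beta))
  df <- n - p
  fit <- structure(
    list(
      coefficients = sol$beta,
      std_errors = stats::setNames(se, names(sol$beta)),
      cov_beta = sol$cov_beta,
      lambda = lambda_hat,
      lambda_estimated = lambda_estimated,
      sigma2 = sol$sigma2,
      loglik = ll,
      aic = aic,
      k = k,
      n = n,
      p = p,
      residual_df = df,
      method = method,
      model = model,
      model_tag = attr(Vbm, "model_tag"),
      weights_used = isTRUE(weights_used),
      combine = combine,
      formula = formula,
      taxa = taxa,
      X = X,
      y = y,
      V_bm = Vbm,
      W = W,
      ci_level = ci_level
    ),
    class = "pgls_fit"
  )
  fit$conf_int <- confint_tbl(fit, level = ci_level)
  fit
}

confint_tbl <- function(fit, level) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$residual_df)
  tibble::tibble(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    lower = unname(fit$coefficients - tq * fit$std_errors),
    upper = unname(fit$coefficients + tq * fit$std_errors),
    level = level
  )
}

#' Confidence intervals for a PGLS fit
#'
#' Per-coefficient t intervals, `estimate +/- t(level, n - p) * SE`, matching
#' standard GLS summary semantics.
#'
#' @param object A `pgls_fit`.
#' @param parm Ignored (all coefficients are returned).
#' @param level Confidence level in (0, 1).
#' @param ... Unused.
#' @return A tibble with columns term, estimate, lower, upper, level.
#' @export
confint.pgls_fit <- function(object, parm = NULL, level = 0.95, ...) {
  confint_tbl(object, level)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "PGLS fit (%s, %s): n = %d, lambda = %s, sigma2 = %.4g, AIC = %.2f\n",
    x$model, x$method, x$n,
    if (is.na(x$lambda)) "-" else sprintf("%.3f%s", x$lambda, if (x$lambda_estimated) " (estimated)" else " (fixed)"),
    x$sigma2, x$aic
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy a PGLS fit into a coefficient table
#'
#' @param x A `pgls_fit`.
#' @param conf_level Confidence level for the interval columns.
#' @param ... Unused.
#' @return Tibble with term, estimate, std_error, statistic, p_value,
#'   conf_low, conf_high.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, conf_level = x$ci_level, ...) {
  ci <- confint_tbl(x, conf_level)
  tstat <- unname(x$coefficients / x$std_errors)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(x$std_errors),
    statistic = tstat,
    p_value = 2 * stats::pt(abs(tstat), df = x$residual_df, lower.tail = FALSE),
    conf_low = ci$lower,
    conf_high = ci$upper
  )
}

#' One-row model summary of a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return One-row tibble with n, p, lambda, sigma2, loglik, AIC, method,
#'   model and residual df.
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p, residual_df = x$residual_df,
    lambda = x$lambda, lambda_estimated = x$lambda_estimated,
    sigma2 = x$sigma2, loglik = x$loglik, aic = x$aic,
    method = x$method, model = x$model, weights_used = x$weights_used
  )
}

#' @export
fitted.pgls_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$X %*% object$coefficients), object$taxa)
}

#' @export
residuals.pgls_fit <- function(object, ...) {
  stats::setNames(object$y - fitted(object), object$taxa)
}

#' Compare fitted covariance structures by AIC
#'
#' Ranks fits of the same response/design under different covariance models
#' (star, Brownian, Pagel's lambda) by AIC. Cross-structure comparison
#' requires ML fits (the restricted likelihoods of different covariance
#' structures share the design, so REML comparison is not refused for fits on
#' an identical design, but mixing REML and ML is). Ties are broken by the
#' smaller parameter count, then input order.
#'
#' @param fits List of `pgls_fit` objects on identical `y` and `X`.
#' @return Tibble sorted by AIC with a `delta_aic` column relative to the
#'   best model and a `rank` column.
#' @export
compare_models_aic <- function(fits) {
  if (!length(fits)) stop("`fits` is empty", call. = FALSE)
  if (!all(vapply(fits, inherits, TRUE, "pgls_fit"))) {
    stop("all elements must be pgls_fit objects", call. = FALSE)
  }
  y0 <- fits[[1]]$y
  X0 <- fits[[1]]$X
  for (f in fits[-1]) {
    if (!isTRUE(all.equal(f$y, y0)) || !isTRUE(all.equal(unname(f$X), unname(X0)))) {
      stop("fits compare different responses or designs", call. = FALSE)
    }
  }
  methods <- vapply(fits, `[[`, "", "method")
  if (length(unique(methods)) > 1) {
    stop("mixed estimation methods (REML and ML) cannot be AIC-compared", call. = FALSE)
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, `[[`, "", "model")
  tb <- tibble::tibble(
    name = unname(nm),
    model = unname(vapply(fits, `[[`, "", "model")),
    lambda = unname(vapply(fits, `[[`, 0, "lambda")),
    k = unname(vapply(fits, `[[`, 0L, "k")),
    loglik = unname(vapply(fits, `[[`, 0, "loglik")),
    aic = unname(vapply(fits, `[[`, 0, "aic")),
    input_order = seq_along(fits)
  )
  tb <- dplyr::arrange(tb, .data$aic, .data$k, .data$input_order)
  tb$delta_aic <- tb$aic - tb$aic[1]
  tb$rank <- seq_len(nrow(tb))
  tb
}

#' Serialize a PGLS fit to JSON
#'
#' @param fit A `pgls_fit`.
#' @param file Optional path; when `NULL`, the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
fit_to_json <- function(fit, file = NULL) {
  ci <- fit$conf_int
  obj <- list(
    coefficients = as.list(fit$coefficients),
    std_errors = as.list(fit$std_errors),
    conf_intervals = lapply(seq_len(nrow(ci)), function(i) {
      list(term = ci$term[i], lower = ci$lower[i], upper = ci$upper[i], level = ci$level[i])
    }),
    lambda = if (is.na(fit$lambda)) NULL else fit$lambda,
    lambda_estimated = fit$lambda_estimated,
    sigma2 = fit$sigma2,
    loglik = fit$loglik,
    aic = fit$aic,
    n = fit$n,
    p = fit$p,
    method = fit$method,
    covariance_model = fit$model_tag
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Plot a univariate PGLS fit
#'
#' Scatter of the data with the fitted regression line and its pointwise
#' confidence band; optional literature reference lines can be overlaid.
#'
#' @param object A univariate (intercept + one slope) `pgls_fit`.
#' @param reference Optional data frame with columns `label`, `slope`,
#'   `intercept` for overlay lines (see [amniote_allometries()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pgls_fit
#' @export
autoplot.pgls_fit <- function(object, reference = NULL, ...) {
  if (object$p != 2) {
    stop("autoplot.pgls_fit expects a univariate fit (intercept + slope)", call. = FALSE)
  }
  df <- tibble::tibble(x = object$X[, 2], y = object$y)
  xs <- seq(min(df$x), max(df$x), length.out = 100)
  Xp <- cbind(1, xs)
  pred <- as.numeric(Xp %*% object$coefficients)
  se_pred <- sqrt(rowSums((Xp %*% object$cov_beta) * Xp))
  tq <- stats::qt(1 - (1 - object$ci_level) / 2, object$residual_df)
  band <- tibble::tibble(
    x = xs, y = pred,
    lo = pred - tq * se_pred, hi = pred + tq * se_pred
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(
      data = band, ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "grey80", alpha = 0.7
    ) +
    ggplot2::geom_line(data = band, linewidth = 0.8) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = colnames(object$X)[2], y = "response (log10)",
      subtitle = sprintf(
        "slope = %.3f, lambda = %s", object$coefficients[2],
        if (is.na(object$lambda)) "-" else sprintf("%.2f", object$lambda)
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_abline(
      data = reference,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept, colour = .data$label),
      linetype = "dashed"
    )
  }
  p
}
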