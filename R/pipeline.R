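#' Fit a log-log allometry for one trait in one clade
#'
#' Applies [prepare_traits()] then fits `log10(trait) ~ log10(mass)` either
#' by ordinary least squares (`phylo = FALSE`; GLS with identity covariance)
#' or by PGLS with the clade's tree and Pagel's lambda estimated
#' (`phylo = TRUE`). The tree is pruned to the analyzed taxa first; for
#' non-ultrametric trees fixed-variance weights are engaged automatically.
#'
#' @param table Raw trait table (see [read_trait_table()]).
#' @param trait Trait column name.
#' @param clade Clade name (`"Reptilia"` or `NULL` uses all rows).
#' @param tree `phylo` covering the clade's species; required when
#'   `phylo = TRUE`.
#' @param phylo Logical: correct for phylogeny?
#' @param min_n Minimum number of complete species (default 4); fewer is a
#'   refusal error reporting the count.
#' @param ... Passed to [fit_pgls()] (e.g. `model`, `lambda`, `method`,
#'   `ci_level`, `combine`).
#' @return A `pgls_fit`.
#' @export
fit_allometry <- function(table, trait, clade = NULL, tree = NULL,
                          phylo = TRUE, min_n = 4, ...) {
  dat <- prepare_traits(table, trait, clade)
  if (nrow(dat) < min_n) {
    stop(sprintf(
      "insufficient data for %s%s: %d complete species (need >= %d)",
      trait, if (is.null(clade)) "" else paste0(" in ", clade), nrow(dat), min_n
    ), call. = FALSE)
  }
  if (phylo) {
    if (is.null(tree)) stop("`tree` required when phylo = TRUE", call. = FALSE)
    fit_pgls(dat, log_trait ~ log_mass, tree = tree, ...)
  } else {
    fit_pgls(dat, log_trait ~ log_mass, model = "star", ...)
  }
}

#' Screen an altitude covariate alongside body mass
#'
#' Multivariate regression of a log10 trait on log10 adult mass and log10
#' maximum altitude, without (`phylo = FALSE`) or with phylogenetic
#' correction, so the altitude effect can be judged from its confidence
#' interval.
#'
#' @inheritParams fit_allometry
#' @param min_n Minimum complete cases (default 5).
#' @return A `pgls_fit` with three coefficients.
#' @export
fit_altitude_model <- function(table, trait, clade = NULL, tree = NULL,
                               phylo = TRUE, min_n = 5, ...) {
  tb <- tibble::as_tibble(table)
  if (!"max_altitude_m" %in% names(tb)) {
    stop("no `max_altitude_m` column in table", call. = FALSE)
  }
  zero_alt <- !is.na(tb$max_altitude_m) & tb$max_altitude_m <= 0 &
    !is.na(tb[[trait]])
  if (any(zero_alt)) {
    stop(
      "zero/negative max_altitude_m (log10 undefined) for: ",
      paste(normalize_labels(tb$species[zero_alt]), collapse = ", "),
      call. = FALSE
    )
  }
  dat <- prepare_traits(tb, trait, clade, extra_cols = "max_altitude_m")
  if (nrow(dat) < min_n) {
    stop(sprintf(
      "insufficient data for altitude model on %s: %d complete species (need >= %d)",
      trait, nrow(dat), min_n
    ), call. = FALSE)
  }
  form <- log_trait ~ log_mass + log_max_altitude
  if (phylo) {
    if (is.null(tree)) stop("`tree` required when phylo = TRUE", call. = FALSE)
    fit_pgls(dat, form, tree = tree, ...)
  } else {
    fit_pgls(dat, form, model = "star", ...)
  }
}

#' Compare two clade fits by confidence-interval overlap
#'
#' The study's inference rule: two clades differ in a coefficient iff the
#' 95% confidence intervals of that coefficient are disjoint. Touching
#' endpoints count as overlap (`max(lowers) <= min(uppers)`).
#'
#' @param fit_a,fit_b `pgls_fit` objects for the same trait with the same
#'   design structure (same coefficient names).
#' @param level Confidence level for the intervals.
#' @param trait Optional trait name carried into the output.
#' @param clade_a,clade_b Labels for the two fits.
#' @return A `clade_comparison` tibble: one row per coefficient with both
#'   intervals, the overlap flag, and `difference = !overlap`.
#' @export
compare_clades <- function(fit_a, fit_b, level = 0.95, trait = NA_character_,
                           clade_a = "A", clade_b = "B") {
  if (!identical(names(fit_a$coefficients), names(fit_b$coefficients))) {
    stop("fits have different coefficient sets; cannot compare", call. = FALSE)
  }
  ci_a <- confint_tbl(fit_a, level)
  ci_b <- confint_tbl(fit_b, level)
  out <- tibble::tibble(
    trait = trait,
    clade_a = clade_a,
    clade_b = clade_b,
    term = ci_a$term,
    estimate_a = ci_a$estimate, lower_a = ci_a$lower, upper_a = ci_a$upper,
    estimate_b = ci_b$estimate, lower_b = ci_b$lower, upper_b = ci_b$upper,
    level = level
  )
  out$overlap <- pmax(out$lower_a, out$lower_b) <= pmin(out$upper_a, out$upper_b)
  out$difference <- !out$overlap
  class(out) <- c("clade_comparison", class(out))
  out
}

#' Residual distance of a focal species from a clade regression
#'
#' The value expected for a species of equal body mass from the clade
#' regression minus the focal species' observed value, on the log10 scale:
#' `(i + s * focal_log_mass) - focal_log_trait`. The magnitude locates the
#' focal species relative to competing clade models.
#'
#' @param fit A univariate allometry `pgls_fit` (intercept + mass slope).
#' @param focal_log_mass log10 adult mass of the focal species (g).
#' @param focal_log_trait log10 observed trait value of the focal species.
#' @return Tibble with `predicted`, `observed`, `residual` (signed,
#'   predicted - observed) and `magnitude`.
#' @export
residual_distance <- function(fit, focal_log_mass, focal_log_trait) {
  if (fit$p != 2) {
    stop("residual_distance needs a univariate allometry (intercept + slope); got ",
      fit$p, " coefficients",
      call. = FALSE
    )
  }
  pred <- unname(fit$coefficients[1] + fit$coefficients[2] * focal_log_mass)
  res <- pred - focal_log_trait
  tibble::tibble(
    predicted = pred, observed = focal_log_trait,
    residual = res, magnitude = abs(res)
  )
}

#' Residual profile of a focal species across clades and traits
#'
#' Evaluates [residual_distance()] for every (clade, trait) fit and flags,
#' per trait, the clade whose regression the focal species falls closest to
#' (smallest residual magnitude).
#'
#' @param fits Nested named list: `fits[[clade]][[trait]]` is a univariate
#'   `pgls_fit` (entries may be missing where no model could be fitted).
#' @param focal_species Label for the focal species.
#' @param focal_mass_g Adult mass of the focal species in grams.
#' @param focal_traits Named list/vector of the focal species' trait values
#'   on the original (unlogged) scale; names are trait columns.
#' @return A `residual_profile` tibble with one row per available
#'   (clade, trait) pair and a logical `best_clade` column.
#' @export
residual_profile <- function(fits, focal_species, focal_mass_g, focal_traits) {
  stopifnot(focal_mass_g > 0)
  lm_mass <- log10(focal_mass_g)
  rows <- list()
  for (clade in names(fits)) {
    for (trait in names(fits[[clade]])) {
      fit <- fits[[clade]][[trait]]
      if (is.null(fit) || !trait %in% names(focal_traits)) next
      value <- focal_traits[[trait]]
      if (is.na(value)) next
      rd <- residual_distance(fit, lm_mass, log10(value))
      rows[[length(rows) + 1]] <- tibble::tibble(
        focal_species = focal_species, clade = clade, trait = trait, rd
      )
    }
  }
  if (!length(rows)) stop("no (clade, trait) fit matched the focal traits", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  out <- out |>
    dplyr::group_by(.data$trait) |>
    dplyr::mutate(best_clade = .data$magnitude == min(.data$magnitude)) |>
    dplyr::ungroup()
  class(out) <- c("residual_profile", class(out))
  out
}

#' Plot a clade-comparison table
#'
#' Interval plot of per-clade coefficient CIs, one panel per coefficient,
#' mirroring the usual slope/intercept comparison figures.
#'
#' @param object A `clade_comparison` tibble (rows may span several traits).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clade_comparison
#' @export
autoplot.clade_comparison <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, .data$trait, .data$term,
      clade = .data$clade_a,
      estimate = .data$estimate_a, lower = .data$lower_a, upper = .data$upper_a
    ),
    dplyr::transmute(object, .data$trait, .data$term,
      clade = .data$clade_b,
      estimate = .data$estimate_b, lower = .data$lower_b, upper = .data$upper_b
    )
  ) |> dplyr::distinct()
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$trait, y = .data$estimate,
    ymin = .data$lower, ymax = .data$upper, colour = .data$clade
  )) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "estimate with CI")
}

#' Plot a residual profile
#'
#' Bar chart of residual magnitudes per trait and clade, highlighting the
#' best (closest) clade for each trait.
#'
#' @param object A `residual_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot residual_profile
#' @export
autoplot.residual_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$trait, y = .data$magnitude, fill = .data$clade,
    alpha = .data$best_clade
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.45, `TRUE` = 1), guide = "none") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = NULL, y = "|residual distance| (log10 units)",
      title = unique(object$focal_species)
    )
}
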