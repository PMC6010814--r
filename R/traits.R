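#' Names of the life-history trait columns
#'
#' The nine traits covering the complete life cycle: egg weight (g), clutch
#' size, clutches per year, incubation/gestation time (days), birthweight
#' (g), birth size (total length, cm), age at female maturity (days), size at
#' maturity (cm), and maximum longevity (years).
#'
#' @return Character vector of column names.
#' @export
life_history_traits <- function() {
  c(
    "egg_weight_g", "clutch_size", "clutches_per_year", "incubation_days",
    "birth_weight_g", "birth_size_cm", "female_maturity_days",
    "size_at_maturity_cm", "max_longevity_yr"
  )
}

#' Read a species-by-trait table from CSV
#'
#' Expects columns `species`, `clade`, `adult_weight_g`, any of the
#' [life_history_traits()] columns, and optionally `max_altitude_m`.
#'
#' @param file CSV path.
#' @return A tibble with normalized species labels.
#' @export
read_trait_table <- function(file) {
  tb <- readr::read_csv(file, show_col_types = FALSE)
  required <- c("species", "adult_weight_g")
  miss <- setdiff(required, names(tb))
  if (length(miss)) {
    stop("trait table missing required column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  tb$species <- normalize_labels(as.character(tb$species))
  tb
}

#' Prepare aligned log10 analysis vectors for one trait
#'
#' Applies the study's preprocessing rules: multiple records per species are
#' arithmetically averaged, rows with a missing trait or mass are dropped
#' casewise (per trait), and both the trait and adult mass are
#' log10-transformed. Non-positive values are an error because the log is
#' undefined.
#'
#' @param raw_table Data frame with at least `species`, `adult_weight_g` and
#'   the trait column; multiple rows per species are allowed.
#' @param trait Name of the trait column to analyze.
#' @param clade Optional clade name; rows are filtered to `clade == clade`
#'   first (requires a `clade` column). The clade `"Reptilia"` (or `NULL`)
#'   keeps all rows.
#' @param extra_cols Further columns to average and log10-transform alongside
#'   (e.g. `"max_altitude_m"`).
#' @return Tibble with columns `species`, `log_mass`, `log_trait` (and
#'   `log_<extra>` for each extra column), one row per retained species.
#' @export
prepare_traits <- function(raw_table, trait, clade = NULL, extra_cols = NULL) {
  tb <- tibble::as_tibble(raw_table)
  if (!trait %in% names(tb)) {
    stop("trait column `", trait, "` not found", call. = FALSE)
  }
  if (!is.null(clade) && !identical(clade, "Reptilia")) {
    if (!"clade" %in% names(tb)) stop("no `clade` column to filter on", call. = FALSE)
    tb <- dplyr::filter(tb, .data$clade == !!clade)
  }
  tb$species <- normalize_labels(as.character(tb$species))
  num_cols <- c("adult_weight_g", trait, extra_cols)
  tb <- tb |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(num_cols),
      ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)
    ), .groups = "drop")
  tb <- tb[stats::complete.cases(tb[, num_cols, drop = FALSE]), , drop = FALSE]
  for (col in num_cols) {
    bad <- tb[[col]] <= 0
    if (any(bad)) {
      stop(sprintf(
        "non-positive %s for species %s: log10 undefined",
        col, paste(tb$species[bad], collapse = ", ")
      ), call. = FALSE)
    }
  }
  out <- tibble::tibble(
    species = tb$species,
    log_mass = log10(tb$adult_weight_g),
    log_trait = log10(tb[[trait]])
  )
  for (col in extra_cols %||% character()) {
    out[[paste0("log_", sub("_m$|_g$|_cm$|_days$|_yr$", "", col))]] <- log10(tb[[col]])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mammal and bird literature allometries for comparison overlays
#'
#' Published allometric coefficients (log10-log10 scale) for mammals and
#' birds, used only to overlay reference lines next to fitted reptile
#' allometries; the package never refits these groups. Intercepts are on the
#' same units as the package's trait columns (ages in days, masses in g,
#' lengths in cm), i.e. already transformed where the original sources used
#' other units.
#'
#' @return Tibble with columns trait, group, slope, intercept, source.
#' @export
amniote_allometries <- function() {
  tibble::tribble(
    ~trait, ~group, ~slope, ~intercept, ~source,
    "clutch_size", "birds", 0.06, 0.82, "Werner & Griebeler 2011",
    "clutch_size", "mammals", -0.05, 0.16, "Werner & Griebeler 2011",
    "egg_weight_g", "birds", 0.746, 0, "Martin et al. 2006",
    "female_maturity_days", "birds", 0.303, 1.89, "De Magalhaes et al. 2007",
    "female_maturity_days", "mammals", 0.214, 1.98, "De Magalhaes et al. 2007",
    "incubation_days", "birds", 0.167, 0.96, "Rahn 1975",
    "incubation_days", "mammals", 0.09, 1.72, "Clauss et al. 2014",
    "max_longevity_yr", "mammals", 0.127, 1.18, "Lemaitre et al. 2014 (AnAge)",
    "max_longevity_yr", "birds", 0.218, 0.72, "De Magalhaes et al. 2007",
    "size_at_maturity_cm", "birds", 1, 0, "Charnov 1993",
    "size_at_maturity_cm", "mammals", 1, 0, "Charnov 1993"
  )
}
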