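#' Run the full allometry study pipeline
#'
#' Orchestrates every stage on one trait table and a set of clade trees:
#' per-clade and pooled GLS/PGLS allometric fits for each trait, altitude
#' covariate screening, all pairwise clade comparisons by CI overlap, and a
#' focal-species residual profile. Clades or traits with too few complete
#' species are reported as `"insufficient data"` and the run continues.
#'
#' @param config A list (or path to a YAML/JSON file) with elements:
#'   \describe{
#'     \item{trait_table}{data frame or CSV path (schema of [read_trait_table()]).}
#'     \item{trees}{named list of `phylo` objects or Newick file paths, one
#'       per clade (names must match the `clade` column).}
#'     \item{traits}{character vector of trait columns (default all nine).}
#'     \item{clades}{character vector of clades to fit (default the tree names).}
#'     \item{pooled_clade}{name for the all-species fit on the composite
#'       unit-branch tree (default `"Reptilia"`; `NULL` disables).}
#'     \item{backbone}{Newick string for the composite backbone (default
#'       `"(Squamata,(Testudines,Crocodilia));"`).}
#'     \item{focal}{optional list(species, mass_g, traits = named values) for
#'       the residual profile.}
#'     \item{ci_level}{confidence level (default 0.95).}
#'     \item{lambda_bounds}{lambda search interval (default c(0, 1)).}
#'     \item{screen_altitude}{logical (default TRUE when the table has a
#'       `max_altitude_m` column).}
#'     \item{seed}{integer seed recorded in the manifest (the pipeline itself
#'       is deterministic).}
#'     \item{out_dir}{optional output directory for CSV/JSON artifacts.}
#'   }
#' @return An `allometry_study` list with tibbles `fits`, `altitude`,
#'   `comparisons`, `residuals`, a character `log`, and a `manifest` list.
#' @export
run_study <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- config
  log_lines <- character()
  say <- function(level, ...) {
    line <- paste0("[", level, "] ", sprintf(...))
    log_lines <<- c(log_lines, line)
  }

  table_path <- NULL
  tb <- cfg$trait_table
  if (is.character(tb)) {
    table_path <- tb
    tb <- read_trait_table(tb)
  } else {
    tb <- tibble::as_tibble(tb)
    tb$species <- normalize_labels(as.character(tb$species))
  }
  trees <- cfg$trees %||% list()
  tree_paths <- character()
  trees <- lapply(trees, function(t) {
    if (is.character(t)) {
      tree_paths <<- c(tree_paths, t)
      read_newick(file = t)
    } else {
      t
    }
  })
  traits <- cfg$traits %||% intersect(life_history_traits(), names(tb))
  clades <- cfg$clades %||% names(trees)
  pooled <- if ("pooled_clade" %in% names(cfg)) cfg$pooled_clade else "Reptilia"
  ci_level <- cfg$ci_level %||% 0.95
  lambda_bounds <- cfg$lambda_bounds %||% c(0, 1)
  seed <- cfg$seed %||% NA_integer_
  say("INFO", "study start: %d traits, %d clades, %d species rows", length(traits), length(clades), nrow(tb))

  # composite unit-branch tree for the pooled fit
  composite <- NULL
  if (!is.null(pooled) && length(trees) >= 1) {
    backbone <- cfg$backbone %||% "(Squamata,(Testudines,Crocodilia));"
    bb <- suppressWarnings(read_newick(backbone))
    usable <- trees[intersect(bb$tip.label, names(trees))]
    if (length(usable) == length(bb$tip.label)) {
      composite <- build_composite(bb, usable, mode = "unit-all")
      say("INFO", "composite tree built: %d tips, unit branch lengths", length(composite$tip.label))
    } else {
      say("WARNING", "composite skipped: backbone tips without trees")
    }
  }

  clade_tree <- function(clade) {
    if (!is.null(pooled) && identical(clade, pooled)) composite else trees[[clade]]
  }
  fit_units <- tidyr::expand_grid(
    clade = c(clades, if (!is.null(composite)) pooled),
    trait = traits,
    phylo = c(FALSE, TRUE)
  )

  all_fits <- list() # keyed clade|trait, PGLS only (for residual profile)
  fit_rows <- purrr::pmap(fit_units, function(clade, trait, phylo) {
    tr <- clade_tree(clade)
    fit <- tryCatch(
      fit_allometry(tb, trait, clade = clade, tree = tr,
        phylo = phylo, ci_level = ci_level, lambda_bounds = lambda_bounds
      ),
      error = function(e) conditionMessage(e)
    )
    method_lab <- if (phylo) "PGLS" else "GLS"
    if (is.character(fit)) {
      say("WARNING", "%s %s / %s: %s", method_lab, clade, trait, fit)
      return(tibble::tibble(
        clade = clade, trait = trait, method = method_lab,
        status = if (grepl("insufficient data", fit)) "insufficient data" else "error",
        n = NA_integer_, intercept = NA_real_, slope = NA_real_,
        se_intercept = NA_real_, se_slope = NA_real_,
        ci_intercept_lower = NA_real_, ci_intercept_upper = NA_real_,
        ci_slope_lower = NA_real_, ci_slope_upper = NA_real_,
        lambda = NA_real_, sigma2 = NA_real_, loglik = NA_real_, aic = NA_real_
      ))
    }
    if (phylo) all_fits[[paste(clade, trait, sep = "|")]] <<- fit
    ci <- fit$conf_int
    tibble::tibble(
      clade = clade, trait = trait, method = method_lab, status = "ok",
      n = fit$n,
      intercept = unname(fit$coefficients[1]), slope = unname(fit$coefficients[2]),
      se_intercept = unname(fit$std_errors[1]), se_slope = unname(fit$std_errors[2]),
      ci_intercept_lower = ci$lower[1], ci_intercept_upper = ci$upper[1],
      ci_slope_lower = ci$lower[2], ci_slope_upper = ci$upper[2],
      lambda = fit$lambda, sigma2 = fit$sigma2, loglik = fit$loglik, aic = fit$aic
    )
  })
  fits_tbl <- dplyr::bind_rows(fit_rows)

  # altitude screening
  altitude_tbl <- tibble::tibble()
  screen_alt <- cfg$screen_altitude %||% ("max_altitude_m" %in% names(tb))
  if (isTRUE(screen_alt) && "max_altitude_m" %in% names(tb)) {
    alt_units <- tidyr::expand_grid(
      clade = c(clades, if (!is.null(composite)) pooled),
      trait = traits, phylo = c(FALSE, TRUE)
    )
    altitude_tbl <- dplyr::bind_rows(purrr::pmap(alt_units, function(clade, trait, phylo) {
      fit <- tryCatch(
        fit_altitude_model(tb, trait, clade = clade, tree = clade_tree(clade),
          phylo = phylo, ci_level = ci_level, lambda_bounds = lambda_bounds
        ),
        error = function(e) conditionMessage(e)
      )
      method_lab <- if (phylo) "PGLS" else "GLS"
      if (is.character(fit)) {
        return(tibble::tibble(
          clade = clade, trait = trait, method = method_lab,
          status = if (grepl("insufficient data", fit)) "insufficient data" else "error",
          n = NA_integer_, altitude_coef = NA_real_,
          altitude_ci_lower = NA_real_, altitude_ci_upper = NA_real_,
          altitude_effect = NA
        ))
      }
      ci <- fit$conf_int
      i <- match("log_max_altitude", ci$term)
      tibble::tibble(
        clade = clade, trait = trait, method = method_lab, status = "ok",
        n = fit$n, altitude_coef = ci$estimate[i],
        altitude_ci_lower = ci$lower[i], altitude_ci_upper = ci$upper[i],
        altitude_effect = !(ci$lower[i] <= 0 & ci$upper[i] >= 0)
      )
    }))
    say("INFO", "altitude screening done: %d models", nrow(altitude_tbl))
  }

  # pairwise clade comparisons (PGLS fits)
  comparisons <- tibble::tibble()
  if (length(clades) >= 2) {
    pairs <- utils::combn(clades, 2, simplify = FALSE)
    comparisons <- dplyr::bind_rows(purrr::map(pairs, function(pr) {
      dplyr::bind_rows(purrr::map(traits, function(trait) {
        fa <- all_fits[[paste(pr[1], trait, sep = "|")]]
        fb <- all_fits[[paste(pr[2], trait, sep = "|")]]
        if (is.null(fa) || is.null(fb)) {
          return(tibble::tibble(
            trait = trait, clade_a = pr[1], clade_b = pr[2],
            term = NA_character_, status = "insufficient data"
          ))
        }
        cmp <- compare_clades(fa, fb, level = ci_level, trait = trait,
          clade_a = pr[1], clade_b = pr[2]
        )
        cmp$status <- "ok"
        cmp
      }))
    }))
    say("INFO", "clade comparisons done")
  }

  # focal-species residual profile
  residuals_tbl <- tibble::tibble()
  if (!is.null(cfg$focal)) {
    focal <- cfg$focal
    fits_by_clade <- list()
    for (clade in clades) {
      fits_by_clade[[clade]] <- list()
      for (trait in traits) {
        f <- all_fits[[paste(clade, trait, sep = "|")]]
        if (!is.null(f)) fits_by_clade[[clade]][[trait]] <- f
      }
    }
    residuals_tbl <- tryCatch(
      residual_profile(fits_by_clade, focal$species, focal$mass_g, focal$traits),
      error = function(e) {
        say("ERROR", "residual profile: %s", conditionMessage(e))
        tibble::tibble()
      }
    )
    if (nrow(residuals_tbl)) say("INFO", "residual profile computed for %s", focal$species)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("allophy")),
    r_version = as.character(getRversion()),
    seed = seed,
    ci_level = ci_level,
    lambda_bounds = lambda_bounds,
    traits = traits,
    clades = clades,
    input_files = c(table_path, tree_paths),
    input_md5 = if (length(c(table_path, tree_paths))) {
      as.list(tools::md5sum(c(table_path, tree_paths)))
    } else {
      list()
    }
  )

  out <- structure(
    list(
      fits = fits_tbl, altitude = altitude_tbl, comparisons = comparisons,
      residuals = residuals_tbl, log = log_lines, manifest = manifest
    ),
    class = "allometry_study"
  )
  if (!is.null(cfg$out_dir)) write_study(out, cfg$out_dir)
  out
}

#' Write study artifacts to a directory
#'
#' CSV fit/altitude/comparison tables, a JSON residual profile, the run log
#' and a JSON manifest. Numbers are serialized at full precision so reruns
#' with identical inputs are byte-identical.
#'
#' @param study An `allometry_study` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$fits, file.path(dir, "fit_table.csv"))
  if (nrow(study$altitude)) {
    readr::write_csv(study$altitude, file.path(dir, "altitude_screening.csv"))
  }
  if (nrow(study$comparisons)) {
    readr::write_csv(study$comparisons, file.path(dir, "clade_comparisons.csv"))
  }
  if (nrow(study$residuals)) {
    jsonlite::write_json(study$residuals, file.path(dir, "residual_profile.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  writeLines(study$log, file.path(dir, "run_log.txt"))
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @export
print.allometry_study <- function(x, ...) {
  ok <- sum(x$fits$status == "ok")
  cat(sprintf(
    "Allometry study: %d fits (%d ok), %d comparisons, %d residual rows\n",
    nrow(x$fits), ok, nrow(x$comparisons), nrow(x$residuals)
  ))
  invisible(x)
}
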