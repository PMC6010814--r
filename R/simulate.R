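# Simulators emulating the statistical structure the analysis assumes:
# pure-birth trees, Brownian traits with lambda-damped covariance, and
# allometric datasets trait = i + s * log10(mass) + correlated error.
# All are pure functions of (arguments, seed).

#' Validate and assemble a simulation configuration
#'
#' @param n_tips Number of species (>= 4).
#' @param birth_rate Speciation rate of the pure-birth tree (per unit time).
#' @param s_true True allometric slope (default 0.75).
#' @param i_true True intercept on the log10 scale.
#' @param sigma2 Brownian rate (trait variance per unit branch length);
#'   0 is allowed as the exact noiseless limit.
#' @param lambda_true Pagel's lambda of the generating process, in \[0, 1\].
#' @param mass_log10_range Range of log10 adult mass (g); the default spans
#'   five orders of magnitude, matching the span of the reptile clades.
#' @param altitude_effect Optional coefficient of log10 maximum altitude;
#'   `NULL` omits the covariate.
#' @param missing_fraction Fraction of trait values knocked out completely at
#'   random, in \[0, 1).
#' @param seed Integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_tips = 128, birth_rate = 1, s_true = 0.75,
                       i_true = 0, sigma2 = 0.1, lambda_true = 0.8,
                       mass_log10_range = c(0, 5), altitude_effect = NULL,
                       missing_fraction = 0, seed = 1) {
  stopifnot(
    n_tips >= 4, birth_rate > 0, sigma2 >= 0,
    lambda_true >= 0, lambda_true <= 1,
    missing_fraction >= 0, missing_fraction < 1,
    length(mass_log10_range) == 2, diff(mass_log10_range) >= 0
  )
  structure(
    list(
      n_tips = as.integer(n_tips), birth_rate = birth_rate, s_true = s_true,
      i_true = i_true, sigma2 = sigma2, lambda_true = lambda_true,
      mass_log10_range = mass_log10_range, altitude_effect = altitude_effect,
      missing_fraction = missing_fraction, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Constant-rate birth process: exponential waiting times between speciation
#' events, run until `n_tips` lineages. Reproducible under `seed`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_pure_birth_tree <- function(n_tips, birth_rate = 1, seed = 1) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  set.seed(seed)
  ape::rphylo(n_tips, birth = birth_rate, death = 0)
}

#' Simulate Brownian traits with lambda-damped covariance on a tree
#'
#' One draw from `MVN(root_state * 1, sigma2 * V_lambda)` where `V_lambda` is
#' the Brownian matrix of the tree with off-diagonals scaled by `lambda`
#' (see [apply_lambda()]). Uses a Cholesky transform of the exact covariance.
#'
#' @param tree A `phylo` with positive root-to-tip depths.
#' @param sigma2 Brownian rate (>= 0; 0 returns `root_state` for every tip).
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param root_state Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, lambda = 1, root_state = 0, seed = 1) {
  stopifnot(sigma2 >= 0, lambda >= 0, lambda <= 1)
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    return(stats::setNames(rep(root_state, n), tree$tip.label))
  }
  V <- apply_lambda(phylo_vcv(tree), lambda)
  S <- sigma2 * unclass(V)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    # lambda in [0,1] keeps S PSD; fall back to an eigen square root for
    # numerically singular cases (e.g. zero-length cherries)
    eg <- eigen(S, symmetric = TRUE)
    if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
      stop("internal error: simulated covariance is not PSD", call. = FALSE)
    }
    R <- t(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors)))
  }
  set.seed(seed)
  z <- stats::rnorm(n)
  stats::setNames(root_state + as.numeric(crossprod(R, z)), tree$tip.label)
}

#' Simulate a species-by-trait dataset with allometric structure
#'
#' Draws log10 masses uniformly over `mass_log10_range` (or evolves them by
#' Brownian motion on the tree with `mass_mode = "bm"`), builds
#' `log10 trait = i + s * log10(mass) (+ b_alt * log10(altitude)) + eps` with
#' `eps ~ MVN(0, sigma2 * V_lambda)`, back-transforms to positive trait
#' values, and applies completely-at-random missingness. The optional
#' altitude covariate is drawn independently of the trait error.
#'
#' @param config A [sim_config()].
#' @param tree Optional `phylo`; simulated from the config when `NULL`.
#' @param trait_name Column name for the simulated trait.
#' @param clade Value for the `clade` column of the output.
#' @param mass_mode `"uniform"` (default) or `"bm"`.
#' @return A tibble with columns `species`, `clade`, `adult_weight_g`,
#'   `<trait_name>` and (if configured) `max_altitude_m`; the tree used is
#'   attached as attribute `"tree"`.
#' @export
simulate_allometric_dataset <- function(config, tree = NULL,
                                        trait_name = "trait_value",
                                        clade = "SimClade",
                                        mass_mode = c("uniform", "bm")) {
  mass_mode <- match.arg(mass_mode)
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree)) {
    tree <- simulate_pure_birth_tree(config$n_tips, config$birth_rate,
      seed = config$seed
    )
  }
  n <- length(tree$tip.label)
  # deterministic sub-streams per component, derived from the root seed
  seeds <- config$seed + c(mass = 101L, alt = 202L, err = 303L, miss = 404L)
  if (mass_mode == "uniform") {
    set.seed(seeds[["mass"]])
    log_mass <- stats::runif(n, config$mass_log10_range[1], config$mass_log10_range[2])
  } else {
    mid <- mean(config$mass_log10_range)
    scale2 <- (diff(config$mass_log10_range) / 4)^2 /
      max(mean(root_to_tip(tree)), .Machine$double.eps)
    log_mass <- simulate_bm_traits(tree,
      sigma2 = scale2, lambda = 1,
      root_state = mid, seed = seeds[["mass"]]
    )
  }
  log_trait <- config$i_true + config$s_true * log_mass
  alt <- NULL
  if (!is.null(config$altitude_effect)) {
    set.seed(seeds[["alt"]])
    log_alt <- stats::runif(n, 1, 3.5) # 10 m to ~3000 m
    log_trait <- log_trait + config$altitude_effect * log_alt
    alt <- 10^log_alt
  }
  eps <- simulate_bm_traits(tree,
    sigma2 = config$sigma2, lambda = config$lambda_true,
    root_state = 0, seed = seeds[["err"]]
  )
  log_trait <- log_trait + unname(eps)
  out <- tibble::tibble(
    species = tree$tip.label,
    clade = clade,
    adult_weight_g = 10^log_mass,
    !!trait_name := 10^log_trait
  )
  if (!is.null(alt)) out$max_altitude_m <- alt
  if (config$missing_fraction > 0) {
    set.seed(seeds[["miss"]])
    drop <- stats::runif(n) < config$missing_fraction
    out[[trait_name]][drop] <- NA_real_
  }
  attr(out, "tree") <- tree
  out
}

#' Parameter-recovery experiment over a grid of simulation settings
#'
#' For each grid cell, repeatedly simulates a tree + dataset, fits the PGLS
#' allometry with lambda estimated by REML, and (optionally) runs ML
#' model selection over {star, BM, lambda}. Summaries are reproducible from
#' the seeds: replicate r of cell c uses seed `seed + 1000 * c + r`.
#'
#' @param grid Data frame whose columns override [sim_config()] arguments
#'   (e.g. `n_tips`, `lambda_true`, `s_true`, `sigma2`); one row per cell.
#' @param n_reps Replicates per cell.
#' @param seed Root seed.
#' @param select_models Also run AIC model selection (slower)?
#' @param ci_level Level of the slope interval used for coverage.
#' @return Tibble: one row per cell with mean/sd of slope, intercept and
#'   lambda estimates, slope CI coverage, and (optionally) the fraction of
#'   replicates where each covariance model ranked best and where the star
#'   model was within delta AIC <= 2 of the best.
#' @export
recovery_experiment <- function(grid, n_reps = 100, seed = 1,
                                select_models = FALSE, ci_level = 0.95) {
  grid <- tibble::as_tibble(grid)
  if (!nrow(grid)) stop("empty simulation grid", call. = FALSE)
  purrr::map_dfr(seq_len(nrow(grid)), function(ci) {
    cell <- as.list(grid[ci, ])
    reps <- purrr::map(seq_len(n_reps), function(r) {
      cfg <- do.call(sim_config, c(cell, list(seed = seed + 1000L * ci + r)))
      dat <- simulate_allometric_dataset(cfg)
      tr <- attr(dat, "tree")
      dat$log_mass <- log10(dat$adult_weight_g)
      dat$log_trait <- log10(dat$trait_value)
      fit <- fit_pgls(dat, log_trait ~ log_mass, tree = tr,
        model = "lambda", method = "REML", ci_level = ci_level
      )
      ci_slope <- fit$conf_int[fit$conf_int$term == "log_mass", ]
      # machine-level slack so the degenerate zero-width interval of an
      # exact noiseless fit still counts as covering the truth
      eps <- 1e-10 * max(1, abs(cfg$s_true))
      res <- list(
        slope = unname(fit$coefficients["log_mass"]),
        intercept = unname(fit$coefficients["(Intercept)"]),
        lambda = fit$lambda,
        covered = ci_slope$lower - eps <= cfg$s_true &&
          cfg$s_true <= ci_slope$upper + eps
      )
      if (select_models) {
        fits <- list(
          star = fit_pgls(dat, log_trait ~ log_mass, model = "star", method = "ML"),
          BM = fit_pgls(dat, log_trait ~ log_mass, tree = tr, model = "BM", method = "ML"),
          lambda = fit_pgls(dat, log_trait ~ log_mass, tree = tr, model = "lambda", method = "ML")
        )
        rk <- compare_models_aic(fits)
        res$best_model <- rk$name[1]
        res$star_delta <- rk$delta_aic[rk$name == "star"]
      }
      res
    })
    out <- tibble::tibble(
      !!!cell,
      n_reps = n_reps,
      slope_mean = mean(purrr::map_dbl(reps, "slope")),
      slope_sd = stats::sd(purrr::map_dbl(reps, "slope")),
      intercept_mean = mean(purrr::map_dbl(reps, "intercept")),
      intercept_sd = stats::sd(purrr::map_dbl(reps, "intercept")),
      lambda_mean = mean(purrr::map_dbl(reps, "lambda")),
      lambda_median = stats::median(purrr::map_dbl(reps, "lambda")),
      coverage = mean(purrr::map_lgl(reps, "covered"))
    )
    if (select_models) {
      best <- purrr::map_chr(reps, "best_model")
      out$frac_best_star <- mean(best == "star")
      out$frac_best_bm <- mean(best == "BM")
      out$frac_best_lambda <- mean(best == "lambda")
      out$frac_star_competitive <- mean(purrr::map_dbl(reps, "star_delta") <= 2)
    }
    out
  })
}

#' Write a complete synthetic mini-study directory
#'
#' Emits the same artifacts the pipeline consumes: one trait CSV covering
#' several clades (each simulated on its own tree with its own true
#' parameters) and one Newick file per clade. The generated table includes a
#' focal species row usable for residual profiling.
#'
#' @param dir Output directory.
#' @param n_per_clade Tips per simulated clade.
#' @param clades Clade names (default the three reptile clades).
#' @param slopes,intercepts True per-clade parameters (recycled).
#' @param sigma2,lambda_true Shared noise parameters.
#' @param seed Root seed.
#' @return List with paths `trait_csv` and `trees` (named), invisibly a
#'   description of the truth used.
#' @export
write_study_fixture <- function(dir, n_per_clade = 24,
                                clades = c("Squamata", "Testudines", "Crocodilia"),
                                slopes = c(0.25, 0.45, 0.65),
                                intercepts = c(0.4, 0.0, -0.4),
                                sigma2 = 0.05, lambda_true = 0.8, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slopes <- rep_len(slopes, length(clades))
  intercepts <- rep_len(intercepts, length(clades))
  tabs <- list()
  tree_paths <- character()
  for (k in seq_along(clades)) {
    cfg <- sim_config(
      n_tips = n_per_clade, s_true = slopes[k], i_true = intercepts[k],
      sigma2 = sigma2, lambda_true = lambda_true, seed = seed + 17L * k
    )
    dat <- simulate_allometric_dataset(cfg, clade = clades[k])
    tr <- attr(dat, "tree")
    tr$tip.label <- paste0(clades[k], "_", tr$tip.label)
    dat$species <- paste0(clades[k], "_", dat$species)
    p <- file.path(dir, paste0(tolower(clades[k]), ".nwk"))
    write_newick(tr, p)
    tree_paths[clades[k]] <- p
    tabs[[k]] <- dat
  }
  tb <- dplyr::bind_rows(tabs)
  csv <- file.path(dir, "traits.csv")
  readr::write_csv(tb, csv)
  invisible(list(
    trait_csv = csv, trees = tree_paths,
    truth = tibble::tibble(
      clade = clades, slope = slopes, intercept = intercepts,
      sigma2 = sigma2, lambda = lambda_true
    )
  ))
}
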