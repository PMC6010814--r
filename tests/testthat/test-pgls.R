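test_that("star-model and lambda = 0 fits reproduce OLS coefficients", {
  cfg <- sim_config(n_tips = 24, seed = 8)
  dat <- sim_fit_data(cfg)
  tr <- attr(dat, "tree")
  ols <- lm(log_trait ~ log_mass, data = dat)

  star <- fit_pgls(dat, log_trait ~ log_mass, model = "star")
  expect_equal(unname(star$coefficients), unname(coef(ols)), tolerance = 1e-10)

  lam0 <- fit_pgls(dat, log_trait ~ log_mass, tree = tr, lambda = 0)
  expect_equal(unname(lam0$coefficients), unname(coef(ols)), tolerance = 1e-8)

  # data simulated on a star tree: estimated-lambda fit equals OLS too
  star_tree <- read_newick(paste0(
    "(", paste0(dat$species, ":1", collapse = ","), ");"
  ))
  flat <- fit_pgls(dat, log_trait ~ log_mass, tree = star_tree)
  expect_equal(unname(flat$coefficients), unname(coef(ols)), tolerance = 1e-8)
})

test_that("fit_pgls matches nlme::gls with corPagel on an ultrametric tree", {
  skip_if_not_installed("nlme")
  cfg <- sim_config(n_tips = 48, lambda_true = 0.7, seed = 7)
  dat <- sim_fit_data(cfg)
  tr <- attr(dat, "tree")
  mine <- fit_pgls(dat, log_trait ~ log_mass, tree = tr)
  df <- as.data.frame(dat)
  rownames(df) <- df$species
  ref <- nlme::gls(log_trait ~ log_mass,
    data = df,
    correlation = ape::corPagel(0.5, phy = tr, form = ~species), method = "REML"
  )
  expect_equal(unname(mine$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(mine$std_errors), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  lam_ref <- as.numeric(coef(ref$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(mine$lambda, lam_ref, tolerance = 1e-4)
  iv <- nlme::intervals(ref)$coef
  expect_equal(mine$conf_int$lower, unname(iv[, "lower"]), tolerance = 1e-5)
  expect_equal(mine$conf_int$upper, unname(iv[, "upper"]), tolerance = 1e-5)
})

test_that("stored loglik, AIC and parameter count are mutually consistent", {
  cfg <- sim_config(n_tips = 32, seed = 10)
  dat <- sim_fit_data(cfg)
  tr <- attr(dat, "tree")
  for (fit in list(
    fit_pgls(dat, log_trait ~ log_mass, tree = tr),
    fit_pgls(dat, log_trait ~ log_mass, tree = tr, model = "BM", method = "ML"),
    fit_pgls(dat, log_trait ~ log_mass, model = "star")
  )) {
    expect_identical(fit$aic, -2 * fit$loglik + 2 * fit$k)
    expect_identical(fit$k, fit$p + 1L + as.integer(fit$lambda_estimated))
    expect_identical(fit$residual_df, fit$n - fit$p)
    expect_gte(fit$sigma2, 0)
  }
})

test_that("confidence intervals use the t distribution on n - p df", {
  cfg <- sim_config(n_tips = 10, seed = 12)
  dat <- sim_fit_data(cfg)
  fit <- fit_pgls(dat, log_trait ~ log_mass, model = "star")
  ci <- confint(fit, level = 0.95)
  # independent quantile: invert pt numerically instead of calling qt
  tq <- uniroot(function(q) pt(q, df = 8) - 0.975, c(0.1, 50), tol = 1e-10)$root
  expect_equal(ci$upper - ci$estimate, tq * unname(fit$std_errors), tolerance = 1e-6)
  expect_true(all(ci$lower < ci$estimate & ci$estimate < ci$upper))

  wider <- confint(fit, level = 0.99)
  expect_true(all(wider$lower < ci$lower & wider$upper > ci$upper))
  expect_error(confint(fit, level = 1.2), "level")
})

test_that("lambda estimates respond monotonically to the true signal", {
  # REML lambda at n = 32 may be biased; assert only that the median
  # estimate is nondecreasing in the generating lambda
  meds <- vapply(c(0, 0.5, 1), function(lam) {
    est <- vapply(1:40, function(r) {
      cfg <- sim_config(n_tips = 32, lambda_true = lam, seed = 900 + 37 * r)
      dat <- sim_fit_data(cfg)
      fit_pgls(dat, log_trait ~ log_mass, tree = attr(dat, "tree"))$lambda
    }, 0)
    median(est)
  }, 0)
  expect_true(all(diff(meds) >= -1e-8))
})

test_that("compare_models_aic ranks, ties and refuses mixed inputs", {
  cfg <- sim_config(n_tips = 40, seed = 14)
  dat <- sim_fit_data(cfg)
  tr <- attr(dat, "tree")
  f_star <- fit_pgls(dat, log_trait ~ log_mass, model = "star", method = "ML")
  f_bm <- fit_pgls(dat, log_trait ~ log_mass, tree = tr, model = "BM", method = "ML")
  rk <- compare_models_aic(list(star = f_star, BM = f_bm))
  expect_equal(rk$delta_aic[1], 0)
  expect_equal(rk$aic, sort(rk$aic))

  # identical model twice: tie broken by parameter count then input order
  f_lam <- fit_pgls(dat, log_trait ~ log_mass, tree = tr, model = "lambda", method = "ML")
  f_bm2 <- f_bm
  tie <- compare_models_aic(list(a = f_bm, b = f_bm2))
  expect_equal(tie$name, c("a", "b"))
  expect_equal(tie$delta_aic, c(0, 0))

  f_reml <- fit_pgls(dat, log_trait ~ log_mass, tree = tr, model = "BM", method = "REML")
  expect_error(compare_models_aic(list(f_star, f_reml)), "mixed estimation")

  other <- sim_fit_data(sim_config(n_tips = 40, seed = 999))
  f_other <- fit_pgls(other, log_trait ~ log_mass, model = "star", method = "ML")
  expect_error(compare_models_aic(list(f_star, f_other)), "different responses")
})

test_that("fixed-variance weights engage on non-ultrametric trees", {
  set.seed(16)
  tr <- ape::rtree(30)
  cfg <- sim_config(n_tips = 30, seed = 16)
  dat <- sim_fit_data(cfg, tree = tr)
  fit <- fit_pgls(dat, log_trait ~ log_mass, tree = tr)
  expect_true(fit$weights_used)
  expect_equal(diag(fit$W), fixed_variance_weights(fit$V_bm)[fit$taxa])

  # weights-only mode drops the correlation entirely
  fit_d <- fit_pgls(dat, log_trait ~ log_mass, tree = tr, combine = "weights-only")
  expect_equal(unclass(fit_d$W), diag(diag(fit_d$W)), ignore_attr = TRUE)

  # ultrametric tree: no weights
  fit_u <- fit_pgls(sim_fit_data(sim_config(n_tips = 20, seed = 17)),
    log_trait ~ log_mass,
    tree = attr(sim_fit_data(sim_config(n_tips = 20, seed = 17)), "tree")
  )
  expect_false(fit_u$weights_used)
})

test_that("fit_pgls errors on non-overlapping taxa and tiny samples", {
  cfg <- sim_config(n_tips = 8, seed = 18)
  dat <- sim_fit_data(cfg)
  tr <- attr(dat, "tree")
  dat_bad <- dat
  dat_bad$species[1] <- "Not_in_tree"
  expect_error(fit_pgls(dat_bad, log_trait ~ log_mass, tree = tr), "absent from tree")
  expect_error(
    fit_pgls(dat[1:3, ], log_trait ~ log_mass, tree = tr),
    "insufficient data"
  )
})

test_that("fit serialization as JSON round-trips the key quantities", {
  cfg <- sim_config(n_tips = 16, seed = 19)
  dat <- sim_fit_data(cfg)
  fit <- fit_pgls(dat, log_trait ~ log_mass, tree = attr(dat, "tree"))
  parsed <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(parsed$coefficients$log_mass, unname(fit$coefficients["log_mass"]))
  expect_equal(parsed$lambda, fit$lambda)
  expect_equal(parsed$aic, fit$aic)
  expect_equal(parsed$n, fit$n)
})

test_that("tidy, glance and autoplot provide the broom-style surface", {
  cfg <- sim_config(n_tips = 20, seed = 20)
  dat <- sim_fit_data(cfg)
  fit <- fit_pgls(dat, log_trait ~ log_mass, tree = attr(dat, "tree"))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error", "statistic", "p_value", "conf_low", "conf_high"))
  gl <- glance(fit)
  expect_equal(gl$n, 20L)
  p <- autoplot(fit, reference = dplyr::transmute(
    amniote_allometries()[1:2, ],
    label = group, slope, intercept
  ))
  expect_s3_class(p, "ggplot")
})
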