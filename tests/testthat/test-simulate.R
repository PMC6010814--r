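test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_tips = 3))
  expect_error(sim_config(sigma2 = -0.1))
  expect_error(sim_config(lambda_true = 1.5))
  expect_error(sim_config(missing_fraction = 1))
})

test_that("pure-birth trees are ultrametric, sized and reproducible", {
  tr <- simulate_pure_birth_tree(2, seed = 1)
  expect_equal(length(tr$tip.label), 2L)
  expect_true(is_ultrametric(tr))

  tr1 <- simulate_pure_birth_tree(25, seed = 4)
  tr2 <- simulate_pure_birth_tree(25, seed = 4)
  expect_identical(write_newick(tr1), write_newick(tr2))
  expect_true(is_ultrametric(tr1, tol = 1e-6))
})

test_that("pure-birth depth matches an independent Monte-Carlo expectation", {
  # independent forward-time Yule simulation of the same process: the
  # root-to-tip depth is the time to go from 2 to n lineages, a sum of
  # exponential waits with rates k*b for k = 2..n-1
  yule_depth_mc <- function(n, b, reps, seed) {
    set.seed(seed)
    vapply(seq_len(reps), function(r) {
      sum(rexp(n - 2, rate = b * (2:(n - 1))))
    }, 0)
  }
  n <- 40
  depths <- vapply(1:80, function(r) {
    max(root_to_tip(simulate_pure_birth_tree(n, 1, seed = 5000 + r)))
  }, 0)
  mc <- yule_depth_mc(n, 1, 2000, seed = 99)
  se <- sqrt(var(depths) / length(depths) + var(mc) / length(mc))
  expect_lt(abs(mean(depths) - mean(mc)), 3 * se)
})

test_that("simulate_bm_traits moments match theory", {
  tr <- simulate_pure_birth_tree(16, seed = 6)

  # degenerate limit
  expect_equal(
    unname(simulate_bm_traits(tr, sigma2 = 0, root_state = 2, seed = 1)),
    rep(2, 16)
  )

  # lambda = 0: tips independent, variance = sigma2 * depth
  depth <- mean(root_to_tip(tr))
  vars <- vapply(1:1000, function(r) {
    var(simulate_bm_traits(tr, sigma2 = 0.5, lambda = 0, seed = r))
  }, 0)
  expect_equal(mean(vars), 0.5 * depth, tolerance = 0.1)

  # sister-pair covariance = sigma2 * lambda * shared depth
  tr2 <- read_newick("((A:1,B:1):1,C:2);")
  draws <- t(vapply(
    1:2000,
    function(r) simulate_bm_traits(tr2, sigma2 = 1, lambda = 0.6, seed = 10000 + r),
    setNames(numeric(3), tr2$tip.label)
  ))
  expect_equal(cov(draws[, "A"], draws[, "B"]), 0.6 * 1, tolerance = 0.12)
  expect_equal(cov(draws[, "A"], draws[, "C"]), 0, tolerance = 0.12)
})

test_that("simulators are pure functions of (config, seed)", {
  cfg <- sim_config(n_tips = 20, missing_fraction = 0.2, seed = 42)
  d1 <- simulate_allometric_dataset(cfg)
  d2 <- simulate_allometric_dataset(cfg)
  expect_identical(d1$adult_weight_g, d2$adult_weight_g)
  expect_identical(d1$trait_value, d2$trait_value)
  d3 <- simulate_allometric_dataset(sim_config(n_tips = 20, missing_fraction = 0.2, seed = 43))
  expect_false(identical(d1$trait_value, d3$trait_value))
})

test_that("noiseless datasets lie exactly on the generating line", {
  cfg <- sim_config(n_tips = 16, sigma2 = 1e-12, s_true = 0.6, i_true = -0.25, seed = 3)
  dat <- sim_fit_data(cfg)
  fit <- fit_pgls(dat, log_trait ~ log_mass, model = "star")
  expect_equal(unname(fit$coefficients), c(-0.25, 0.6), tolerance = 1e-5)
  expect_equal(fit$sigma2, 0, tolerance = 1e-10)
})

test_that("missingness thins the analyzable sample binomially", {
  cfg <- sim_config(n_tips = 200, missing_fraction = 0.3, seed = 77)
  dat <- simulate_allometric_dataset(cfg)
  n_obs <- sum(!is.na(dat$trait_value))
  expect_lt(abs(n_obs - 140), 3 * sqrt(200 * 0.3 * 0.7) + 1)
  prep <- prepare_traits(dat, "trait_value")
  expect_equal(nrow(prep), n_obs)
})

test_that("altitude covariate enters the generative model when configured", {
  cfg <- sim_config(
    n_tips = 150, sigma2 = 0.01, altitude_effect = 0.4, seed = 21
  )
  dat <- sim_fit_data(cfg)
  expect_true("max_altitude_m" %in% names(dat))
  fit <- fit_altitude_model(dat, "trait_value", phylo = FALSE)
  est <- fit$coefficients[["log_max_altitude"]]
  expect_equal(est, 0.4, tolerance = 0.1)
})

test_that("recovery_experiment summarizes cells reproducibly and sd shrinks with n", {
  grid <- tibble::tibble(n_tips = c(32, 128), sigma2 = 0.1)
  res <- recovery_experiment(grid, n_reps = 25, seed = 5)
  expect_equal(nrow(res), 2)
  expect_lt(res$slope_sd[res$n_tips == 128], res$slope_sd[res$n_tips == 32])
  res2 <- recovery_experiment(grid, n_reps = 25, seed = 5)
  expect_identical(res$slope_mean, res2$slope_mean)

  # noiseless cell: estimates exact, degenerate intervals still cover
  quiet <- recovery_experiment(
    tibble::tibble(n_tips = 16, sigma2 = 0),
    n_reps = 10, seed = 6
  )
  expect_equal(quiet$coverage, 1)
  expect_lt(quiet$slope_sd, 1e-8)
})

test_that("write_study_fixture emits a loadable mini-study", {
  dir <- withr::local_tempdir()
  fx <- write_study_fixture(dir, n_per_clade = 10, seed = 2)
  expect_true(file.exists(fx$trait_csv))
  expect_length(fx$trees, 3)
  tb <- read_trait_table(fx$trait_csv)
  expect_setequal(unique(tb$clade), c("Squamata", "Testudines", "Crocodilia"))
  tr <- read_newick(file = fx$trees[["Squamata"]])
  expect_setequal(tr$tip.label, tb$species[tb$clade == "Squamata"])
})
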