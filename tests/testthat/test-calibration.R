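test_that("initial_params starts covariate-unit parameters at sample quantiles", {
  x <- seq(0, 40)  # uniform grid
  ip <- initial_params("wang_engel", x)
  expect_equal(unname(ip$start[c("psi_base", "psi_opt", "psi_max")]),
               unname(quantile(x, c(0.05, 0.5, 0.95))))
  expect_true(all(ip$lower <= ip$start & ip$start <= ip$upper))

  lin <- initial_params("linear", x)
  expect_equal(unname(lin$start), c(0, 1))  # intercept 0, slope 1

  expect_error(initial_params("wang_engel", 5), "degenerate")
  expect_error(initial_params("wang_engel", rep(3, 10)), "degenerate")
})

test_that("calibration_loss equals a hand-computed per-day loop on a toy set", {
  x <- rbind(c(10, 20, 30, 25, 15),
             c(25, 25, 25, 25, 25),
             c(5, 10, 20, 30, 35))
  ed <- toy_env_data(x, obs_duration = c(3, 2, 4))
  par <- c(psi_base = 0, psi_opt = 25, psi_max = 35, r = 1)

  # independent brute-force evaluation of the stated definition
  a <- log(2) / log(35 / 25)
  f <- function(v) ifelse(v > 0 & v < 35, (2 * v^a * 25^a - v^(2 * a)) / 25^(2 * a), 0)
  cum <- t(apply(x, 1, function(r) cumsum(f(r))))
  req <- median(cum[cbind(1:3, c(3, 2, 4))])
  pred <- apply(cum >= req, 1, function(r) if (any(r)) which(r)[1] else ncol(x))
  expected <- sqrt(mean((c(3, 2, 4) - pred)^2))

  expect_equal(calibration_loss(par, "wang_engel", ed), expected,
               tolerance = 1e-12)
})

test_that("calibration_loss returns the sentinel for degenerate parameters", {
  x <- matrix(runif(20, 5, 20), 4, 5)
  ed <- toy_env_data(x, obs_duration = rep(3, 4))
  # base above every observed temperature: all doses zero
  dead <- c(psi_base = 50, psi_opt = 60, psi_max = 70, r = 1)
  expect_equal(calibration_loss(dead, "wang_engel", ed), 1e10)
  # constraint violation
  bad <- c(psi_base = 30, psi_opt = 20, psi_max = 40, r = 1)
  expect_equal(calibration_loss(bad, "wang_engel", ed), 1e10)
})

test_that("true parameters give near-zero loss on noise-free synthetic data", {
  cfg <- synthetic_config(n_stations = 3, n_years = 5, seed = 31, noise_sd = 0,
                          weather = list(tas = list(mean = 11, amplitude = 11,
                                                    ar1 = 0.7, sd = 3),
                                         station_tas_spread = 5))
  w <- gen_weather(cfg)
  env <- gen_phenology(w, cfg)
  ed <- phase_env_data(env, w, "tas", "heading-senescence")
  truth <- c(psi_base = 0, psi_opt = 25, psi_max = 35, r = 1)
  expect_lte(calibration_loss(truth, "wang_engel", ed), 1)  # discretization only
})

test_that("two-step fit improves on its starting point and stays feasible", {
  cfg <- recovery_config(32, n_stations = 6, n_years = 6)
  w <- gen_weather(cfg)
  env <- gen_phenology(w, cfg)
  ed <- phase_env_data(env, w, "tas", "heading-senescence")
  par <- fit_drc_two_step(ed, "wang_engel", calibration_config())
  init <- initial_params("wang_engel", as.vector(ed$x), calibration_config())
  expect_lte(attr(par, "loss"),
             calibration_loss(init$start, "wang_engel", ed, interpolate = TRUE))
  expect_true(par[["psi_base"]] < par[["psi_opt"]])
  expect_true(par[["psi_opt"]] < par[["psi_max"]])
  expect_gt(attr(par, "required_dose"), 0)
})

test_that("ensemble with subsample fraction 1 collapses to the single fit", {
  cfg <- recovery_config(33, n_stations = 5, n_years = 5)
  w <- gen_weather(cfg)
  env <- gen_phenology(w, cfg)
  ed <- phase_env_data(env, w, "tas", "heading-senescence")
  ccfg <- calibration_config(ensemble_runs = 3, subsample_fraction = 1, seed = 7)
  res <- ensemble_calibrate(ed, "wang_engel", ccfg)
  single <- fit_drc_two_step(ed, "wang_engel", ccfg)
  expect_equal(unname(res$median_params), unname(single[seq_along(single)]),
               tolerance = 1e-12)
  expect_length(res$ensemble_params, 3)
})

test_that("ensemble calibration is bit-reproducible under a fixed seed", {
  cfg <- recovery_config(34, n_stations = 5, n_years = 5)
  w <- gen_weather(cfg)
  env <- gen_phenology(w, cfg)
  ed <- phase_env_data(env, w, "tas", "heading-senescence")
  ccfg <- calibration_config(ensemble_runs = 3, seed = 55)
  r1 <- ensemble_calibrate(ed, "wang_engel", ccfg)
  r2 <- ensemble_calibrate(ed, "wang_engel", ccfg)
  expect_identical(r1$median_params, r2$median_params)
  expect_identical(r1$score_rmse, r2$score_rmse)
  expect_error(ensemble_calibrate(ed, "wang_engel",
                                  calibration_config(ensemble_runs = 3)),
               "seed")
})

fake_result <- function(family, cor, rmse) {
  structure(list(covariate = "RH", phase = "jointing-heading", family = family,
                 median_params = NULL, score_cor = cor, score_rmse = rmse),
            class = "calibration_result")
}

test_that("select_best_drc maximizes Pearson r with parsimony tie-breaks", {
  a <- fake_result("linear", 0.3, 5)
  b <- fake_result("wang_engel", 0.5, 5)
  expect_identical(select_best_drc(list(a, b))$family, "wang_engel")

  tie1 <- fake_result("broken_stick", 0.5, 6)  # 2 parameters
  tie2 <- fake_result("wang_engel", 0.5, 4)    # 4 parameters
  expect_identical(select_best_drc(list(tie2, tie1))$family, "broken_stick")

  expect_identical(select_best_drc(list(a))$family, "linear")
  expect_error(select_best_drc(list()), "no candidates")
})

test_that("restricted family policy yields 16 candidates over 7 covariates", {
  n <- vapply(PHENO_COVARIATES, function(cv) length(families_for_covariate(cv)), 0)
  expect_equal(unname(n[c("tasmin", "tas", "tasmax", "GR")]), rep(1, 4))
  expect_equal(unname(n[c("RH", "SPI", "VPD")]), rep(4, 3))
  expect_equal(sum(n), 16)
})
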