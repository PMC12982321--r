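test_that("the generator is deterministic and obeys physical invariants", {
  cfg <- synthetic_config(n_stations = 2, n_years = 4, seed = 81)
  w1 <- gen_weather(cfg)
  w2 <- gen_weather(cfg)
  expect_identical(w1, w2)
  # ordering and ranges are guaranteed by construction
  expect_true(all(w1$tasmin <= w1$tas & w1$tas <= w1$tasmax))
  expect_true(all(w1$RH >= 0 & w1$RH <= 100))
  expect_true(all(w1$pr >= 0) && all(w1$GR >= 0))
  e1 <- gen_phenology(w1, cfg)
  e2 <- gen_phenology(w2, cfg)
  expect_identical(e1, e2)
  # every record passes the io-module ordering validation unchanged
  expect_equal(nrow(validate_phenology(e1)), nrow(e1))
})

test_that("zero amplitude and noise give a constant series at the mean", {
  cfg <- synthetic_config(
    n_stations = 1, n_years = 2, seed = 82,
    weather = list(tas = list(mean = 12, amplitude = 0, ar1 = 0, sd = 0),
                   station_tas_spread = 0, spread_sd = 0))
  w <- gen_weather(cfg)
  expect_equal(unique(w$tas), 12)
})

test_that("long-run temperature mean matches the configured mean", {
  cfg <- synthetic_config(n_stations = 1, n_years = 30, seed = 83,
                          weather = list(station_tas_spread = 0))
  w <- gen_weather(cfg)
  # annual-cycle average of the cosine is ~0; AR(1) mean is 0
  expect_lt(abs(mean(w$tas) - 9), 0.2)
})

test_that("noise-free durations sit exactly at the dose-crossing day", {
  cfg <- synthetic_config(n_stations = 1, n_years = 3, seed = 84, noise_sd = 0)
  w <- gen_weather(cfg)
  env <- gen_phenology(w, cfg)
  spec <- cfg$truth[["jointing-heading"]]$drc_map$tas
  req <- cfg$truth[["jointing-heading"]]$required_dose
  for (i in seq_len(nrow(env))) {
    # independent crossing search via accumulate_dose
    d <- accumulate_dose(spec, w, env$jointing[i], env$jointing[i] + 120)
    crossing <- which(d$cumulative >= req)[1]
    expect_equal(as.integer(env$heading[i] - env$jointing[i]), crossing)
  }
})

test_that("doubling the required dose weakly lengthens every duration", {
  cfg1 <- synthetic_config(n_stations = 2, n_years = 4, seed = 85, noise_sd = 0)
  cfg2 <- cfg1
  cfg2$truth[["jointing-heading"]]$required_dose <-
    2 * cfg1$truth[["jointing-heading"]]$required_dose
  w <- gen_weather(cfg1)
  e1 <- gen_phenology(w, cfg1)
  e2 <- gen_phenology(w, cfg2)
  shared <- intersect(paste(e1$station_id, e1$harvest_year),
                      paste(e2$station_id, e2$harvest_year))
  i1 <- match(shared, paste(e1$station_id, e1$harvest_year))
  i2 <- match(shared, paste(e2$station_id, e2$harvest_year))
  d1 <- as.integer(e1$heading[i1] - e1$jointing[i1])
  d2 <- as.integer(e2$heading[i2] - e2$jointing[i2])
  expect_true(all(d2 >= d1))
})

test_that("zero-perturbation simulations replicate the observations", {
  cfg <- synthetic_config(n_stations = 2, n_years = 4, seed = 86,
                          scenario = list(n_simulations = 3,
                                          rcm_ids = c("R1", "R2")))
  w <- gen_weather(cfg)
  ens <- suppressWarnings(gen_scenario_ensemble(w, cfg))
  for (sim in ens$simulations) {
    expect_equal(sim$weather$tas, w$tas, tolerance = 1e-12)
    expect_equal(sim$weather$pr, w$pr, tolerance = 1e-12)
  }
  expect_equal(vapply(ens$simulations, `[[`, "", "rcm_id"),
               c("R1", "R2", "R1"))  # cyclic RCM tagging
})

test_that("a pure additive bias reproduces the closed-form scenario error", {
  cfg <- synthetic_config(n_stations = 1, n_years = 4, seed = 87,
                          scenario = list(n_simulations = 2, rcm_ids = "R1",
                                          bias = c(tas = 1.5)))
  w <- gen_weather(cfg)
  ens <- suppressWarnings(gen_scenario_ensemble(w, cfg))
  eps <- covariate_scenario_rmse(derive_covariates(w), ens, "tas")
  yr <- as.integer(format(w$date, "%Y"))
  ref <- w$tas[yr >= ens$reference_window[1] & yr <= ens$reference_window[2]]
  expect_equal(eps, 1.5 / (diff(range(ref)) + 1.5), tolerance = 1e-10)
})

test_that("a warming trend raises post-reference temperatures only", {
  cfg <- synthetic_config(
    n_stations = 1, n_years = 5, seed = 88,
    scenario = list(n_simulations = 1, rcm_ids = "R1",
                    trend_per_year = c(tas = 0.1, tasmin = 0.1, tasmax = 0.1),
                    reference_window = c(2000, 2004), horizon_year = 2014))
  w <- gen_weather(cfg)
  ens <- suppressWarnings(gen_scenario_ensemble(w, cfg))
  sw <- ens$simulations[[1]]$weather
  yr <- as.integer(format(sw$date, "%Y"))
  base_yr <- as.integer(format(w$date, "%Y"))
  # inside the reference window the simulation equals the observations
  expect_equal(sw$tas[yr <= 2004], w$tas[base_yr <= 2004], tolerance = 1e-12)
  doy_mean <- function(y) mean(sw$tas[yr == y])
  expect_gt(doy_mean(2014), doy_mean(2006))
  expect_true(all(sw$tasmin <= sw$tas & sw$tas <= sw$tasmax))
})

test_that("bundles are self-consistent and reproducible", {
  cfg <- synthetic_config(n_stations = 2, n_years = 4, seed = 89)
  b1 <- gen_bundle(cfg, ensemble = FALSE)
  b2 <- gen_bundle(cfg, ensemble = FALSE)
  expect_identical(b1$weather, b2$weather)
  expect_identical(b1$environments, b2$environments)
  expect_s3_class(b1$truth_models[["jointing-heading"]], "composite_model")
  # the truth chain reproduces the noise-free generator within a day
  cfg0 <- cfg; cfg0$noise_sd <- 0
  env0 <- gen_phenology(gen_weather(cfg0), cfg0)
  w <- b1$weather
  one <- env0[1, ]
  res <- chain_phases(b1$truth_models, w[w$station_id == one$station_id, ],
                      one$sowing)
  expect_lte(max(abs(as.numeric(res$end -
                                  as.Date(unlist(one[c("emergence", "jointing",
                                                       "heading", "senescence")]))))),
             1)
})

test_that("scenario ensembles round-trip through the YAML manifest format", {
  cfg <- synthetic_config(n_stations = 1, n_years = 6, seed = 90,
                          scenario = list(n_simulations = 2, rcm_ids = "R1"))
  w <- gen_weather(cfg)
  ens <- suppressWarnings(gen_scenario_ensemble(w, cfg))
  dir <- withr::local_tempdir()
  write_scenario_ensemble(ens, dir)
  back <- read_scenario_ensemble(dir)
  expect_equal(length(back$simulations), 2)
  expect_equal(back$reference_window, ens$reference_window)
  expect_equal(back$simulations[[1]]$weather$tas,
               ens$simulations[[1]]$weather$tas, tolerance = 1e-12)
})
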