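# Shared synthetic worlds. Expensive fixtures are built lazily once per test
# run and cached in this environment (helpers are loaded once by testthat).

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .world_cache)) assign(key, builder(), .world_cache)
  get(key, .world_cache)
}

# Warm multi-station world whose summer temperatures straddle the 25 deg C
# optimum of the true Wang-Engel response, so curve parameters are
# identifiable from phase durations. Station annual means span +/- 5 deg C.
recovery_config <- function(seed, n_stations = 25, n_years = 20) {
  synthetic_config(
    n_stations = n_stations, n_years = n_years, seed = seed,
    weather = list(tas = list(mean = 11, amplitude = 11, ar1 = 0.7, sd = 3),
                   station_tas_spread = 5))
}

# Three-covariate truth (tas + GR + SPI) on the summer phase; the other
# phases keep the single-covariate default truth (they only set the chain's
# start dates).
world_b_config <- function(seed = 11, n_stations = 10, n_years = 20) {
  truth <- default_truth()
  truth[["heading-senescence"]] <- list(
    drc_map = list(
      tas = drc_spec("wang_engel", "tas", "heading-senescence",
                     list(psi_base = 0, psi_opt = 25, psi_max = 35, r = 1)),
      GR  = drc_spec("wang_engel", "GR", "heading-senescence",
                     list(psi_base = 0, psi_opt = 1500, psi_max = 3000, r = 1)),
      SPI = drc_spec("linear", "SPI", "heading-senescence",
                     list(intercept = 0.5, slope = 0.15))),
    beta = c(tas = 1, GR = 1, SPI = 1),
    required_dose = 75)
  synthetic_config(
    n_stations = n_stations, n_years = n_years, seed = seed,
    weather = list(tas = list(mean = 11, amplitude = 11, ar1 = 0.7, sd = 3),
                   station_tas_spread = 5),
    truth = truth)
}

strip_derived <- function(weather) {
  weather[, setdiff(names(weather), c("SPI", "VPD")), drop = FALSE]
}

# Fully processed world B: data, 80/20 split, calibrated DRCs
# (ensemble_runs = 5 for runtime), composite grid and Max_GT selection for
# the heading-senescence phase.
world_b <- function() {
  cached("world_b", function() {
    cfg <- world_b_config(11)
    weather <- derive_covariates(gen_weather(cfg))
    env <- gen_phenology(weather, cfg)
    split <- stratified_split(env, 0.2, seed = 101)
    train <- split[split$split == "training", ]
    val <- split[split$split == "validation", ]
    ccfg <- calibration_config(ensemble_runs = 5, seed = 202)
    cal <- suppressWarnings(
      calibrate_phase(train, weather, "heading-senescence", ccfg,
                      covariates = c("tas", "GR", "SPI")))
    drc_map <- lapply(cal$best, drc_from_result)
    grid <- fit_model_grid(train, weather, drc_map, "heading-senescence")
    gt <- select_max_gt(grid, val, weather)
    list(cfg = cfg, weather = weather, env = env, train = train, val = val,
         cal = cal, drc_map = drc_map, grid = grid, gt = gt,
         starts = median_phase_starts(env))
  })
}

# Compact companion of world B for scenario-ensemble work: same truth, fewer
# stations/years so Max_CS evaluations stay cheap.
world_b_small <- function() {
  cached("world_b_small", function() {
    cfg <- world_b_config(12, n_stations = 4, n_years = 8)
    weather <- derive_covariates(gen_weather(cfg))
    env <- gen_phenology(weather, cfg)
    wb <- world_b()
    # reuse world B's fitted best-per-complexity models on this world
    best_models <- lapply(seq_len(nrow(wb$gt$profile)), function(i)
      wb$grid$models[[wb$gt$profile$model_id[i]]])
    list(cfg = cfg, weather = weather, env = env,
         raw = strip_derived(weather), best_models = best_models,
         starts = median_phase_starts(env))
  })
}

# World C embodies the complexity trade-off premise: three covariates each
# carrying strong *independent* information about the summer phase, so the
# ground-truth selection genuinely favors multi-covariate models. (In world
# B the covariates are nearly exchangeable and one suffices.)
world_c_config <- function(seed = 21, n_stations = 10, n_years = 20) {
  truth <- default_truth()
  truth[["heading-senescence"]] <- list(
    drc_map = list(
      tas = drc_spec("wang_engel", "tas", "heading-senescence",
                     list(psi_base = 0, psi_opt = 25, psi_max = 35, r = 1)),
      GR  = drc_spec("wang_engel", "GR", "heading-senescence",
                     list(psi_base = 0, psi_opt = 1800, psi_max = 2600, r = 1)),
      SPI = drc_spec("linear", "SPI", "heading-senescence",
                     list(intercept = 0.3, slope = 0.5))),
    beta = c(tas = 1, GR = 1, SPI = 1),
    required_dose = 75)
  synthetic_config(
    n_stations = n_stations, n_years = n_years, seed = seed,
    weather = list(tas = list(mean = 11, amplitude = 11, ar1 = 0.7, sd = 3),
                   station_tas_spread = 5),
    truth = truth)
}

world_c <- function() {
  cached("world_c", function() {
    cfg <- world_c_config(21)
    weather <- derive_covariates(gen_weather(cfg))
    env <- gen_phenology(weather, cfg)
    split <- stratified_split(env, 0.2, seed = 303)
    train <- split[split$split == "training", ]
    val <- split[split$split == "validation", ]
    ccfg <- calibration_config(ensemble_runs = 5, seed = 404)
    cal <- suppressWarnings(
      calibrate_phase(train, weather, "heading-senescence", ccfg,
                      covariates = c("tas", "GR", "SPI")))
    drc_map <- lapply(cal$best, drc_from_result)
    grid <- fit_model_grid(train, weather, drc_map, "heading-senescence")
    gt <- select_max_gt(grid, val, weather)
    # small companion world (same truth) for cheap ensemble evaluations
    cfg_small <- world_c_config(22, n_stations = 4, n_years = 8)
    weather_small <- derive_covariates(gen_weather(cfg_small))
    env_small <- gen_phenology(weather_small, cfg_small)
    best_models <- lapply(seq_len(nrow(gt$profile)), function(i)
      grid$models[[gt$profile$model_id[i]]])
    list(cfg = cfg, weather = weather, env = env, grid = grid, gt = gt,
         cfg_small = cfg_small, weather_small = weather_small,
         raw_small = strip_derived(weather_small),
         best_models = best_models,
         starts_small = median_phase_starts(env_small))
  })
}

# Tiny single-station weather table with controllable series, for unit tests
toy_weather <- function(n = 30, start = as.Date("2001-04-01"), tas = 15,
                        station_id = "TST") {
  tas <- rep_len(tas, n)
  data.frame(station_id = station_id, date = seq(start, by = "day", length.out = n),
             tasmin = tas - 4, tas = tas, tasmax = tas + 4,
             RH = 70, pr = 1, GR = 1000)
}

# a minimal phase_env_data object built by hand (x: matrix, durations)
toy_env_data <- function(x, obs_duration, covariate = "tas",
                         phase = "jointing-heading") {
  structure(list(x = x, obs_duration = obs_duration,
                 horizon = rep(ncol(x), nrow(x)),
                 start = rep(as.Date("2001-04-01"), nrow(x)),
                 station_id = paste0("S", seq_len(nrow(x))),
                 env_index = seq_len(nrow(x)),
                 covariate = covariate, phase = phase),
            class = "phase_env_data")
}
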