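#' Configuration of the synthetic-data generator
#'
#' States the simulated world: multi-station daily weather with sinusoidal
#' seasonality plus AR(1) anomalies, phenology generated by a known additive
#' dose model, and a scenario ensemble that equals the observed climate in
#' the reference period up to controllable per-covariate bias/noise plus an
#' optional warming trend. Defaults emulate a temperate winter-wheat setting:
#' annual mean temperature 9 deg C with 9 deg C seasonal amplitude and
#' day-to-day AR(1) anomalies (phi 0.7, SD 2 deg C), humid climate (RH
#' around 75%), ~45% wet days with gamma rainfall, and radiation peaking
#' midsummer. Phase truths use a Wang-Engel temperature response with
#' cardinal values (0, 25, 35) deg C — plausible wheat values, documented as
#' test constructs, not claims. Observation noise on phase durations is
#' 2 days (SD) by default.
#'
#' @param n_stations,n_years,start_year World size. Defaults 5 stations,
#'   12 harvest years starting 2000.
#' @param seed Integer seed (mandatory).
#' @param weather Per-covariate seasonal/noise parameters (see Details in
#'   the source; override selectively).
#' @param truth Named list per phase: `drc_map` (true [drc_spec()]s),
#'   `beta` (named weights) and `required_dose`.
#' @param noise_sd Duration observation noise SD in days. Default 2.
#' @param sowing_day Fixed sowing `"MM-DD"`. Default `"10-30"`.
#' @param scenario List: `n_simulations`, `rcm_ids`, per-covariate `bias`
#'   and `noise_sd` (named, raw covariates), AR(1) `ar1` of the noise,
#'   `trend_per_year` (named; deg C/year etc., applied beyond the reference
#'   window), `reference_window` and `horizon_year`.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_stations = 5, n_years = 12, start_year = 2000,
                             seed,
                             weather = list(),
                             truth = default_truth(),
                             noise_sd = 2,
                             sowing_day = "10-30",
                             scenario = list()) {
  if (missing(seed)) stop("synthetic_config: seed is mandatory", call. = FALSE)
  wdef <- list(
    tas = list(mean = 9, amplitude = 9, ar1 = 0.7, sd = 2),
    station_tas_spread = 2,
    spread_min = 4, spread_max = 5, spread_sd = 0.5,
    RH = list(mean = 75, amplitude = 10, ar1 = 0.5, sd = 6),
    pr = list(wet_prob = 0.45, shape = 0.9, scale = 6),
    GR = list(mean = 1100, amplitude = 850, ar1 = 0.4, sd = 160)
  )
  wdef[names(weather)] <- weather
  sdef <- list(n_simulations = 6, rcm_ids = c("RCM-A", "RCM-B"),
               bias = numeric(0), noise_sd = numeric(0), ar1 = 0.5,
               trend_per_year = numeric(0),
               reference_window = c(start_year, start_year + n_years - 1),
               horizon_year = start_year + n_years - 1,
               rcp_label = "RCP8.5")
  sdef[names(scenario)] <- scenario
  if (sdef$horizon_year < sdef$reference_window[2]) {
    stop("synthetic_config: horizon before reference end", call. = FALSE)
  }
  if (wdef$spread_min <= 0 || wdef$spread_max <= 0) {
    stop("synthetic_config: temperature spreads must be positive", call. = FALSE)
  }
  structure(list(n_stations = n_stations, n_years = n_years,
                 start_year = start_year, seed = as.integer(seed),
                 weather = wdef, truth = truth, noise_sd = noise_sd,
                 sowing_day = sowing_day, scenario = sdef),
            class = "synthetic_config")
}

#' Default ground-truth model of the generator
#'
#' Every phase driven by mean temperature through a Wang-Engel response with
#' cardinal values (0, 25, 35) deg C and unit peak rate; required doses are
#' set so that typical durations are realistic for winter wheat sown late
#' October (emergence ~2-3 weeks, jointing in spring, heading early summer,
#' senescence ~7 weeks later).
#'
#' @return Named list per phase with `drc_map`, `beta`, `required_dose`.
#' @export
default_truth <- function() {
  we <- function(ph) drc_spec("wang_engel", "tas", ph,
                              list(psi_base = 0, psi_opt = 25, psi_max = 35, r = 1))
  doses <- c("sowing-emergence" = 1.0, "emergence-jointing" = 9,
             "jointing-heading" = 15, "heading-senescence" = 30)
  out <- lapply(PHENO_PHASES, function(ph) {
    list(drc_map = setNames(list(we(ph)), "tas"),
         beta = c(tas = 1), required_dose = unname(doses[ph]))
  })
  setNames(out, PHENO_PHASES)
}

seasonal_cycle <- function(doy, mean, amplitude, peak_doy = 197) {
  mean + amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
}

ar1_series <- function(rng, n, ar1, sd) {
  innov <- rng$rnorm(n, 0, sd * sqrt(1 - ar1^2))
  as.numeric(stats::filter(innov, ar1, method = "recursive"))
}

#' Generate multi-station daily weather
#'
#' Sinusoidal annual cycles (temperature and radiation peaking midsummer,
#' relative humidity in winter) plus AR(1) anomalies; `tasmin`/`tasmax` are
#' built from `tas` with positive random spreads so the ordering invariant
#' holds by construction; precipitation is zero-inflated gamma; radiation is
#' non-negative and RH clipped to \[20, 100\]. Deterministic for a fixed
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @param end_year Optional last calendar year (defaults to the configured
#'   span; the series always starts in July of `start_year - 1` so the first
#'   harvest season has its sowing available).
#' @return A weather table passing [validate_weather()].
#' @export
gen_weather <- function(config, end_year = NULL) {
  wc <- config$weather
  end_year <- end_year %||% (config$start_year + config$n_years - 1)
  dates <- seq(as.Date(paste0(config$start_year - 1, "-07-01")),
               as.Date(paste0(end_year, "-12-31")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  n <- length(dates)
  rng <- local_rng(config$seed)
  out <- vector("list", config$n_stations)
  # regional climate gradient: station annual means evenly spaced across
  # +/- station_tas_spread deg C (think lowland vs upland sites)
  offs <- if (config$n_stations > 1) {
    seq(-wc$station_tas_spread, wc$station_tas_spread,
        length.out = config$n_stations)
  } else 0
  for (s in seq_len(config$n_stations)) {
    tas <- seasonal_cycle(doy, wc$tas$mean + offs[s], wc$tas$amplitude) +
      ar1_series(rng, n, wc$tas$ar1, wc$tas$sd)
    tasmin <- tas - (wc$spread_min + abs(rng$rnorm(n, 0, wc$spread_sd)))
    tasmax <- tas + (wc$spread_max + abs(rng$rnorm(n, 0, wc$spread_sd)))
    RH <- pmin(pmax(seasonal_cycle(doy, wc$RH$mean, -wc$RH$amplitude) +
                      ar1_series(rng, n, wc$RH$ar1, wc$RH$sd), 20), 100)
    pr <- rng$rbinom(n, 1, wc$pr$wet_prob) *
      rng$rgamma(n, shape = wc$pr$shape, scale = wc$pr$scale)
    GR <- pmax(seasonal_cycle(doy, wc$GR$mean, wc$GR$amplitude) +
                 ar1_series(rng, n, wc$GR$ar1, wc$GR$sd), 0)
    out[[s]] <- data.frame(station_id = sprintf("ST%02d", s), date = dates,
                           tasmin = tasmin, tas = tas, tasmax = tasmax,
                           RH = RH, pr = pr, GR = GR)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_weather(res, where = "gen_weather")
}

# combined weighted dose series of one phase truth from a start index
truth_dose <- function(truth_ph, w, i0, n) {
  dose <- numeric(n)
  for (cov in names(truth_ph$drc_map)) {
    x <- w[[truth_ph$drc_map[[cov]]$covariate]][i0:(i0 + n - 1)]
    dose <- dose + truth_ph$beta[[cov]] * cumsum(eval_drc(truth_ph$drc_map[[cov]], x))
  }
  dose
}

#' Generate phenology observations from the true dose model
#'
#' Per station and harvest year, each phase ends on the first day the true
#' beta-weighted accumulated dose reaches the true required dose, plus
#' rounded Gaussian observation noise (duration floor 1 day, so stage
#' ordering holds by construction); the next phase starts at the noisy
#' observed end, as a rater would record it. Seasons whose dose never
#' reaches the requirement within the weather coverage are skipped and
#' counted (attribute `n_skipped`).
#'
#' @param weather Generated (or real) weather table with the truth's
#'   covariates present.
#' @param config A [synthetic_config()] (uses `truth`, `noise_sd`,
#'   `sowing_day`, and a seed derived from `seed`).
#' @return Phenology environment table.
#' @export
gen_phenology <- function(weather, config) {
  rng <- local_rng(config$seed + 1L)
  need <- unique(unlist(lapply(config$truth, function(tr)
    vapply(tr$drc_map, `[[`, "", "covariate"))))
  if (!all(need %in% names(weather))) {
    if (all(setdiff(need, names(weather)) %in% c("SPI", "VPD"))) {
      weather <- derive_covariates(weather)
    } else {
      stop("gen_phenology: truth covariate(s) missing from weather: ",
           paste(setdiff(need, names(weather)), collapse = ", "), call. = FALSE)
    }
  }
  wsplit <- split(weather, weather$station_id)
  years <- config$start_year:(config$start_year + config$n_years - 1)
  rows <- list(); skipped <- 0L
  for (sid in names(wsplit)) {
    w <- wsplit[[sid]]
    for (yr in years) {
      sowing <- as.Date(paste0(yr - 1, "-", config$sowing_day))
      i0 <- match(sowing, w$date)
      if (is.na(i0)) { skipped <- skipped + 1L; next }
      stages <- setNames(rep(as.Date(NA), 5), pheno_stages())
      stages["sowing"] <- sowing
      start <- sowing; ok <- TRUE
      for (ph in PHENO_PHASES) {
        tr <- config$truth[[ph]]
        is <- match(start, w$date)
        n_avail <- nrow(w) - is + 1
        if (is.na(is) || n_avail < 10) { ok <- FALSE; break }
        dose <- truth_dose(tr, w, is, n_avail)
        hit <- which(dose >= tr$required_dose)
        if (length(hit) == 0) { ok <- FALSE; break }
        D <- max(1L, hit[1] + as.integer(round(rng$rnorm(1, 0, config$noise_sd))))
        if (is + D > nrow(w)) { ok <- FALSE; break }
        end <- start + D
        stages[phase_stages(ph)[2]] <- end
        start <- end
      }
      if (!ok) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1]] <- data.frame(
        station_id = sid, harvest_year = yr,
        sowing = stages[["sowing"]], emergence = stages[["emergence"]],
        jointing = stages[["jointing"]], heading = stages[["heading"]],
        senescence = stages[["senescence"]])
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty_phenology()
  rownames(out) <- NULL
  if (skipped > 0) attr(out, "n_skipped") <- skipped
  out
}

# day-of-year climatology extension of observed weather beyond its last year,
# recycling seasonal structure with AR(1) anomalies around it
extend_weather <- function(weather, to_year, config) {
  last <- max(weather$date)
  if (as.integer(format(last, "%Y")) >= to_year) return(weather)
  rng <- local_rng(config$seed + 2L)
  ext <- lapply(split(weather, weather$station_id), function(w) {
    doy <- as.integer(format(w$date, "%j"))
    new_dates <- seq(last + 1, as.Date(paste0(to_year, "-12-31")), by = "day")
    nd <- as.integer(format(new_dates, "%j"))
    res <- data.frame(station_id = w$station_id[1], date = new_dates)
    for (v in weather_raw_covariates()) {
      clim <- tapply(w[[v]], doy, mean)
      resid_sd <- sd(w[[v]] - clim[as.character(doy)])
      vals <- clim[as.character(nd)] + ar1_series(rng, length(nd), 0.6, resid_sd)
      if (v %in% c("pr", "GR")) vals <- pmax(vals, 0)
      if (v == "RH") vals <- pmin(pmax(vals, 0), 100)
      res[[v]] <- as.numeric(vals)
    }
    # repair temperature ordering after independent anomalies
    tri <- t(apply(res[, c("tasmin", "tas", "tasmax")], 1, sort))
    res$tasmin <- tri[, 1]; res$tas <- tri[, 2]; res$tasmax <- tri[, 3]
    rbind(w, res)
  })
  res <- do.call(rbind, ext)
  rownames(res) <- NULL
  res
}

#' Generate a scenario ensemble around observed weather
#'
#' Each simulation equals the observed weather plus a per-covariate additive
#' bias, AR(1) noise (independently seeded per simulation) and, beyond the
#' reference window, a linear trend; coverage is extended to the projection
#' horizon by recycling the observed seasonal structure. Temperature
#' ordering is repaired row-wise after perturbation, RH/pr/GR are clipped to
#' their physical ranges, and SPI/VPD are re-derived per simulation from its
#' own perturbed series. RCM labels are assigned cyclically. With zero
#' bias/noise/trend every simulation is identical to the observations in the
#' reference window.
#'
#' @param weather Observed weather table (raw covariates).
#' @param config A [synthetic_config()] (uses the `scenario` block).
#' @return A [scenario_ensemble()] with derived covariates on each
#'   simulation.
#' @export
gen_scenario_ensemble <- function(weather, config) {
  sc <- config$scenario
  base <- extend_weather(weather, sc$horizon_year, config)
  years <- as.integer(format(base$date, "%Y"))
  beyond <- pmax(years - sc$reference_window[2], 0)
  rng <- local_rng(config$seed + 3L)
  sim_seeds <- vapply(seq_len(sc$n_simulations), function(i) rng$draw_seed(), 0)
  sims <- vector("list", sc$n_simulations)
  for (k in seq_len(sc$n_simulations)) {
    srng <- local_rng(sim_seeds[k] %% .Machine$integer.max)
    w <- base
    for (v in weather_raw_covariates()) {
      pert <- rep(0, nrow(w))
      if (v %in% names(sc$bias)) pert <- pert + sc$bias[[v]]
      if (v %in% names(sc$noise_sd) && sc$noise_sd[[v]] > 0) {
        for (i in split(seq_len(nrow(w)), w$station_id)) {
          pert[i] <- pert[i] + ar1_series(srng, length(i), sc$ar1, sc$noise_sd[[v]])
        }
      }
      if (v %in% names(sc$trend_per_year)) {
        pert <- pert + sc$trend_per_year[[v]] * beyond
      }
      w[[v]] <- w[[v]] + pert
    }
    tri <- t(apply(w[, c("tasmin", "tas", "tasmax")], 1, sort))
    w$tasmin <- tri[, 1]; w$tas <- tri[, 2]; w$tasmax <- tri[, 3]
    w$RH <- pmin(pmax(w$RH, 0), 100)
    w$pr <- pmax(w$pr, 0); w$GR <- pmax(w$GR, 0)
    sims[[k]] <- list(
      simulation_id = sprintf("sim%02d", k),
      rcm_id = sc$rcm_ids[((k - 1) %% length(sc$rcm_ids)) + 1],
      gcm_id = sprintf("GCM%02d", k), rcp_label = sc$rcp_label,
      weather = derive_covariates(w))
  }
  scenario_ensemble(sims, sc$reference_window,
                    c(sc$reference_window[1], sc$horizon_year))
}

#' The true model chain as composite models
#'
#' Expresses each phase's generator truth as a `composite_model` whose
#' logistic response crosses probability 0.5 exactly when the beta-weighted
#' combined dose reaches the true required dose (steep logistic, sharpness
#' scaled to the dose).
#'
#' @param config A [synthetic_config()].
#' @return Named list of `composite_model`s per phase.
#' @export
truth_model_chain <- function(config) {
  out <- lapply(PHENO_PHASES, function(ph) {
    tr <- config$truth[[ph]]
    covs <- names(tr$drc_map)
    s <- 20 / tr$required_dose
    beta <- c(-s * tr$required_dose, s * tr$beta[covs])
    names(beta) <- c("(Intercept)", paste0("Z_", covs))
    structure(list(phase = ph, subset = sort(covs),
                   subset_id = subset_id(covs), coefficients = beta,
                   drc_map = tr$drc_map[sort(covs)], threshold = 0.5,
                   penalized = FALSE, loglik = NA_real_,
                   complexity = length(covs)),
              class = "composite_model")
  })
  setNames(out, PHENO_PHASES)
}

#' Generate a complete ground-truth bundle
#'
#' Weather (with derived covariates), phenology environments, the true model
#' chain and a scenario ensemble, all reproducible bit-for-bit from the
#' config and its seed (carried as `provenance`).
#'
#' @param config A [synthetic_config()].
#' @param ensemble Also generate the scenario ensemble. Default TRUE.
#' @return List of class `ground_truth_bundle` with `weather`,
#'   `environments`, `truth_models`, `ensemble`, `provenance`.
#' @export
gen_bundle <- function(config, ensemble = TRUE) {
  raw <- gen_weather(config)
  weather <- derive_covariates(raw)
  env <- gen_phenology(weather, config)
  ens <- if (ensemble) gen_scenario_ensemble(raw, config) else NULL
  structure(list(weather = weather, environments = env,
                 truth_models = truth_model_chain(config),
                 ensemble = ens, provenance = config),
            class = "ground_truth_bundle")
}
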