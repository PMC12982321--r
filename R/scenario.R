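#' Climate scenario ensemble
#'
#' A set of daily weather simulations tagged with regional climate model
#' (RCM), global climate model (GCM) and emission pathway (RCP) identifiers,
#' covering a reference window (overlapping observations) and a projection
#' window.
#'
#' @param simulations List; each element a list with `simulation_id`,
#'   `rcm_id`, `gcm_id`, `rcp_label` and `weather` (a multi-station weather
#'   table with derived covariates).
#' @param reference_window,projection_window Integer `c(start_year, end_year)`.
#' @return Object of class `scenario_ensemble` with a `stations` field
#'   (stations common to all simulations).
#' @export
scenario_ensemble <- function(simulations, reference_window,
                              projection_window = reference_window) {
  stopifnot(length(simulations) >= 1,
            length(reference_window) == 2, length(projection_window) == 2)
  station_sets <- lapply(simulations, function(s) unique(s$weather$station_id))
  stations <- Reduce(intersect, station_sets)
  if (length(stations) == 0) {
    stop("scenario_ensemble: simulations share no station", call. = FALSE)
  }
  for (s in simulations) {
    yrs <- range(as.integer(format(s$weather$date, "%Y")))
    if (yrs[1] > reference_window[1] || yrs[2] < reference_window[2]) {
      stop("scenario_ensemble: simulation ", s$simulation_id,
           " does not cover the reference window", call. = FALSE)
    }
  }
  structure(list(simulations = simulations,
                 reference_window = as.integer(reference_window),
                 projection_window = as.integer(projection_window),
                 stations = stations),
            class = "scenario_ensemble")
}

#' @export
print.scenario_ensemble <- function(x, ...) {
  rcps <- table(vapply(x$simulations, `[[`, "", "rcp_label"))
  cat("<scenario_ensemble> ", length(x$simulations), " simulations, ",
      length(x$stations), " station(s)\n  reference ",
      x$reference_window[1], "-", x$reference_window[2], ", projection ",
      x$projection_window[1], "-", x$projection_window[2], "\n  RCPs: ",
      paste(names(rcps), rcps, sep = " x ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a scenario ensemble as CSV files plus a YAML manifest
#'
#' One CSV per simulation plus `manifest.yaml` mapping each filename to its
#' (simulation_id, rcm, gcm, rcp) tags and recording the windows.
#'
#' @param ensemble A `scenario_ensemble`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_scenario_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(ensemble$simulations, function(s) {
    fn <- paste0(s$simulation_id, ".csv")
    write_weather(s$weather, file.path(dir, fn))
    list(filename = fn, simulation_id = s$simulation_id, rcm = s$rcm_id,
         gcm = s$gcm_id, rcp = s$rcp_label)
  })
  manifest <- list(format_version = 1L,
                   reference_window = as.integer(ensemble$reference_window),
                   projection_window = as.integer(ensemble$projection_window),
                   simulations = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a scenario ensemble from a manifest directory
#'
#' @param dir Directory containing `manifest.yaml` and the per-simulation
#'   CSVs written by [write_scenario_ensemble()].
#' @param derive Add SPI/VPD columns to each simulation. Default TRUE.
#' @return A `scenario_ensemble`.
#' @export
read_scenario_ensemble <- function(dir, derive = TRUE) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  sims <- lapply(manifest$simulations, function(e) {
    w <- read_weather(file.path(dir, e$filename))
    if (derive) w <- derive_covariates(w)
    list(simulation_id = e$simulation_id, rcm_id = e$rcm, gcm_id = e$gcm,
         rcp_label = e$rcp, weather = w)
  })
  scenario_ensemble(sims, unlist(manifest$reference_window),
                    unlist(manifest$projection_window))
}
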