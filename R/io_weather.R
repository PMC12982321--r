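#' Read a station weather table
#'
#' Expects comma-delimited text with a header containing `station_id`, `date`
#' (ISO-8601) and the six raw daily covariates `tasmin`, `tas`, `tasmax`
#' (deg C), `RH` (%), `pr` (mm/day) and `GR` (J/cm2/day). Rows are typed and
#' sorted by station and date; integrity is enforced:
#' duplicate (station, date) rows, calendar gaps, `RH` outside \[0, 100\],
#' negative `pr`/`GR` or a row with `tasmin > tas` or `tas > tasmax` are
#' errors. Use [fill_weather_gaps()] beforehand for short gaps.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with one row per station and day.
#' @export
read_weather <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  validate_weather(type_weather(raw), where = path)
}

type_weather <- function(raw) {
  need <- c("station_id", "date", weather_raw_covariates())
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("weather table: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw$date <- as.Date(raw$date)
  if (anyNA(raw$date)) stop("weather table: unparseable date(s)", call. = FALSE)
  for (v in weather_raw_covariates()) raw[[v]] <- as.numeric(raw[[v]])
  raw[order(raw$station_id, raw$date), , drop = FALSE]
}

weather_raw_covariates <- function() c("tasmin", "tas", "tasmax", "RH", "pr", "GR")

#' Validate weather-table invariants
#'
#' @param weather A typed weather table (sorted per station by date).
#' @param where Label used in error messages.
#' @return The table, invisibly duplicated as return value, if valid.
#' @keywords internal
#' @export
validate_weather <- function(weather, where = "weather") {
  if (any(weather$RH < 0 | weather$RH > 100, na.rm = TRUE)) {
    stop(where, ": RH outside [0, 100]", call. = FALSE)
  }
  if (any(weather$pr < 0, na.rm = TRUE)) stop(where, ": negative pr", call. = FALSE)
  if (any(weather$GR < 0, na.rm = TRUE)) stop(where, ": negative GR", call. = FALSE)
  bad <- which(weather$tasmin > weather$tas | weather$tas > weather$tasmax)
  if (length(bad) > 0) {
    stop(where, ": tasmin <= tas <= tasmax violated at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  for (sid in unique(weather$station_id)) {
    d <- weather$date[weather$station_id == sid]
    dd <- diff(as.integer(d))
    if (any(dd == 0)) {
      stop(where, ": duplicated dates for station ", sid, call. = FALSE)
    }
    if (any(dd != 1)) {
      stop(where, ": station ", sid, " has ", sum(dd != 1),
           " calendar gap(s); fill short gaps with fill_weather_gaps()",
           call. = FALSE)
    }
  }
  weather
}

#' Linearly interpolate short weather gaps
#'
#' Inserts missing calendar days per station and fills each raw covariate by
#' linear interpolation, but only across gaps of at most `max_gap` consecutive
#' missing days; a longer gap is an error (external imputation machinery is
#' out of scope).
#'
#' @param weather Typed weather table, possibly with calendar gaps.
#' @param max_gap Longest gap (days) that may be interpolated. Default 3.
#' @return Gap-free weather table passing [validate_weather()].
#' @export
fill_weather_gaps <- function(weather, max_gap = 3) {
  out <- lapply(split(weather, weather$station_id), function(w) {
    w <- w[order(w$date), , drop = FALSE]
    full <- seq(min(w$date), max(w$date), by = "day")
    idx <- match(full, w$date)
    gaps <- rle(is.na(idx))
    if (any(gaps$values & gaps$lengths > max_gap)) {
      stop("fill_weather_gaps: station ", w$station_id[1],
           " has a gap longer than ", max_gap, " days", call. = FALSE)
    }
    res <- data.frame(station_id = w$station_id[1], date = full)
    known <- which(!is.na(idx))
    for (v in weather_raw_covariates()) {
      res[[v]] <- stats::approx(x = known, y = w[[v]][idx[known]],
                                xout = seq_along(full), rule = 2)$y
    }
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_weather(res, where = "fill_weather_gaps")
}

#' Write a weather table as CSV
#' @param weather Weather table.
#' @param path Output path.
#' @export
write_weather <- function(weather, path) {
  write.csv(weather, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read phenology observations
#'
#' Expects comma-delimited text with header `station_id`, `harvest_year` and
#' the stage dates `sowing`, `emergence`, `jointing`, `heading`, `senescence`
#' (ISO-8601; any stage may be empty). One record per station and harvest
#' year. Records whose present stage dates are not strictly increasing are
#' dropped with a warning carrying the count.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of phenology environments, one row per
#'   station x harvest year, stage columns of class `Date`.
#' @export
read_phenology <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("read_phenology: empty file ", path)
    return(empty_phenology())
  }
  need <- c("station_id", "harvest_year", pheno_stages())
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("phenology table: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw$harvest_year <- as.integer(raw$harvest_year)
  for (s in pheno_stages()) {
    v <- raw[[s]]
    v[v %in% c("", "NA")] <- NA
    parsed <- as.Date(v, format = "%Y-%m-%d")
    if (any(!is.na(v) & is.na(parsed))) {
      stop("phenology table: unparseable date in column '", s, "'",
           call. = FALSE)
    }
    raw[[s]] <- parsed
  }
  validate_phenology(raw)
}

pheno_stages <- function() c("sowing", "emergence", "jointing", "heading", "senescence")

empty_phenology <- function() {
  out <- data.frame(station_id = character(), harvest_year = integer())
  for (s in pheno_stages()) out[[s]] <- as.Date(character())
  out
}

#' Drop phenology records violating stage ordering
#'
#' Present stages must be strictly increasing in calendar time
#' (sowing < emergence < jointing < heading < senescence).
#'
#' @param env Phenology environment table.
#' @return The table without misordered records (warning carries the count).
#' @export
validate_phenology <- function(env) {
  ok <- vapply(seq_len(nrow(env)), function(i) {
    d <- as.numeric(unlist(env[i, pheno_stages()]))
    d <- d[!is.na(d)]
    length(d) < 2 || all(diff(d) > 0)
  }, logical(1))
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " phenology record(s) violating stage ordering")
  }
  out <- env[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write phenology observations as CSV
#' @param env Phenology environment table.
#' @param path Output path.
#' @export
write_phenology <- function(env, path) {
  write.csv(env, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/validation split of environments
#'
#' Splits station x harvest-year environments into training and validation
#' sets, stratified by harvest year so that year densities are balanced
#' between the two sets. Within each year stratum the validation fraction is
#' honoured up to rounding; strata with fewer than 2 environments go wholly
#' to training with a warning. Deterministic for a fixed seed.
#'
#' @param environments Phenology environment table.
#' @param validation_fraction Proportion in (0, 1) held out. Default 0.2.
#' @param seed Integer seed (required; there is no hidden global RNG).
#' @return The input table with an added factor column `split` taking values
#'   `"training"`/`"validation"`.
#' @export
stratified_split <- function(environments, validation_fraction = 0.2, seed) {
  if (missing(seed)) stop("stratified_split: seed is required", call. = FALSE)
  if (!(validation_fraction > 0 && validation_fraction < 1)) {
    stop("stratified_split: validation_fraction must be in (0, 1)", call. = FALSE)
  }
  rng <- local_rng(seed)
  split <- rep("training", nrow(environments))
  for (yr in sort(unique(environments$harvest_year))) {
    idx <- which(environments$harvest_year == yr)
    if (length(idx) < 2) {
      warning("stratified_split: year ", yr,
              " has < 2 environments; assigned wholly to training")
      next
    }
    n_val <- round(validation_fraction * length(idx))
    n_val <- min(max(n_val, 0), length(idx) - 1)
    if (n_val > 0) split[rng$sample(idx, n_val)] <- "validation"
  }
  environments$split <- factor(split, levels = c("training", "validation"))
  environments
}

# Self-contained RNG stream: never touches .Random.seed of the caller.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      })
      f(...)
    }
  }
  list(
    sample = with_state(function(x, size) sample(x, size)),
    rnorm = with_state(stats::rnorm),
    runif = with_state(stats::runif),
    rgamma = with_state(stats::rgamma),
    rbinom = with_state(stats::rbinom),
    draw_seed = with_state(function() sample.int(.Machine$integer.max, 1))
  )
}
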