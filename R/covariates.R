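#' Vapour pressure deficit from temperature and relative humidity
#'
#' `VPD = e_s(tas) * (1 - RH/100)` with the Magnus saturation vapour pressure
#' `e_s(T) = 6.1078 * exp(17.27 * T / (T + 237.3))` in hPa — standard
#' agrometeorological practice.
#'
#' @param tas Air temperature, deg C.
#' @param RH Relative humidity in percent, within \[0, 100\].
#' @return VPD in hPa (>= 0), vectorised.
#' @export
compute_vpd <- function(tas, RH) {
  if (any(RH < 0 | RH > 100, na.rm = TRUE)) {
    stop("compute_vpd: RH outside [0, 100]", call. = FALSE)
  }
  magnus_es(tas) * (1 - RH / 100)
}

magnus_es <- function(tas) 6.1078 * exp(17.27 * tas / (tas + 237.3))

#' Fit the SPI probability model to a sample of precipitation sums
#'
#' Mixed distribution `F(x) = q + (1 - q) * G(x)` where `q` is the fraction of
#' zero sums and `G` a gamma CDF fitted to the nonzero sums by maximum
#' likelihood (BFGS on log-parameters from a Thom-approximation start).
#'
#' @param sums Numeric vector of (30-day) precipitation sums, >= 0.
#' @return List with `q`, `shape`, `rate`.
#' @export
spi_fit <- function(sums) {
  sums <- sums[!is.na(sums)]
  if (length(sums) == 0) stop("spi_fit: empty sample", call. = FALSE)
  pos <- sums[sums > 0]
  if (length(pos) == 0) {
    stop("spi_fit: degenerate distribution (all precipitation sums are zero)",
         call. = FALSE)
  }
  if (sd(pos) == 0 || length(pos) < 3) {
    stop("spi_fit: degenerate distribution (constant nonzero sums)",
         call. = FALSE)
  }
  q <- mean(sums == 0)
  # Thom (1958) approximate gamma ML, then exact ML on log scale
  A <- log(mean(pos)) - mean(log(pos))
  shape0 <- if (A > 0) (1 + sqrt(1 + 4 * A / 3)) / (4 * A) else 1
  rate0 <- shape0 / mean(pos)
  nll <- function(lp) -sum(stats::dgamma(pos, exp(lp[1]), exp(lp[2]), log = TRUE))
  fit <- optim(log(c(shape0, rate0)), nll, method = "BFGS")
  list(q = q, shape = exp(fit$par[1]), rate = exp(fit$par[2]))
}

#' SPI value of precipitation sums under a fitted model
#'
#' Probit transform of the mixed CDF: zero sums map to `qnorm(q)`, positive
#' sums to `qnorm(q + (1 - q) * G(x))`. Probabilities are clamped away from 0
#' and 1 so the transform stays finite.
#'
#' @param fit Result of [spi_fit()].
#' @param sums Numeric vector of precipitation sums.
#' @return Unitless SPI values.
#' @export
spi_value <- function(fit, sums) {
  p <- ifelse(sums <= 0, fit$q,
              fit$q + (1 - fit$q) * pgamma(sums, fit$shape, fit$rate))
  qnorm(pmin(pmax(p, 1e-8), 1 - 1e-8))
}

#' 30-day standardized precipitation index
#'
#' For each day the trailing `window`-day precipitation sum is computed, then
#' transformed to a standard-normal scale through a gamma CDF with a point
#' mass at zero, fitted per calendar month pooled across years (so the index
#' measures anomaly relative to that time of year). The first `window - 1`
#' days are `NA`.
#'
#' @param pr Daily precipitation series (mm/day) of one station, gap-free.
#' @param dates `Date` vector parallel to `pr`.
#' @param window Accumulation window, days. Default 30.
#' @return Numeric SPI series aligned with `dates`.
#' @export
compute_spi <- function(pr, dates, window = 30) {
  if (length(pr) != length(dates)) stop("compute_spi: length mismatch", call. = FALSE)
  if (length(pr) < window) stop("compute_spi: series shorter than window", call. = FALSE)
  if (length(pr) < 5 * 365) {
    warning("compute_spi: fewer than 5 years of data; gamma fits may be unstable")
  }
  sums <- as.numeric(stats::filter(pr, rep(1, window), sides = 1))
  month <- as.integer(format(as.Date(dates), "%m"))
  out <- rep(NA_real_, length(pr))
  valid <- !is.na(sums)
  for (m in sort(unique(month[valid]))) {
    idx <- which(valid & month == m)
    fit <- spi_fit(sums[idx])
    out[idx] <- spi_value(fit, sums[idx])
  }
  out
}

#' Derive SPI and VPD columns on a weather table
#'
#' Adds `VPD` (from `tas` and `RH`) and `SPI` (from `pr`, per station) to a
#' validated weather table, completing the seven composite-model covariates.
#'
#' @param weather Weather table (see [read_weather()]).
#' @param spi_window SPI accumulation window in days. Default 30.
#' @return The table with `VPD` and `SPI` columns added.
#' @export
derive_covariates <- function(weather, spi_window = 30) {
  weather$VPD <- compute_vpd(weather$tas, weather$RH)
  weather$SPI <- NA_real_
  for (sid in unique(weather$station_id)) {
    i <- which(weather$station_id == sid)
    weather$SPI[i] <- compute_spi(weather$pr[i], weather$date[i], spi_window)
  }
  weather
}

#' Min/max standardization over pooled observation and scenario values
#'
#' Both series are rescaled by the *pooled* minimum and maximum (union of the
#' two series), so the pooled minimum maps to 0 and the pooled maximum to 1.
#' Used before comparing observed and scenario covariates so that per-covariate
#' errors are unit-free and comparable.
#'
#' @param obs_series,scn_series Numeric vectors.
#' @return List with `obs`, `scn` (standardized series) and `range`
#'   (`c(min, max)` of the pool).
#' @export
minmax_standardize <- function(obs_series, scn_series) {
  pool <- range(c(obs_series, scn_series), na.rm = TRUE)
  if (!is.finite(diff(pool)) || diff(pool) == 0) {
    stop("minmax_standardize: pooled series is constant", call. = FALSE)
  }
  list(obs = (obs_series - pool[1]) / diff(pool),
       scn = (scn_series - pool[1]) / diff(pool),
       range = pool)
}
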