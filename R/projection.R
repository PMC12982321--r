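#' Apply a model chain to a scenario ensemble over named periods
#'
#' For every simulation, station and season, the four-phase model chain is
#' run from a fixed sowing date (month-day of the calendar year preceding
#' harvest; default October 30). Per-station medians of each phase's
#' predicted date — expressed in days after sowing and days after emergence
#' (DAE) — are computed within each named period across seasons and
#' simulations, from non-censored seasons only; the censoring fraction is
#' reported.
#'
#' @param models Named list of `composite_model`s per phase (the selected
#'   chain).
#' @param ensemble A [scenario_ensemble()].
#' @param sowing_day `"MM-DD"` fixed sowing date. Default `"10-30"`.
#' @param periods Named list of `c(start_year, end_year)` harvest-year
#'   windows, e.g. `list(reference = c(1981, 2010), "2085" = c(2070, 2099))`.
#' @param horizons Per-phase scan horizons (days), as in [chain_phases()].
#' @return Object of class `projection_summary`: list with `seasons` (per
#'   simulation x station x season phase predictions) and `period_medians`
#'   (per station x period x phase medians with censoring fractions).
#' @export
project_periods <- function(models, ensemble, sowing_day = "10-30",
                            periods, horizons = 250) {
  stopifnot(length(periods) >= 1, !is.null(names(periods)))
  all_years <- unlist(lapply(periods, function(p) seq(p[1], p[2])))
  seasons <- sort(unique(all_years))
  rows <- list()
  for (sim in ensemble$simulations) {
    wsplit <- split(sim$weather, sim$weather$station_id)
    for (sid in ensemble$stations) {
      w <- wsplit[[sid]]
      for (yr in seasons) {
        sowing <- as.Date(paste0(yr - 1, "-", sowing_day))
        if (is.na(match(sowing, w$date))) next
        ch <- tryCatch(chain_phases(models, w, sowing, horizons),
                       error = function(e) NULL)
        if (is.null(ch)) next
        emergence <- ch$end[ch$phase == "sowing-emergence"]
        rows[[length(rows) + 1]] <- data.frame(
          simulation_id = sim$simulation_id, rcm_id = sim$rcm_id,
          rcp_label = sim$rcp_label, station_id = sid, season = yr,
          phase = ch$phase,
          date = ch$end,
          days_after_sowing = as.numeric(ch$end - sowing),
          days_after_emergence = as.numeric(ch$end - emergence),
          censored = ch$censored)
      }
    }
  }
  if (length(rows) == 0) stop("project_periods: ensemble covers no requested season",
                              call. = FALSE)
  seasons_df <- do.call(rbind, rows)
  rownames(seasons_df) <- NULL

  med_rows <- list()
  for (pn in names(periods)) {
    p <- periods[[pn]]
    sub <- seasons_df[seasons_df$season >= p[1] & seasons_df$season <= p[2], ]
    if (nrow(sub) == 0) {
      stop("project_periods: period '", pn, "' outside ensemble coverage",
           call. = FALSE)
    }
    for (sid in unique(sub$station_id)) {
      for (ph in PHENO_PHASES) {
        g <- sub[sub$station_id == sid & sub$phase == ph, ]
        ok <- !g$censored
        med_rows[[length(med_rows) + 1]] <- data.frame(
          period = pn, station_id = sid, phase = ph,
          median_days_after_sowing = if (any(ok)) median(g$days_after_sowing[ok]) else NA_real_,
          median_days_after_emergence = if (any(ok)) median(g$days_after_emergence[ok]) else NA_real_,
          n = sum(ok), censoring_fraction = mean(!ok))
      }
    }
  }
  med <- do.call(rbind, med_rows)
  rownames(med) <- NULL
  structure(list(seasons = seasons_df, period_medians = med,
                 sowing_day = sowing_day),
            class = "projection_summary")
}

#' @export
print.projection_summary <- function(x, ...) {
  cat("<projection_summary> ", length(unique(x$seasons$simulation_id)),
      " simulation(s), ", length(unique(x$seasons$station_id)),
      " station(s), sowing ", x$sowing_day, "\n", sep = "")
  print(x$period_medians)
  invisible(x)
}

#' Centered 30-season rolling mean of an even order
#'
#' Classical centered moving average for an even window: the two outermost
#' seasons enter with half weight, so a linear trend is reproduced exactly on
#' interior points. Near the series ends the window truncates symmetrically
#' to the available seasons (at least `min_half` on each side).
#'
#' @param x Numeric series ordered by season.
#' @param window Even window length in seasons. Default 30.
#' @param min_half Minimum half-window retained at the ends. Default 5.
#' @return Smoothed series of the same length.
#' @export
rolling_mean_centered <- function(x, window = 30, min_half = 5) {
  n <- length(x)
  h <- window / 2
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    k <- min(h, t - 1, n - t)        # symmetric available half-width
    k <- max(k, 0)
    if (k >= h) {
      idx <- (t - h):(t + h)
      wts <- c(0.5, rep(1, window - 1), 0.5) / window
    } else {
      idx <- (t - k):(t + k)
      wts <- rep(1 / length(idx), length(idx))
    }
    out[t] <- sum(x[idx] * wts)
  }
  attr(out, "truncated") <- c(head = min(h, n), tail = min(h, n))
  out
}

#' Rolling 30-season trends with cross-station envelopes
#'
#' Smooths each simulation x station series of predicted values (e.g. phase
#' dates in days after emergence) with a two-sided 30-season rolling mean,
#' then summarizes across stations per season with minimum, median and
#' maximum (pointwise, so min <= median <= max everywhere).
#'
#' @param predictions `data.frame` with columns `simulation_id`,
#'   `station_id`, `season` and `value`.
#' @param window Rolling window in seasons. Default 30.
#' @return List with `smoothed` (per simulation x station) and `envelope`
#'   (per simulation x season: `min`, `median`, `max` across stations).
#' @export
rolling_trend <- function(predictions, window = 30) {
  need <- c("simulation_id", "station_id", "season", "value")
  stopifnot(all(need %in% names(predictions)))
  sm <- lapply(split(predictions, predictions[c("simulation_id", "station_id")],
                     drop = TRUE), function(g) {
    g <- g[order(g$season), , drop = FALSE]
    if (nrow(g) < window) {
      stop("rolling_trend: fewer than ", window, " seasons for ",
           g$simulation_id[1], "/", g$station_id[1], call. = FALSE)
    }
    g$smoothed <- as.numeric(rolling_mean_centered(g$value, window))
    g
  })
  smoothed <- do.call(rbind, sm)
  rownames(smoothed) <- NULL
  env <- do.call(rbind, lapply(
    split(smoothed, smoothed[c("simulation_id", "season")], drop = TRUE),
    function(g) data.frame(simulation_id = g$simulation_id[1],
                           season = g$season[1],
                           min = min(g$smoothed), median = median(g$smoothed),
                           max = max(g$smoothed))))
  env <- env[order(env$simulation_id, env$season), ]
  rownames(env) <- NULL
  list(smoothed = smoothed, envelope = env)
}
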