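#' Best model per complexity level
#'
#' Given per-model metrics, keeps for each complexity (number of covariates)
#' the model with the smallest RMSE; ties break towards the lexicographically
#' smallest subset id — deterministic and auditable.
#'
#' @param metrics `data.frame` with columns `model_id`, `complexity`, `rmse`
#'   and optionally `mae`, `cor`.
#' @return `data.frame` (one row per complexity) of class
#'   `complexity_profile`.
#' @export
best_per_complexity <- function(metrics) {
  stopifnot(all(c("model_id", "complexity", "rmse") %in% names(metrics)))
  out <- do.call(rbind, lapply(split(metrics, metrics$complexity), function(g) {
    g[order(g$rmse, g$model_id), , drop = FALSE][1, , drop = FALSE]
  }))
  out <- out[order(out$complexity), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("complexity_profile", "data.frame")
  out
}

# overall winner on a profile: smallest score, ties -> fewer covariates,
# then lexicographic id
pick_overall <- function(profile, score_col = "rmse") {
  ord <- order(profile[[score_col]], profile$complexity, profile$model_id)
  profile[ord[1], , drop = FALSE]
}

selection_outcome <- function(strategy, phase, winner, profile) {
  structure(list(strategy = strategy, phase = phase,
                 model_id = winner$model_id,
                 complexity = winner$complexity,
                 trace = profile),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat("<selection_outcome> ", x$strategy, " [", x$phase, "]: ",
      x$model_id, " (complexity ", x$complexity, ")\n", sep = "")
  invisible(x)
}

#' Max_GT model selection: best fit to ground-truth phenology
#'
#' Evaluates every composite model of the grid on held-out validation
#' environments (RMSE, MAE, Pearson r between observed and predicted phase
#' durations), keeps the RMSE-best model per complexity, and declares the
#' global RMSE minimum the winner (ties towards fewer covariates, then
#' lexicographic subset id).
#'
#' @param grid A [fit_model_grid()] result.
#' @param environments Validation environments (disjoint from training).
#' @param weather Weather table with derived covariates.
#' @return List with `profile` (a `complexity_profile` carrying `rmse_gt`)
#'   and `outcome` (a `selection_outcome`), plus the full `metrics` table.
#' @export
select_max_gt <- function(grid, environments, weather) {
  if (nrow(environments) == 0) stop("select_max_gt: empty validation set",
                                    call. = FALSE)
  rows <- lapply(grid$models, function(m) {
    pred <- predict_environment_durations(m, environments, weather)
    met <- evaluate_model(pred$predicted, pred$observed)
    data.frame(model_id = m$subset_id, complexity = m$complexity,
               rmse = met$rmse, mae = met$mae, cor = met$cor,
               n = met$n, n_censored = met$n_censored)
  })
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  profile <- best_per_complexity(metrics)
  outcome <- selection_outcome("Max_GT", grid$phase, pick_overall(profile),
                               profile)
  list(profile = profile, outcome = outcome, metrics = metrics)
}

#' Median observed phase-start days of year
#'
#' Default fixed phase starts for [select_max_cs()]: per phase, the median
#' day-of-year of the observed phase start. A start is attributed to the
#' previous calendar year (relative to harvest) when the median day-of-year
#' falls after mid-year, as for the autumn sowing of winter wheat.
#'
#' @param environments Phenology environment table.
#' @return `data.frame` with `phase`, `month_day` (`"MM-DD"`), `prev_year`.
#' @export
median_phase_starts <- function(environments) {
  rows <- lapply(PHENO_PHASES, function(ph) {
    st <- phase_stages(ph)[1]
    d <- environments[[st]]
    d <- d[!is.na(d)]
    if (length(d) == 0) stop("median_phase_starts: no observed ", st, " dates",
                             call. = FALSE)
    doy <- as.integer(format(d, "%j"))
    md <- round(median(doy))
    ref <- as.Date(paste0("2001-01-01")) + (md - 1)  # non-leap template year
    data.frame(phase = ph, month_day = format(ref, "%m-%d"),
               prev_year = md > 182)
  })
  do.call(rbind, rows)
}

phase_start_date <- function(starts, phase, harvest_year) {
  row <- starts[starts$phase == phase, , drop = FALSE]
  if (nrow(row) != 1) stop("no fixed start for phase ", phase, call. = FALSE)
  yr <- if (row$prev_year) harvest_year - 1 else harvest_year
  as.Date(paste0(yr, "-", row$month_day))
}

#' Max_CS model selection: least sensitivity to climate-scenario input
#'
#' For each complexity level, the Max_GT-best model is driven once with
#' observed weather and once with each scenario simulation over the
#' reference period, from a fixed phase start day of year per station and
#' year (decoupling phases from each other). The RMSE between observation-
#' driven and simulation-driven predicted durations is computed per
#' simulation across station x years, averaged within each RCM and then
#' across RCMs (so over-represented RCMs do not dominate); the winner is the
#' complexity with the smallest ensemble RMSE (ties towards fewer
#' covariates).
#'
#' @param models Named list of `composite_model`s, one per complexity level
#'   (the Max_GT best-per-complexity models).
#' @param obs_weather Observed weather with derived covariates for the
#'   ensemble's stations.
#' @param ensemble A `scenario_ensemble` (see [scenario_ensemble()]).
#' @param fixed_starts Fixed phase-start table ([median_phase_starts()]
#'   format) for the models' phase.
#' @param horizon Scan horizon in days. Default 366.
#' @param average `"rmse_by_rcm"` (default: per-simulation RMSE, mean within
#'   RCM, mean across RCMs) or `"predictions_first"` (average simulation
#'   predictions per environment before a single RMSE).
#' @return List with `profile` (complexity profile carrying `rmse_cs`) and
#'   `outcome`.
#' @export
select_max_cs <- function(models, obs_weather, ensemble, fixed_starts,
                          horizon = 366,
                          average = c("rmse_by_rcm", "predictions_first")) {
  average <- match.arg(average)
  ref <- ensemble$reference_window
  phase <- models[[1]]$phase
  stations <- intersect(unique(obs_weather$station_id),
                        ensemble$stations)
  if (length(stations) == 0) stop("select_max_cs: no shared stations",
                                  call. = FALSE)
  years <- seq(ref[1], ref[2])
  obs_years <- as.integer(format(obs_weather$date, "%Y"))
  if (!any(obs_years >= ref[1] & obs_years <= ref[2])) {
    stop("select_max_cs: observations do not overlap the reference window",
         call. = FALSE)
  }
  obs_split <- split(obs_weather, obs_weather$station_id)

  predict_grid <- function(model, wsplit) {
    # durations per station x year from the fixed start under one weather source
    vapply(stations, function(sid) {
      w <- wsplit[[sid]]
      vapply(years, function(yr) {
        start <- phase_start_date(fixed_starts, phase, yr)
        if (is.na(match(start, w$date))) return(NA_real_)
        pr <- tryCatch(predict_phase_end(model, w, start, horizon),
                       error = function(e) NULL)
        if (is.null(pr) || pr$censored) NA_real_ else pr$duration
      }, 0)
    }, numeric(length(years)))
  }

  rows <- lapply(models, function(m) {
    dur_obs <- predict_grid(m, obs_split)
    per_sim <- vapply(ensemble$simulations, function(sim) {
      wsplit <- split(sim$weather, sim$weather$station_id)
      dur_sim <- predict_grid(m, wsplit)
      ok <- !is.na(dur_obs) & !is.na(dur_sim)
      if (!any(ok)) return(NA_real_)
      sqrt(mean((dur_obs[ok] - dur_sim[ok])^2))
    }, 0)
    rcm <- vapply(ensemble$simulations, `[[`, "", "rcm_id")
    if (average == "rmse_by_rcm") {
      rmse_cs <- rcm_two_stage_mean(per_sim, rcm)
    } else {
      dur_mean <- Reduce(`+`, lapply(ensemble$simulations, function(sim) {
        predict_grid(m, split(sim$weather, sim$weather$station_id))
      })) / length(ensemble$simulations)
      ok <- !is.na(dur_obs) & !is.na(dur_mean)
      rmse_cs <- sqrt(mean((dur_obs[ok] - dur_mean[ok])^2))
    }
    data.frame(model_id = m$subset_id, complexity = m$complexity,
               rmse = rmse_cs)
  })
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  profile <- best_per_complexity(metrics)
  outcome <- selection_outcome("Max_CS", phase, pick_overall(profile), profile)
  list(profile = profile, outcome = outcome, metrics = metrics)
}

# two-stage ensemble mean: per-simulation scores averaged within each RCM,
# then across RCMs, so duplicated simulations of one RCM cannot dominate
rcm_two_stage_mean <- function(per_sim, rcm) {
  mean(tapply(per_sim, rcm, mean, na.rm = TRUE))
}

#' Opt model selection: the compromise of Max_GT and Max_CS
#'
#' Per complexity level, the mean of the ground-truth RMSE and the
#' climate-scenario RMSE is computed; the winner is the smallest mean within
#' the closed complexity interval bounded by the Max_GT and Max_CS winners
#' (ties towards fewer covariates). The chosen complexity always lies inside
#' that interval.
#'
#' @param gt Result of [select_max_gt()].
#' @param cs Result of [select_max_cs()].
#' @return A `selection_outcome` whose trace carries `rmse_gt`, `rmse_cs`
#'   and `mean_rmse` per complexity.
#' @export
select_opt <- function(gt, cs) {
  shared <- intersect(gt$profile$complexity, cs$profile$complexity)
  if (length(shared) == 0) stop("select_opt: profiles share no complexity",
                                call. = FALSE)
  g <- gt$profile[match(shared, gt$profile$complexity), ]
  c_ <- cs$profile[match(shared, cs$profile$complexity), ]
  trace <- data.frame(complexity = shared, model_id = g$model_id,
                      rmse_gt = g$rmse, rmse_cs = c_$rmse,
                      mean_rmse = (g$rmse + c_$rmse) / 2)
  k_lo <- min(gt$outcome$complexity, cs$outcome$complexity)
  k_hi <- max(gt$outcome$complexity, cs$outcome$complexity)
  inside <- trace[trace$complexity >= k_lo & trace$complexity <= k_hi, ]
  ord <- order(inside$mean_rmse, inside$complexity, inside$model_id)
  winner <- inside[ord[1], , drop = FALSE]
  stopifnot(winner$complexity >= k_lo, winner$complexity <= k_hi)
  out <- selection_outcome("Opt", gt$outcome$phase,
                           data.frame(model_id = winner$model_id,
                                      complexity = winner$complexity),
                           trace)
  out$interval <- c(k_lo, k_hi)
  out
}

#' Standardize a skill score by phase-duration variability
#'
#' Divides an RMSE (days) by the standard deviation of the observed phase
#' duration (days), giving a unit-free relative uncertainty that can be
#' compared across phases and with the propagated scenario uncertainty.
#'
#' @param rmse RMSE in days.
#' @param duration_sd Standard deviation of observed phase durations, days.
#' @return Unitless ratio.
#' @export
relative_uncertainty <- function(rmse, duration_sd) {
  if (any(duration_sd <= 0)) stop("relative_uncertainty: duration_sd must be > 0",
                                  call. = FALSE)
  rmse / duration_sd
}
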