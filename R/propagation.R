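#' Per-covariate observation-vs-scenario error over the reference period
#'
#' Standardizes the observed and each simulated covariate series by their
#' pooled min/max over the reference window, computes per-simulation RMSE
#' against the observations matched by station and calendar day, and returns
#' the mean over simulations (or the within/across-RCM two-stage mean).
#' The result is unit-free, on the standardized \[0, 1\] range scale.
#'
#' @param obs Observed weather with derived covariates.
#' @param ensemble A [scenario_ensemble()].
#' @param covariate Covariate name.
#' @param reference_window `c(start_year, end_year)`; defaults to the
#'   ensemble's reference window.
#' @param average `"uniform"` (default; plain mean over simulations) or
#'   `"rcm"` (mean within each RCM, then across RCMs).
#' @return Scalar `epsilon >= 0`.
#' @export
covariate_scenario_rmse <- function(obs, ensemble, covariate,
                                    reference_window = ensemble$reference_window,
                                    average = c("uniform", "rcm")) {
  average <- match.arg(average)
  in_window <- function(w) {
    yr <- as.integer(format(w$date, "%Y"))
    w[yr >= reference_window[1] & yr <= reference_window[2] &
        w$station_id %in% ensemble$stations, , drop = FALSE]
  }
  o <- in_window(obs)
  if (nrow(o) == 0) stop("covariate_scenario_rmse: no reference overlap",
                         call. = FALSE)
  key <- function(w) paste(w$station_id, w$date)
  okey <- key(o)
  sim_vals <- lapply(ensemble$simulations, function(s) {
    w <- in_window(s$weather)
    v <- w[[covariate]][match(okey, key(w))]
    if (anyNA(v)) stop("covariate_scenario_rmse: calendars misaligned for ",
                       s$simulation_id, call. = FALSE)
    v
  })
  pool <- range(c(o[[covariate]], unlist(sim_vals)), na.rm = TRUE)
  if (diff(pool) == 0) stop("covariate_scenario_rmse: constant pooled series",
                            call. = FALSE)
  ostd <- (o[[covariate]] - pool[1]) / diff(pool)
  per_sim <- vapply(sim_vals, function(v) {
    sqrt(mean((ostd - (v - pool[1]) / diff(pool))^2))
  }, 0)
  if (average == "uniform") return(mean(per_sim))
  rcm <- vapply(ensemble$simulations, `[[`, "", "rcm_id")
  mean(tapply(per_sim, rcm, mean))
}

#' Root-sum-of-squares propagation of per-covariate errors
#'
#' `epsilon_f = sqrt(sum(epsilon_i^2))`: the combined error of an additive
#' model over `n` covariates with uncorrelated, roughly homoscedastic
#' per-covariate errors.
#'
#' @param errors Numeric vector of per-covariate errors (>= 0, length 1..7).
#' @return Scalar `epsilon_f`.
#' @export
propagate_rss <- function(errors) {
  if (length(errors) < 1 || length(errors) > 7) {
    stop("propagate_rss: need 1..7 errors", call. = FALSE)
  }
  if (any(errors < 0)) stop("propagate_rss: negative error", call. = FALSE)
  sqrt(sum(errors^2))
}

#' Propagated uncertainty for every covariate subset
#'
#' Applies [propagate_rss()] to each enumerated subset (127 for the full
#' seven covariates). Since the norm is monotone, adding a covariate never
#' decreases the propagated uncertainty — the structural reason scenario
#' input data favours simpler models.
#'
#' @param errors Named numeric vector: covariate -> epsilon.
#' @param subsets List of covariate subsets (default: all non-empty subsets
#'   of `names(errors)`).
#' @return Named numeric vector keyed by subset id.
#' @export
propagate_grid <- function(errors, subsets = enumerate_combinations(names(errors))) {
  out <- vapply(subsets, function(s) {
    missing <- setdiff(s, names(errors))
    if (length(missing) > 0) {
      stop("propagate_grid: no error for covariate(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    propagate_rss(errors[s])
  }, 0)
  names(out) <- vapply(subsets, subset_id, "")
  out
}
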