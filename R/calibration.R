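#' Calibration configuration
#'
#' Controls the two-step constrained optimization and the subsampling
#' ensemble. Defaults follow the reference procedure: coarse step with at
#' most 500 evaluations and relative tolerance 1e-2, fine step with
#' 1000 x (number of parameters) evaluations and relative tolerance 1e-8,
#' absolute local tolerance 1e-24, and an ensemble of 20 fits on random 80%
#' subsamples of the training data (64% of all data per run after the 80/20
#' train/validation split).
#'
#' @param coarse_max_iter Max evaluations of the coarse step. Default 500.
#' @param fine_max_iter_factor Fine-step evaluations per parameter. Default 1000.
#' @param abs_tol Local absolute tolerance. Default 1e-24.
#' @param rel_tol_coarse,rel_tol_fine Relative tolerances. Defaults 1e-2, 1e-8.
#' @param ensemble_runs Number of subsample fits. Default 20.
#' @param subsample_fraction Fraction of training environments per run. Default 0.8.
#' @param start_quantiles Quantiles of the observed covariate used as starting
#'   values for covariate-unit parameters (base, optimum, maximum).
#'   Default `c(0.05, 0.5, 0.95)`.
#' @param unit_free_starts Named starting values for unit-free parameters.
#' @param seed Integer seed driving the subsampling (required for ensembles).
#' @return List of class `calibration_config`.
#' @export
calibration_config <- function(coarse_max_iter = 500,
                               fine_max_iter_factor = 1000,
                               abs_tol = 1e-24,
                               rel_tol_coarse = 1e-2,
                               rel_tol_fine = 1e-8,
                               ensemble_runs = 20,
                               subsample_fraction = 0.8,
                               start_quantiles = c(0.05, 0.5, 0.95),
                               unit_free_starts = c(slope = 1, intercept = 0,
                                                    Asym = 1, lrc = 0, r = 1),
                               seed = NULL) {
  stopifnot(abs_tol > 0, rel_tol_coarse > 0, rel_tol_fine > 0,
            ensemble_runs >= 1,
            subsample_fraction > 0, subsample_fraction <= 1)
  structure(list(coarse_max_iter = coarse_max_iter,
                 fine_max_iter_factor = fine_max_iter_factor,
                 abs_tol = abs_tol, rel_tol_coarse = rel_tol_coarse,
                 rel_tol_fine = rel_tol_fine, ensemble_runs = ensemble_runs,
                 subsample_fraction = subsample_fraction,
                 start_quantiles = start_quantiles,
                 unit_free_starts = unit_free_starts, seed = seed),
            class = "calibration_config")
}

#' Precompute per-environment covariate windows for one phase
#'
#' For each environment observing the phase, extracts the covariate series
#' from the phase start over `horizon_factor` times the observed duration
#' (clipped to weather coverage) into a row of an NA-padded matrix. The
#' matrix is reused across candidate parameter evaluations, ensemble
#' subsamples and DRC families.
#'
#' @param environments Phenology environment table.
#' @param weather Weather table with derived covariates.
#' @param covariate Covariate name.
#' @param phase Phase label.
#' @param horizon_factor Window length as a multiple of observed duration.
#' @return List of class `phase_env_data` with elements `x` (matrix
#'   environments x days), `obs_duration`, `horizon`, `start`, `station_id`,
#'   `env_index`.
#' @export
phase_env_data <- function(environments, weather, covariate, phase,
                           horizon_factor = 2) {
  st <- phase_stages(phase)
  has <- !is.na(environments[[st[1]]]) & !is.na(environments[[st[2]]])
  env <- environments[has, , drop = FALSE]
  if (nrow(env) == 0) stop("no environment observes phase ", phase, call. = FALSE)
  if (!covariate %in% names(weather)) {
    stop("covariate '", covariate, "' not in weather (run derive_covariates?)",
         call. = FALSE)
  }
  wsplit <- split(weather[, c("date", covariate)], weather$station_id)
  n <- nrow(env)
  D <- as.integer(env[[st[2]]] - env[[st[1]]])
  keep <- logical(n); L <- integer(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    w <- wsplit[[as.character(env$station_id[i])]]
    if (is.null(w)) { keep[i] <- FALSE; next }
    i0 <- match(env[[st[1]]][i], w$date)
    if (is.na(i0) || D[i] < 1) { keep[i] <- FALSE; next }
    avail <- nrow(w) - i0 + 1
    if (avail < D[i]) { keep[i] <- FALSE; next }
    L[i] <- min(ceiling(horizon_factor * D[i]), avail)
    rows[[i]] <- w[[covariate]][i0:(i0 + L[i] - 1)]
    keep[i] <- !anyNA(rows[[i]])
  }
  if (any(!keep)) {
    warning("phase_env_data: dropping ", sum(!keep),
            " environment(s) without full weather coverage for ", phase)
  }
  if (!any(keep)) stop("phase_env_data: no usable environments", call. = FALSE)
  idx <- which(keep)
  maxL <- max(L[idx])
  x <- matrix(NA_real_, length(idx), maxL)
  for (j in seq_along(idx)) x[j, seq_len(L[idx[j]])] <- rows[[idx[j]]]
  structure(list(x = x, obs_duration = D[idx], horizon = L[idx],
                 start = env[[st[1]]][idx],
                 station_id = env$station_id[idx],
                 env_index = which(has)[idx],
                 covariate = covariate, phase = phase),
            class = "phase_env_data")
}

subset_env_data <- function(ed, rows) {
  ed$x <- ed$x[rows, , drop = FALSE]
  ed$obs_duration <- ed$obs_duration[rows]
  ed$horizon <- ed$horizon[rows]
  ed$start <- ed$start[rows]
  ed$station_id <- ed$station_id[rows]
  ed$env_index <- ed$env_index[rows]
  ed
}

#' Starting values and bounds from covariate quantiles
#'
#' Parameters in covariate units (`psi_base`, `psi_opt`, `psi_max`) start at
#' the configured sample quantiles (defaults 0.05 / 0.5 / 0.95) of the
#' observed covariate, with bounds bracketing the starts; unit-free
#' parameters (slope, intercept, Asym, lrc, r) start at documented defaults.
#'
#' @param family DRC family.
#' @param covariate_values Sample of observed covariate values.
#' @param config A [calibration_config()].
#' @return List with numeric vectors `start`, `lower`, `upper` (named by
#'   parameter).
#' @export
initial_params <- function(family, covariate_values,
                           config = calibration_config()) {
  x <- covariate_values[!is.na(covariate_values)]
  if (length(x) < 2 || diff(range(x)) == 0) {
    stop("initial_params: degenerate covariate sample", call. = FALSE)
  }
  qs <- unname(quantile(x, config$start_quantiles, type = 7))
  rng <- diff(range(x))
  u <- config$unit_free_starts
  unit_free <- function(name, lo, hi) {
    c(start = unname(u[name]), lower = lo, upper = hi)
  }
  p <- switch(family,
    linear = list(
      intercept = unit_free("intercept", -10, 10),
      slope     = unit_free("slope", -10, 10)),
    broken_stick = list(
      psi_base = c(start = qs[1], lower = min(x) - rng, upper = qs[3]),
      slope    = unit_free("slope", -10, 10)),
    asymptotic = list(
      psi_base = c(start = qs[1], lower = min(x) - rng, upper = qs[3]),
      lrc      = unit_free("lrc", -10, 5),
      Asym     = unit_free("Asym", 1e-6, 10)),
    wang_engel = list(
      psi_base = c(start = qs[1], lower = min(x) - rng, upper = qs[2]),
      psi_opt  = c(start = qs[2], lower = qs[1], upper = max(x)),
      psi_max  = c(start = qs[3], lower = qs[2], upper = max(x) + rng),
      r        = unit_free("r", 1e-6, 10)),
    stop("unknown family ", family, call. = FALSE)
  )
  list(start = vapply(p, `[[`, 0, "start"),
       lower = vapply(p, `[[`, 0, "lower"),
       upper = vapply(p, `[[`, 0, "upper"))
}

# family feasibility for a raw parameter vector (named)
params_feasible <- function(family, par) {
  if (any(!is.finite(par))) return(FALSE)
  if (family == "wang_engel") {
    return(par[["psi_base"]] < par[["psi_opt"]] &&
           par[["psi_opt"]] < par[["psi_max"]])
  }
  if (family == "asymptotic") return(par[["Asym"]] > 0)
  TRUE
}

LOSS_SENTINEL <- 1e10

#' Duration-RMSE calibration loss of a single-covariate DRC
#'
#' For candidate parameters, each environment's required dose is the
#' accumulated dose at its observed phase end; the common required dose is
#' the median of these across environments. The predicted duration of an
#' environment is the first day its cumulative dose reaches the common
#' required dose (censored at the window end if never). The loss is the RMSE
#' between observed and predicted durations in days. Degenerate parameters
#' (constraint violations, all-zero doses) return a large optimizer-safe
#' sentinel.
#'
#' @param par Named numeric parameter vector for `family`.
#' @param family DRC family.
#' @param env_data A [phase_env_data()] object.
#' @param interpolate Use fractional crossing times (the smooth surface the
#'   optimizer sees). Default `FALSE`: whole predicted days.
#' @return RMSE in days (or the sentinel value `1e10`).
#' @export
calibration_loss <- function(par, family, env_data, interpolate = FALSE) {
  if (!params_feasible(family, par)) return(LOSS_SENTINEL)
  pred <- predict_durations_drc(par, family, env_data, interpolate = interpolate)
  if (is.null(pred)) return(LOSS_SENTINEL)
  sqrt(mean((env_data$obs_duration - pred)^2))
}

# cumulative dose matrix for raw params; NA pads contribute 0 (cumsum stays flat)
cum_dose_matrix <- function(par, family, env_data) {
  spec <- structure(list(family = family, covariate = env_data$covariate,
                         phase = env_data$phase, params = as.list(par)),
                    class = "drc_spec")
  xm <- env_data$x
  resp <- eval_drc(spec, as.vector(xm))
  resp[is.na(resp)] <- 0
  rm <- matrix(resp, nrow = nrow(xm))
  t(apply(rm, 1, cumsum))
}

# predicted durations given raw params; NULL if doses degenerate.
# interpolate = TRUE returns the fractional crossing time (linear within the
# crossing day), giving the optimizer a piecewise-smooth surface instead of
# an integer-stepped one; reported durations stay whole days.
predict_durations_drc <- function(par, family, env_data, required_dose = NULL,
                                  interpolate = FALSE) {
  cum <- cum_dose_matrix(par, family, env_data)
  n <- nrow(cum)
  if (is.null(required_dose)) {
    req_i <- cum[cbind(seq_len(n), env_data$obs_duration)]
    required_dose <- median(req_i)
    if (!is.finite(required_dose) || required_dose <= 0) return(NULL)
  }
  reached <- cum >= required_dose
  any_reached <- rowSums(reached) > 0
  pred <- ifelse(any_reached, max.col(reached, ties.method = "first"),
                 env_data$horizon)
  # a crossing found in the NA-padded flat tail means censoring at the horizon
  pred <- pmin(pred, env_data$horizon)
  if (interpolate) {
    i <- which(any_reached & pred > 1)
    if (length(i) > 0) {
      above <- cum[cbind(i, pred[i])]
      below <- cum[cbind(i, pred[i] - 1L)]
      frac <- (required_dose - below) / pmax(above - below, 1e-12)
      pred[i] <- pred[i] - 1 + pmin(pmax(frac, 0), 1)
    }
  }
  pred
}

required_dose_of <- function(par, family, env_data) {
  cum <- cum_dose_matrix(par, family, env_data)
  median(cum[cbind(seq_len(nrow(cum)), env_data$obs_duration)])
}

#' Two-step constrained DRC fit
#'
#' Step 1 ("coarse") minimizes the calibration loss with an augmented
#' Lagrangian around a COBYLA local solver from quantile-based starting
#' values within quantile-based bounds (at most `coarse_max_iter`
#' evaluations, relative tolerance `rel_tol_coarse`). Step 2 restarts at the
#' step-1 optimum with per-parameter bounds `[v - |v|, v + |v|]` (a
#' zero-valued optimum widened to `+/- 0.1`) and relative tolerance
#' `rel_tol_fine`, at most `fine_max_iter_factor x n_parameters`
#' evaluations. The better of the two optima is returned, so refinement
#' never worsens the loss.
#'
#' @param env_data A [phase_env_data()] object (training environments).
#' @param family DRC family to fit.
#' @param config A [calibration_config()].
#' @return Named numeric vector of fitted parameters with attributes `loss`
#'   and `required_dose`.
#' @export
fit_drc_two_step <- function(env_data, family, config = calibration_config()) {
  init <- initial_params(family, as.vector(env_data$x), config)
  nm <- names(init$start)
  obj <- function(p) {
    names(p) <- nm
    calibration_loss(p, family, env_data, interpolate = TRUE)
  }
  s1 <- nloptr::auglag(
    x0 = init$start, fn = obj, lower = init$lower, upper = init$upper,
    localsolver = "COBYLA", localtol = config$abs_tol,
    control = list(maxeval = config$coarse_max_iter,
                   ftol_rel = config$rel_tol_coarse))
  p1 <- s1$par; names(p1) <- nm
  widen <- pmax(abs(p1), 0.1)
  lo <- p1 - widen; hi <- p1 + widen
  # fine stage: bounded Nelder-Mead. COBYLA's linear approximations stall in
  # the curved base/optimum compensation valley of this loss; the simplex
  # refinement under the same bounds and tolerance contract does not.
  obj_box <- function(p) if (any(p < lo | p > hi)) LOSS_SENTINEL else obj(p)
  s2 <- tryCatch(
    optim(p1, obj_box, method = "Nelder-Mead",
          control = list(maxit = config$fine_max_iter_factor * length(p1),
                         reltol = config$rel_tol_fine,
                         abstol = config$abs_tol)),
    error = function(e) NULL)
  best <- if (!is.null(s2) && s2$value <= s1$value) s2 else s1
  par <- best$par; names(par) <- nm
  if (!params_feasible(family, par) || best$value >= LOSS_SENTINEL) {
    stop("fit_drc_two_step: optimizer failed to reach a feasible optimum ",
         "(best loss ", signif(best$value, 4), ")", call. = FALSE)
  }
  attr(par, "loss") <- best$value
  attr(par, "required_dose") <- required_dose_of(par, family, env_data)
  par
}

#' Subsampling-ensemble DRC calibration
#'
#' Runs `ensemble_runs` independent two-step fits, each on a seeded random
#' `subsample_fraction` subset of the training environments, and aggregates
#' by the elementwise median of the fitted parameters. Scores (Pearson r and
#' RMSE between observed and modelled durations) are computed with the
#' median parameters on the full training set. Failed runs are dropped with
#' a warning; more than half failing is an error.
#'
#' @param env_data A [phase_env_data()] (training environments).
#' @param family DRC family.
#' @param config A [calibration_config()] with a `seed`.
#' @return Object of class `calibration_result` with fields `covariate`,
#'   `phase`, `family`, `ensemble_params`, `median_params`, `required_dose`,
#'   `score_cor`, `score_rmse`, `n_failed`.
#' @export
ensemble_calibrate <- function(env_data, family, config = calibration_config()) {
  if (is.null(config$seed)) stop("ensemble_calibrate: config$seed is required",
                                 call. = FALSE)
  rng <- local_rng(config$seed)
  n <- nrow(env_data$x)
  runs <- vector("list", config$ensemble_runs)
  for (k in seq_len(config$ensemble_runs)) {
    rows <- if (config$subsample_fraction >= 1) seq_len(n) else
      rng$sample(seq_len(n), max(2, round(config$subsample_fraction * n)))
    runs[[k]] <- tryCatch(
      fit_drc_two_step(subset_env_data(env_data, rows), family, config),
      error = function(e) NULL)
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (sum(ok) < length(runs) / 2) {
    stop("ensemble_calibrate: ", sum(!ok), "/", length(runs),
         " runs failed for ", family, " on ", env_data$covariate, call. = FALSE)
  }
  if (any(!ok)) {
    warning("ensemble_calibrate: dropping ", sum(!ok), " failed run(s)")
  }
  pm <- do.call(rbind, runs[ok])
  med <- apply(pm, 2, median)
  names(med) <- colnames(pm)
  med <- enforce_family_constraints(family, med)
  req <- required_dose_of(med, family, env_data)
  pred <- predict_durations_drc(med, family, env_data, required_dose = req)
  score_rmse <- if (is.null(pred)) NA_real_ else
    sqrt(mean((env_data$obs_duration - pred)^2))
  score_cor <- if (is.null(pred) || sd(pred) == 0 ||
                   sd(env_data$obs_duration) == 0) NA_real_ else
    cor(env_data$obs_duration, pred)
  structure(list(covariate = env_data$covariate, phase = env_data$phase,
                 family = family,
                 ensemble_params = lapply(which(ok), function(i) runs[[i]]),
                 median_params = med, required_dose = req,
                 score_cor = score_cor, score_rmse = score_rmse,
                 n_failed = sum(!ok)),
            class = "calibration_result")
}

# elementwise medians of ordered triples stay ordered, but possibly not
# strictly; nudge to keep the wang_engel constraint strict
enforce_family_constraints <- function(family, par) {
  if (family == "wang_engel") {
    eps <- 1e-6
    if (par[["psi_opt"]] <= par[["psi_base"]]) par[["psi_opt"]] <- par[["psi_base"]] + eps
    if (par[["psi_max"]] <= par[["psi_opt"]]) par[["psi_max"]] <- par[["psi_opt"]] + eps
  }
  if (family == "asymptotic" && par[["Asym"]] <= 0) par[["Asym"]] <- 1e-6
  par
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> ", x$family, " on ", x$covariate, " [", x$phase,
      "]\n  cor = ", signif(x$score_cor, 3), ", rmse = ",
      signif(x$score_rmse, 3), " d, required dose = ",
      signif(x$required_dose, 4), "\n", sep = "")
  invisible(x)
}

#' DRC families calibrated for a covariate
#'
#' Temperatures (tasmin, tas, tasmax) and global radiation use only the
#' Wang-Engel response (its base/maximum bounds guard against extrapolation
#' to extreme values under warming); RH, SPI and VPD are tried with all four
#' families. With seven covariates this yields 16 covariate-DRC candidates
#' per phase (4 fixed Wang-Engel + 3 x 4 free).
#'
#' @param covariate Covariate name.
#' @return Character vector of family names.
#' @export
families_for_covariate <- function(covariate) {
  if (covariate %in% c("tasmin", "tas", "tasmax", "GR")) "wang_engel"
  else drc_families()
}

#' Pick the best DRC family by Pearson correlation
#'
#' Selects the candidate with the highest Pearson r between observed and
#' modelled durations; ties break towards fewer parameters, then lower RMSE.
#'
#' @param results List of `calibration_result`s for one covariate x phase.
#' @return The winning `calibration_result`.
#' @export
select_best_drc <- function(results) {
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0) stop("select_best_drc: no candidates", call. = FALSE)
  cors <- vapply(results, function(r) ifelse(is.na(r$score_cor), -Inf, r$score_cor), 0)
  npar <- vapply(results, function(r) length(drc_param_names(r$family)), 0)
  rmse <- vapply(results, function(r) ifelse(is.na(r$score_rmse), Inf, r$score_rmse), 0)
  ord <- order(-cors, npar, rmse)
  results[[ord[1]]]
}

#' Calibrate all covariate-DRC candidates for one phase
#'
#' Runs [ensemble_calibrate()] for every allowed (covariate, family) pair
#' (see [families_for_covariate()]) and keeps, per covariate, the family
#' with the highest Pearson score.
#'
#' @param environments Training phenology environments.
#' @param weather Weather table with derived covariates.
#' @param phase Phase label.
#' @param config A [calibration_config()] with a `seed`.
#' @param covariates Covariates to calibrate. Default the seven standard ones.
#' @return List with `best` (per-covariate winning `calibration_result`) and
#'   `all` (every candidate).
#' @export
calibrate_phase <- function(environments, weather, phase,
                            config = calibration_config(),
                            covariates = PHENO_COVARIATES) {
  all_res <- list()
  best <- list()
  for (cov in covariates) {
    ed <- phase_env_data(environments, weather, cov, phase)
    cand <- list()
    for (fam in families_for_covariate(cov)) {
      key <- paste(cov, fam, sep = ":")
      res <- tryCatch(ensemble_calibrate(ed, fam, config),
                      error = function(e) {
                        warning("calibration failed for ", key, ": ",
                                conditionMessage(e)); NULL
                      })
      cand[[fam]] <- res
      all_res[[key]] <- res
    }
    best[[cov]] <- select_best_drc(cand)
  }
  list(best = best, all = all_res)
}

#' DRC specification from a calibration result
#'
#' @param result A `calibration_result`.
#' @return A [drc_spec()] carrying the median ensemble parameters.
#' @export
drc_from_result <- function(result) {
  drc_spec(result$family, result$covariate, result$phase,
           as.list(result$median_params))
}
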