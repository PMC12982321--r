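#' Enumerate covariate subsets
#'
#' All non-empty subsets of the given covariates, deterministically ordered by
#' (size, lexicographic). Seven covariates give 127 subsets, hence 127
#' composite models per phase and 508 over the four phases.
#'
#' @param covariates Character vector of 1 to 7 distinct covariate names.
#' @return List of character vectors; each has a `subset_id` built by
#'   [subset_id()].
#' @export
enumerate_combinations <- function(covariates) {
  if (anyDuplicated(covariates)) {
    stop("enumerate_combinations: duplicated covariate names", call. = FALSE)
  }
  k <- length(covariates)
  if (k < 1 || k > 7) stop("enumerate_combinations: need 1..7 covariates", call. = FALSE)
  covariates <- sort(covariates)
  out <- list()
  for (size in seq_len(k)) {
    cmb <- combn(covariates, size, simplify = FALSE)
    ids <- vapply(cmb, paste, "", collapse = "+")
    out <- c(out, cmb[order(ids)])
  }
  out
}

#' Stable identifier of a covariate subset
#' @param covariates Character vector.
#' @return Sorted names joined by `"+"`.
#' @export
subset_id <- function(covariates) paste(sort(covariates), collapse = "+")

#' Daily binary-response training design for one phase
#'
#' For each environment, one row per day `d = 0 .. 2D - 1` (with `D` the
#' observed phase duration): the accumulated doses `Z_c(d)` of every
#' calibrated covariate over the first `d` days of the phase, and the binary
#' label `Y` which is 0 up to the day before the observed phase end
#' (`d < D`) and 1 from it onward. The equal-length post-end buffer balances
#' the two classes roughly 1:1.
#'
#' @param environments Phenology environments observing the phase.
#' @param weather Weather table with derived covariates.
#' @param drc_map Named list of [drc_spec()]s, one per covariate.
#' @param phase Phase label.
#' @return A `data.frame` of class `training_design` with columns `env`,
#'   `day`, `label` and one `Z_<covariate>` column per DRC.
#' @export
build_design <- function(environments, weather, drc_map, phase) {
  st <- phase_stages(phase)
  has <- !is.na(environments[[st[1]]]) & !is.na(environments[[st[2]]])
  env <- environments[has, , drop = FALSE]
  if (nrow(env) == 0) stop("build_design: no environment observes ", phase, call. = FALSE)
  wsplit <- split(weather, weather$station_id)
  pieces <- vector("list", nrow(env))
  for (i in seq_len(nrow(env))) {
    D <- as.integer(env[[st[2]]][i] - env[[st[1]]][i])
    w <- wsplit[[as.character(env$station_id[i])]]
    start <- env[[st[1]]][i]
    if (is.null(w) || is.na(match(start, w$date)) ||
        match(start, w$date) + 2 * D - 2 > nrow(w)) {
      stop("build_design: weather does not cover the window + buffer for ",
           env$station_id[i], "/", env$harvest_year[i], call. = FALSE)
    }
    days <- 0:(2 * D - 1)
    piece <- data.frame(
      env = paste(env$station_id[i], env$harvest_year[i], sep = "/"),
      day = days,
      label = as.integer(days >= D))
    i0 <- match(start, w$date)
    for (cov in names(drc_map)) {
      x <- w[[drc_map[[cov]]$covariate]][i0:(i0 + 2 * D - 2)]
      resp <- eval_drc(drc_map[[cov]], x)
      piece[[paste0("Z_", cov)]] <- c(0, cumsum(resp))[seq_along(days)]
    }
    pieces[[i]] <- piece
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("training_design", "data.frame")
  out
}

#' Fit the binomial-logit composite model for one covariate subset
#'
#' Maximum-likelihood logistic regression of the phase-reached label on the
#' accumulated doses of the subset's covariates:
#' `Pr(Y = 1) = logit^-1(beta_0 + sum_c beta_c Z_c)`. Under complete
#' separation (non-finite ML estimates) a lightly ridge-penalized fit
#' (lambda = 1e-6 on the slopes) is used instead.
#'
#' @param design A [build_design()] table.
#' @param subset Character vector of covariate names (columns `Z_<name>`).
#' @param drc_map Optional named list of the [drc_spec()]s behind the `Z`
#'   columns, stored on the model for prediction.
#' @return Object of class `composite_model` (without a decision threshold;
#'   see [roc_threshold()]).
#' @export
fit_composite <- function(design, subset, drc_map = NULL) {
  zcols <- paste0("Z_", subset)
  missing <- setdiff(zcols, names(design))
  if (length(missing) > 0) {
    stop("fit_composite: design lacks column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(design$label)) < 2) {
    stop("fit_composite: design has a single class", call. = FALSE)
  }
  X <- as.matrix(design[, zcols, drop = FALSE])
  y <- design$label
  fit <- suppressWarnings(glm.fit(cbind(1, X), y, family = binomial()))
  beta <- fit$coefficients
  separated <- !fit$converged || any(!is.finite(beta)) ||
    any(abs(beta[-1]) > 1e6) ||
    all(abs(fit$fitted.values - y) < 1e-8)
  penalized <- FALSE
  if (separated) {
    beta <- ridge_logistic(X, y, lambda = 1e-6)
    penalized <- TRUE
  }
  names(beta) <- c("(Intercept)", zcols)
  ll <- logistic_loglik(beta, cbind(1, X), y)
  structure(list(phase = attr(design, "phase"),
                 subset = sort(subset), subset_id = subset_id(subset),
                 coefficients = beta, drc_map = drc_map[sort(subset)],
                 threshold = NA_real_, penalized = penalized,
                 loglik = ll, complexity = length(subset)),
            class = "composite_model")
}

logistic_loglik <- function(beta, Xmat, y) {
  eta <- drop(Xmat %*% beta)
  sum(y * eta - log1p(exp(pmin(eta, 700))))
}

# Newton-Raphson ridge logistic regression; intercept unpenalized
ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 100, tol = 1e-10) {
  Xmat <- cbind(1, X)
  p <- ncol(Xmat)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xmat %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xmat * w, Xmat) + pen
    g <- crossprod(Xmat, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' @export
print.composite_model <- function(x, ...) {
  cat("<composite_model> phase ", x$phase %||% "?", ", covariates {",
      paste(x$subset, collapse = ", "), "}\n", sep = "")
  cat("  tau = ", signif(x$threshold, 4),
      if (x$penalized) " (ridge fallback)", "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROC decision threshold by Youden's J
#'
#' Scans candidate thresholds (midpoints of sorted unique predicted
#' probabilities, plus the outer bounds) and returns the one maximizing
#' `J = sensitivity + specificity - 1`; ties break towards the smallest
#' threshold.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary labels (0/1).
#' @return Threshold `tau` with attribute `J`.
#' @export
roc_threshold <- function(probabilities, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("roc_threshold: both classes must be present", call. = FALSE)
  }
  u <- sort(unique(probabilities))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  cand <- unique(pmin(pmax(cand, 1e-12), 1 - 1e-12))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  J <- vapply(cand, function(t) {
    sens <- sum(probabilities >= t & labels == 1) / n1
    spec <- sum(probabilities < t & labels == 0) / n0
    sens + spec - 1
  }, 0)
  best <- which(J == max(J))
  tau <- min(cand[best])
  if (max(J) <= 0.05) {
    warning("roc_threshold: labels nearly independent of probabilities (J = ",
            signif(max(J), 3), ")")
  }
  structure(tau, J = max(J))
}

#' Attach a ROC threshold derived from a training design
#' @param model A `composite_model`.
#' @param design The training design it was fitted on.
#' @return The model with `threshold` set.
#' @export
set_threshold <- function(model, design) {
  p <- predict_composite_prob(model, design)
  model$threshold <- as.numeric(roc_threshold(p, design$label))
  model
}

predict_composite_prob <- function(model, design) {
  X <- cbind(1, as.matrix(design[, paste0("Z_", model$subset), drop = FALSE]))
  plogis(drop(X %*% model$coefficients))
}

#' Predict the end of a phase under a composite model
#'
#' Accumulates each covariate's dose day by day from `start` and returns the
#' first day on which the model's phase-reached probability meets the
#' decision threshold. If the threshold is never met within `horizon` days
#' the prediction is censored.
#'
#' @param model A `composite_model` with a threshold and `drc_map`.
#' @param weather Single-station weather with derived covariates.
#' @param start Phase start `Date`.
#' @param horizon Maximum days scanned.
#' @return List with `end` (`Date` or `NA`), `duration` (days, horizon if
#'   censored) and `censored` (logical).
#' @export
predict_phase_end <- function(model, weather, start, horizon) {
  if (is.na(model$threshold)) stop("predict_phase_end: model has no threshold",
                                   call. = FALSE)
  if (is.null(model$drc_map)) stop("predict_phase_end: model carries no drc_map",
                                   call. = FALSE)
  start <- as.Date(start)
  i0 <- match(start, weather$date)
  if (is.na(i0)) stop("predict_phase_end: start date not in weather", call. = FALSE)
  n <- min(horizon, nrow(weather) - i0 + 1)
  if (n < 1) stop("predict_phase_end: no weather beyond start", call. = FALSE)
  eta <- rep(model$coefficients[["(Intercept)"]], n)
  for (cov in model$subset) {
    x <- weather[[model$drc_map[[cov]]$covariate]][i0:(i0 + n - 1)]
    if (anyNA(x)) stop("predict_phase_end: missing weather day(s)", call. = FALSE)
    Z <- cumsum(eval_drc(model$drc_map[[cov]], x))
    eta <- eta + model$coefficients[[paste0("Z_", cov)]] * Z
  }
  p <- plogis(eta)
  hit <- which(p >= model$threshold)
  if (length(hit) == 0) {
    return(list(end = as.Date(NA), duration = horizon, censored = TRUE))
  }
  d <- hit[1]
  list(end = start + d, duration = d, censored = FALSE)
}

#' Chain the four phase models into whole-season phenology
#'
#' Each phase starts at the previous phase's predicted end, beginning at the
#' sowing date. A censored phase censors all later phases.
#'
#' @param models Named list of `composite_model`s, one per element of
#'   [PHENO_PHASES].
#' @param weather Single-station weather with derived covariates.
#' @param sowing Sowing `Date`.
#' @param horizons Named (or single) per-phase scan horizons in days.
#' @return `data.frame` with one row per phase: `phase`, `start`, `end`,
#'   `duration`, `censored`.
#' @export
chain_phases <- function(models, weather, sowing, horizons = 400) {
  missing <- setdiff(PHENO_PHASES, names(models))
  if (length(missing) > 0) {
    stop("chain_phases: missing model(s) for phase(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(horizons) == 1) horizons <- setNames(rep(horizons, 4), PHENO_PHASES)
  start <- as.Date(sowing)
  rows <- list()
  censored <- FALSE
  for (ph in PHENO_PHASES) {
    if (censored) {
      rows[[ph]] <- data.frame(phase = ph, start = as.Date(NA), end = as.Date(NA),
                               duration = NA_integer_, censored = TRUE)
      next
    }
    pr <- predict_phase_end(models[[ph]], weather, start, horizons[[ph]])
    rows[[ph]] <- data.frame(phase = ph, start = start, end = pr$end,
                             duration = pr$duration, censored = pr$censored)
    censored <- pr$censored
    if (!censored) start <- pr$end
  }
  out <- do.call(rbind, rows[PHENO_PHASES])
  rownames(out) <- NULL
  out
}

#' Duration-prediction metrics
#'
#' RMSE, MAE and Pearson r between observed and predicted phase durations.
#' Censored pairs (`NA` predictions) are excluded with a logged count; a
#' constant vector makes r undefined (`NA`).
#'
#' @param predicted,observed Numeric vectors of durations in days.
#' @return List with `rmse`, `mae`, `cor`, `n`, `n_censored`.
#' @export
evaluate_model <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("evaluate_model: length mismatch", call. = FALSE)
  }
  ok <- !is.na(predicted) & !is.na(observed)
  n_censored <- sum(!ok)
  if (sum(ok) < 1) stop("evaluate_model: no valid pairs", call. = FALSE)
  p <- predicted[ok]; o <- observed[ok]
  r <- if (sum(ok) >= 3 && sd(p) > 0 && sd(o) > 0) cor(o, p) else NA_real_
  list(rmse = sqrt(mean((o - p)^2)), mae = mean(abs(o - p)), cor = r,
       n = sum(ok), n_censored = n_censored)
}

#' Fit the full composite-model grid for one phase
#'
#' Builds the daily training design once, then fits one logistic composite
#' model with ROC threshold for every non-empty covariate subset
#' (`2^k - 1` models for `k` calibrated covariates; 127 for the full seven).
#'
#' @param environments Training environments.
#' @param weather Weather table with derived covariates.
#' @param drc_map Named list of calibrated [drc_spec()]s per covariate.
#' @param phase Phase label.
#' @return Object of class `model_grid`: list with `phase`, `models` (named
#'   by subset id) and `design_rows`.
#' @export
fit_model_grid <- function(environments, weather, drc_map, phase) {
  design <- build_design(environments, weather, drc_map, phase)
  attr(design, "phase") <- phase
  subsets <- enumerate_combinations(names(drc_map))
  models <- list()
  for (s in subsets) {
    m <- fit_composite(design, s, drc_map = drc_map)
    m$phase <- phase
    models[[m$subset_id]] <- set_threshold(m, design)
  }
  structure(list(phase = phase, models = models, design_rows = nrow(design)),
            class = "model_grid")
}

#' @export
print.model_grid <- function(x, ...) {
  cat("<model_grid> phase ", x$phase, ": ", length(x$models),
      " composite models (design of ", x$design_rows, " daily rows)\n", sep = "")
  invisible(x)
}

#' Predict phase durations for a set of environments
#'
#' Applies one composite model to each environment, starting at the observed
#' phase start, and returns predicted durations (NA when censored).
#'
#' @param model A `composite_model`.
#' @param environments Environments observing the phase.
#' @param weather Weather table with derived covariates.
#' @param horizon_factor Scan horizon as a multiple of each observed duration.
#' @return `data.frame` with `env`, `observed`, `predicted`, `censored`.
#' @export
predict_environment_durations <- function(model, environments, weather,
                                          horizon_factor = 2) {
  st <- phase_stages(model$phase)
  has <- !is.na(environments[[st[1]]]) & !is.na(environments[[st[2]]])
  env <- environments[has, , drop = FALSE]
  wsplit <- split(weather, weather$station_id)
  out <- vector("list", nrow(env))
  for (i in seq_len(nrow(env))) {
    D <- as.integer(env[[st[2]]][i] - env[[st[1]]][i])
    w <- wsplit[[as.character(env$station_id[i])]]
    pr <- predict_phase_end(model, w, env[[st[1]]][i],
                            horizon = ceiling(horizon_factor * D))
    out[[i]] <- data.frame(
      env = paste(env$station_id[i], env$harvest_year[i], sep = "/"),
      observed = D,
      predicted = if (pr$censored) NA_integer_ else pr$duration,
      censored = pr$censored)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
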