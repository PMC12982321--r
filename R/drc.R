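#' Dose-response curve specification
#'
#' A dose-response curve (DRC) maps a daily covariate value to a daily,
#' unitless development increment. Four families are supported:
#'
#' * `linear`: `f(x) = intercept + x * slope` (may be negative),
#' * `broken_stick`: `f(x) = 0` for `x <= psi_base`, else
#'   `(x - psi_base) * slope`,
#' * `asymptotic`: `f(x) = max(0, Asym * (1 - exp(-exp(lrc) * (x - psi_base))))`,
#' * `wang_engel`: the cardinal-temperature response with base, optimum and
#'   maximum (`psi_base < psi_opt < psi_max`), scaled to peak value `r` at
#'   `psi_opt` and zero outside `(psi_base, psi_max)`; its shape exponent
#'   `alpha` follows from the three cardinal values, see [wang_engel_alpha()].
#'
#' @param family One of `"linear"`, `"broken_stick"`, `"asymptotic"`,
#'   `"wang_engel"`.
#' @param covariate Covariate name the curve responds to.
#' @param phase Phenology phase the curve is calibrated for.
#' @param params Named list of family parameters (see above; covariate-unit
#'   parameters `psi_base`, `psi_opt`, `psi_max` are in the covariate's unit).
#' @return An object of class `drc_spec`.
#' @seealso [eval_drc()], [accumulate_dose()]
#' @export
drc_spec <- function(family, covariate, phase = NULL, params = list()) {
  family <- match.arg(family, drc_families())
  spec <- structure(
    list(family = family, covariate = covariate, phase = phase,
         params = lapply(params, as.numeric)),
    class = "drc_spec"
  )
  validate_drc_spec(spec)
  spec
}

drc_families <- function() c("linear", "broken_stick", "asymptotic", "wang_engel")

drc_param_names <- function(family) {
  switch(family,
    linear       = c("intercept", "slope"),
    broken_stick = c("psi_base", "slope"),
    asymptotic   = c("psi_base", "lrc", "Asym"),
    wang_engel   = c("psi_base", "psi_opt", "psi_max", "r")
  )
}

validate_drc_spec <- function(spec) {
  p <- spec$params
  need <- drc_param_names(spec$family)
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    stop("drc_spec(", spec$family, "): missing parameter(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(p[need])
  if (any(!is.finite(vals))) {
    stop("drc_spec(", spec$family, "): parameters must be finite", call. = FALSE)
  }
  if (spec$family == "wang_engel" &&
      !(p$psi_base < p$psi_opt && p$psi_opt < p$psi_max)) {
    stop("wang_engel requires psi_base < psi_opt < psi_max (got ",
         p$psi_base, ", ", p$psi_opt, ", ", p$psi_max, ")", call. = FALSE)
  }
  if (spec$family == "asymptotic" && p$Asym <= 0) {
    stop("asymptotic requires Asym > 0", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.drc_spec <- function(x, ...) {
  cat("<drc_spec> ", x$family, " on ", x$covariate,
      if (!is.null(x$phase)) paste0(" [", x$phase, "]"), "\n", sep = "")
  cat("  params: ",
      paste(names(x$params), signif(unlist(x$params), 5),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Shape exponent of the Wang-Engel response
#'
#' `alpha = ln(2) / ln((psi_max - psi_base) / (psi_opt - psi_base))`. It makes
#' the response peak exactly at `psi_opt` and vanish at both `psi_base` and
#' `psi_max`.
#'
#' @param psi_base,psi_opt,psi_max Cardinal covariate values,
#'   `psi_base < psi_opt < psi_max`.
#' @return Positive scalar `alpha`.
#' @export
wang_engel_alpha <- function(psi_base, psi_opt, psi_max) {
  if (!(psi_base < psi_opt && psi_opt < psi_max)) {
    stop("wang_engel_alpha: need psi_base < psi_opt < psi_max", call. = FALSE)
  }
  log(2) / log((psi_max - psi_base) / (psi_opt - psi_base))
}

#' Evaluate a dose-response curve
#'
#' Vectorised over `x`. The Wang-Engel family returns 0 at and outside its
#' cardinal interval endpoints (the inequalities are strict); the asymptotic
#' family is clipped at 0; the linear family may return negative values.
#'
#' @param spec A [drc_spec()].
#' @param x Numeric vector of covariate values.
#' @return Numeric vector of daily development responses (unitless).
#' @export
eval_drc <- function(spec, x) {
  stopifnot(inherits(spec, "drc_spec"))
  validate_drc_spec(spec)
  p <- spec$params
  x <- as.numeric(x)
  out <- switch(spec$family,
    linear = p$intercept + x * p$slope,
    broken_stick = ifelse(x > p$psi_base, (x - p$psi_base) * p$slope, 0),
    asymptotic = pmax(0, p$Asym * (1 - exp(-exp(p$lrc) * (x - p$psi_base)))),
    wang_engel = {
      a <- wang_engel_alpha(p$psi_base, p$psi_opt, p$psi_max)
      dx <- x - p$psi_base
      dopt <- p$psi_opt - p$psi_base
      inside <- !is.na(x) & x > p$psi_base & x < p$psi_max
      r <- numeric(length(x))
      r[inside] <- p$r *
        (2 * dx[inside]^a * dopt^a - dx[inside]^(2 * a)) / dopt^(2 * a)
      r
    }
  )
  out[is.na(x)] <- NA_real_
  out
}

#' Accumulate a daily dose over a phase window
#'
#' Evaluates a DRC on the covariate series of one station over the half-open
#' day window `[start, end)` and returns per-day responses and their running
#' sum (the accumulated dose `Z`). The half-open convention lets chained
#' phases share a boundary day without double counting.
#'
#' @param spec A [drc_spec()].
#' @param weather Weather table for a single station (see [read_weather()]).
#' @param start,end `Date`s bounding the window, `start <= end`.
#' @return A `data.frame` with columns `date`, `x`, `response`, `cumulative`.
#' @export
accumulate_dose <- function(spec, weather, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("accumulate_dose: end before start", call. = FALSE)
  if (!spec$covariate %in% names(weather)) {
    stop("covariate '", spec$covariate, "' not present in weather table",
         call. = FALSE)
  }
  if (length(unique(weather$station_id)) > 1) {
    stop("accumulate_dose expects a single-station weather table", call. = FALSE)
  }
  if (end == start) {
    return(data.frame(date = as.Date(character()), x = numeric(),
                      response = numeric(), cumulative = numeric()))
  }
  days <- seq(start, end - 1, by = "day")
  idx <- match(days, weather$date)
  if (anyNA(idx)) {
    stop("accumulate_dose: weather is missing ", sum(is.na(idx)),
         " day(s) in [", format(start), ", ", format(end), ")", call. = FALSE)
  }
  x <- weather[[spec$covariate]][idx]
  resp <- eval_drc(spec, x)
  data.frame(date = days, x = x, response = resp, cumulative = cumsum(resp))
}
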