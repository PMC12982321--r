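FORMAT_VERSION <- 1L

#' Write / read a DRC specification as JSON
#'
#' Round-trips decimal parameter values bit-exactly (digits are not
#' truncated on write).
#'
#' @param spec A [drc_spec()].
#' @param path Output path.
#' @return `path` / the `drc_spec`.
#' @export
write_drc_spec <- function(spec, path) {
  obj <- list(format_version = FORMAT_VERSION, family = spec$family,
              covariate = spec$covariate, phase = spec$phase,
              params = spec$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_drc_spec
#' @export
read_drc_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_format_version(obj, path)
  drc_spec(obj$family, obj$covariate, obj$phase,
           lapply(obj$params, as.numeric))
}

check_format_version <- function(obj, path) {
  if (is.null(obj$format_version)) {
    stop("missing format_version in ", path, call. = FALSE)
  }
  if (obj$format_version > FORMAT_VERSION) {
    stop("unsupported format_version ", obj$format_version, " in ", path,
         call. = FALSE)
  }
}

composite_to_list <- function(model) {
  list(phase = model$phase, subset = as.list(model$subset),
       coefficients = as.list(model$coefficients),
       threshold = model$threshold, penalized = model$penalized,
       loglik = model$loglik,
       drc_map = lapply(model$drc_map, function(s)
         list(family = s$family, covariate = s$covariate, phase = s$phase,
              params = s$params)))
}

composite_from_list <- function(obj) {
  subset <- unlist(obj$subset)
  beta <- unlist(obj$coefficients)
  drc_map <- lapply(obj$drc_map, function(s)
    drc_spec(s$family, s$covariate, s$phase, lapply(s$params, as.numeric)))
  structure(list(phase = obj$phase, subset = sort(subset),
                 subset_id = subset_id(subset), coefficients = beta,
                 drc_map = drc_map[sort(subset)],
                 threshold = as.numeric(obj$threshold %||% NA),
                 penalized = isTRUE(obj$penalized),
                 loglik = as.numeric(obj$loglik %||% NA),
                 complexity = length(subset)),
            class = "composite_model")
}

#' Write / read a composite model as JSON
#' @param model A `composite_model`.
#' @param path File path.
#' @return `path` / the `composite_model`.
#' @export
write_composite <- function(model, path) {
  obj <- c(list(format_version = FORMAT_VERSION), composite_to_list(model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_composite
#' @export
read_composite <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_format_version(obj, path)
  composite_from_list(obj)
}

#' Write / read a fitted model grid as JSON
#' @param grid A `model_grid`.
#' @param path File path.
#' @return `path` / the `model_grid`.
#' @export
write_model_grid <- function(grid, path) {
  obj <- list(format_version = FORMAT_VERSION, phase = grid$phase,
              design_rows = grid$design_rows,
              models = lapply(grid$models, composite_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Write / read a four-phase model chain as JSON
#' @param models Named list of `composite_model`s, one per phase.
#' @param path File path.
#' @return `path` / the named list of models.
#' @export
write_model_chain <- function(models, path) {
  obj <- list(format_version = FORMAT_VERSION,
              models = lapply(models, composite_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model_chain
#' @export
read_model_chain <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_format_version(obj, path)
  models <- lapply(obj$models, composite_from_list)
  names(models) <- vapply(models, `[[`, "", "phase")
  models
}

#' @rdname write_model_grid
#' @export
read_model_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_format_version(obj, path)
  models <- lapply(obj$models, composite_from_list)
  names(models) <- vapply(models, `[[`, "", "subset_id")
  structure(list(phase = obj$phase, models = models,
                 design_rows = obj$design_rows),
            class = "model_grid")
}
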