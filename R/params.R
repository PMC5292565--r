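# Parameter sets: a tibble of named constants (value, units, fitted bounds)
# merging the rule-network rate constants with the downstream cascade,
# calcium, and geometry parameters.

#' Load the packaged calibrated parameter set
#'
#' The packaged values are a re-derived calibration: receptor trafficking,
#' calcium and cascade constants were fitted against the receptor-dynamics,
#' calcium-amplitude and dose-response anchor values reported for this model
#' family (see the methods vignette). Network rate constants come from the
#' packaged ruleset file; downstream-module constants from
#' `params_calibrated_synthetic.csv`.
#'
#' @param model_file Optional path to a BNGL-subset model file (defaults to
#'   the packaged VEGF-TSP1 ruleset).
#' @param extra_file Optional path to a CSV of downstream parameters
#'   (columns name, value, units, lower, upper, description).
#' @return A tibble with columns `name`, `value`, `units`, `lower`, `upper`,
#'   `description`.
#' @export
default_params <- function(model_file = NULL, extra_file = NULL) {
  model_file <- model_file %||%
    system.file("extdata", "vegf_tsp1_model.bngl", package = "vegfsig")
  extra_file <- extra_file %||%
    system.file("extdata", "params_calibrated_synthetic.csv", package = "vegfsig")
  mdl <- read_model(model_file)
  net_par <- tibble::tibble(
    name = mdl$params$name, value = mdl$params$value,
    units = NA_character_, lower = mdl$params$value / 100,
    upper = mdl$params$value * 100, description = "network rate constant")
  ext <- utils::read.csv(extra_file, stringsAsFactors = FALSE)
  ext <- tibble::as_tibble(ext)
  dplyr::bind_rows(net_par[!net_par$name %in% ext$name, ], ext)
}

#' Get a parameter value by name
#' @param params Parameter tibble.
#' @param name Parameter name.
#' @return Numeric value.
#' @export
param_get <- function(params, name) {
  i <- match(name, params$name)
  if (any(is.na(i))) stop("unknown parameter(s): ",
                          paste(name[is.na(i)], collapse = ", "))
  params$value[i]
}

#' Set or scale parameter values
#'
#' @param params Parameter tibble.
#' @param ... Named values, e.g. `kdeg_tsp = 0.03`.
#' @return Updated tibble.
#' @export
param_set <- function(params, ...) {
  vals <- list(...)
  for (nm in names(vals)) {
    i <- match(nm, params$name)
    if (is.na(i)) {
      params <- dplyr::bind_rows(params, tibble::tibble(
        name = nm, value = as.numeric(vals[[nm]]), units = NA_character_,
        lower = NA_real_, upper = NA_real_, description = "added"))
    } else {
      params$value[i] <- as.numeric(vals[[nm]])
    }
  }
  params
}

#' Scale parameters by multiplicative fold factors
#' @param params Parameter tibble.
#' @param ... Named folds, e.g. `kdeg_tsp = 21`.
#' @return Updated tibble.
#' @export
param_scale <- function(params, ...) {
  folds <- list(...)
  if (any(unlist(folds) <= 0)) stop("fold scalings must be > 0")
  for (nm in names(folds)) {
    i <- match(nm, params$name)
    if (is.na(i)) stop("unknown parameter: ", nm)
    params$value[i] <- params$value[i] * as.numeric(folds[[nm]])
  }
  params
}

#' Validate a parameter set
#'
#' Checks that all rates are non-negative and that declared bounds contain
#' the value.
#' @param params Parameter tibble.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_params <- function(params) {
  if (any(!is.finite(params$value))) stop("non-finite parameter value")
  if (any(params$value < 0)) stop("negative rate or amount: ",
                                  paste(params$name[params$value < 0], collapse = ", "))
  has_b <- !is.na(params$lower) & !is.na(params$upper)
  bad <- has_b & (params$value < params$lower | params$value > params$upper)
  if (any(bad)) stop("value outside declared bounds: ",
                     paste(params$name[bad], collapse = ", "))
  invisible(TRUE)
}
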