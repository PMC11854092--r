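# The eight-parameter display model. A param_set stores the native-unit
# values of the eight screen controls in a fixed canonical order together
# with the range table used to map them onto the normalized [0,1] scale the
# regressor is trained on.

#' Canonical display-parameter names
#'
#' The eight heads-up-display controls in their fixed canonical order:
#' brightness, saturation, contrast, cyan, gamma, magenta, hue, yellow.
#' Every vector, CSV row and JSON object in the package uses this order.
#'
#' @return Character vector of length 8.
#' @export
param_names <- function() {
  c("brightness", "saturation", "contrast", "cyan",
    "gamma", "magenta", "hue", "yellow")
}

#' Default native parameter ranges
#'
#' The real display's knob ranges are proprietary, so the package fixes a
#' plausible native range per control: additive/scaling controls span -100
#' to 100 (gray levels for brightness and the cyan/magenta/yellow balance
#' offsets; percent for saturation and contrast), display gamma spans
#' 0.2 to 3.0, and hue spans -180 to 180 degrees. Only the normalized
#' [0,1] view ever reaches the network, so the ranges are a configuration
#' concern, not a model assumption.
#'
#' @return A data frame with columns `parameter`, `min`, `max`.
#' @export
default_param_ranges <- function() {
  data.frame(
    parameter = param_names(),
    min = c(-100, -100, -100, -100, 0.2, -100, -180, -100),
    max = c( 100,  100,  100,  100, 3.0,  100,  180,  100)
  )
}

check_ranges <- function(ranges) {
  need <- c("parameter", "min", "max")
  if (!is.data.frame(ranges) || !all(need %in% names(ranges)))
    sv_error("`ranges` must have columns parameter, min, max",
             "surgiview_config_error")
  if (!setequal(ranges$parameter, param_names()))
    sv_error("`ranges` must cover exactly the eight canonical parameters",
             "surgiview_config_error")
  ranges <- ranges[match(param_names(), ranges$parameter), ]
  if (any(ranges$min >= ranges$max))
    sv_error("degenerate parameter range: min must be < max",
             "surgiview_config_error")
  ranges
}

#' Construct a display parameter set
#'
#' @param values Named numeric vector (any order) or unnamed numeric vector
#'   of length 8 in the canonical order of [param_names()].
#' @param ranges Native range table, as from [default_param_ranges()].
#' @return An object of class `param_set`: the native values plus the range
#'   table used for normalization.
#' @examples
#' p <- param_set(c(brightness = 10, saturation = 0, contrast = 5, cyan = 0,
#'                  gamma = 1.2, magenta = 0, hue = -15, yellow = 0))
#' normalize_params(p)
#' @export
param_set <- function(values, ranges = default_param_ranges()) {
  ranges <- check_ranges(ranges)
  if (is.null(names(values))) {
    if (length(values) != 8L)
      sv_error("unnamed `values` must have length 8", "surgiview_input_error")
    names(values) <- param_names()
  }
  if (!setequal(names(values), param_names()))
    sv_error("`values` must name exactly the eight canonical parameters",
             "surgiview_input_error")
  values <- as.numeric(values[param_names()])
  names(values) <- param_names()
  bad <- values < ranges$min | values > ranges$max
  if (any(bad))
    sv_error(paste0("parameter out of native range: ",
                    paste(param_names()[bad], collapse = ", ")),
             "surgiview_range_error")
  structure(list(values = values, ranges = ranges), class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>\n")
  print(round(x$values, 4))
  invisible(x)
}

#' The identity parameter set
#'
#' The unique parameter set for which [render_params()] is the identity
#' map: zero brightness/saturation/contrast/cyan/magenta/hue/yellow and
#' gamma 1. Its normalized view is (0.5, 0.5, 0.5, 0.5, 0.2857..., 0.5,
#' 0.5, 0.5) under the default ranges.
#'
#' @inheritParams param_set
#' @return A `param_set`.
#' @export
identity_params <- function(ranges = default_param_ranges()) {
  param_set(c(brightness = 0, saturation = 0, contrast = 0, cyan = 0,
              gamma = 1, magenta = 0, hue = 0, yellow = 0), ranges)
}

#' Map parameters between native units and the normalized [0,1] scale
#'
#' `normalize_params()` applies the per-parameter affine map
#' `(v - min) / (max - min)`; `denormalize_params()` is its exact inverse.
#' The regression model is always trained on the normalized scale.
#'
#' @param params A `param_set`.
#' @param normalized Numeric vector of length 8 in `[0, 1]`, canonical order.
#' @param ranges Native range table.
#' @return `normalize_params()` a named numeric vector in `[0,1]^8`;
#'   `denormalize_params()` a `param_set`.
#' @export
normalize_params <- function(params) {
  stopifnot(inherits(params, "param_set"))
  r <- params$ranges
  v <- (params$values - r$min) / (r$max - r$min)
  names(v) <- param_names()
  v
}

#' @rdname normalize_params
#' @export
denormalize_params <- function(normalized, ranges = default_param_ranges()) {
  ranges <- check_ranges(ranges)
  if (length(normalized) != 8L || anyNA(normalized))
    sv_error("`normalized` must be 8 non-missing values",
             "surgiview_input_error")
  if (any(normalized < 0 | normalized > 1))
    sv_error("normalized values must lie in [0, 1]", "surgiview_range_error")
  param_set(ranges$min + as.numeric(normalized) * (ranges$max - ranges$min),
            ranges)
}

#' Serialize parameter sets
#'
#' JSON uses one object keyed by parameter name; CSV uses one row in the
#' canonical column order.
#'
#' @param params A `param_set`.
#' @param path File path.
#' @inheritParams param_set
#' @return Readers return a `param_set`; writers return `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "param_set"))
  jsonlite::write_json(as.list(params$values), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path, ranges = default_param_ranges()) {
  v <- unlist(jsonlite::read_json(path))
  param_set(v, ranges)
}
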