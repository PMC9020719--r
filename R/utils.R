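#' @importFrom rlang abort warn %||%
#' @importFrom stats optimize pnorm cor sd rnorm runif quantile setNames
#' @importFrom utils head modifyList packageVersion
NULL

# Dynamic land-use classes, in the order used throughout (competition
# tie-breaks and column layouts follow this order).
lucc_class_names <- function() {
  c("forest_vegetation", "grassland_vegetation", "planted_pasture",
    "agriculture", "mosaic_of_occupation", "forestry")
}

lucc_others_name <- function() "others"

# Classes whose expansion is human-driven; restriction masks act on these.
lucc_anthropic_classes <- function() {
  c("planted_pasture", "agriculture", "mosaic_of_occupation", "forestry")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- rlang::`%||%`

stop_config <- function(msg, ...) {
  rlang::abort(msg, class = "lucc_config_error", ...)
}

stop_dimension <- function(msg, ...) {
  rlang::abort(msg, class = "lucc_dimension_error", ...)
}

stop_validation <- function(msg, ...) {
  rlang::abort(msg, class = "lucc_validation_error", ...)
}
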