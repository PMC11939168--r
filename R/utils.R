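# Internal helpers shared across modules.

# Condition constructors.  Config/contract problems get their own classes so
# the CLI can map them to exit codes (2 = config error, 1 = runtime error).
stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cagecount_config_error", "cagecount_error")))
}

stop_contract <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cagecount_contract_error", "cagecount_error")))
}

stop_parse <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cagecount_parse_error", "cagecount_error")))
}

# Fast data.frame constructor: skips the checks data.frame() performs.  Used
# on hot paths (one call per simulated frame).
quick_df <- function(cols) {
  n <- if (length(cols)) length(cols[[1L]]) else 0L
  structure(cols, class = "data.frame", row.names = c(NA_integer_, -n))
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (so `round_half_up(0.25, 1)`
#' is 0.3, not base R's banker's 0.2).  Used when comparing percentages to
#' printed one-decimal values.
#'
#' @param x numeric vector (non-negative use intended).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9) / scale
}

#' Express a fraction as a one-decimal percentage
#'
#' @param x fraction (0.529... becomes 52.9).
#' @param digits decimal places kept, default 1.
#' @return percentage rounded half-up.
#' @export
as_percent <- function(x, digits = 1) round_half_up(100 * x, digits)

#' Hash a configuration object
#'
#' md5 of the canonical JSON serialization; carried in output metadata so any
#' artifact can be traced back to the exact configuration that produced it.
#'
#' @param x any JSON-serializable R object.
#' @return lowercase md5 hex string.
#' @export
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

# Clamp box coordinates to the frame; returns the modified data.frame.
clamp_boxes <- function(det, image_size) {
  if (!nrow(det)) return(det)
  det$x_min <- pmax(0, pmin(det$x_min, image_size[1]))
  det$x_max <- pmax(0, pmin(det$x_max, image_size[1]))
  det$y_min <- pmax(0, pmin(det$y_min, image_size[2]))
  det$y_max <- pmax(0, pmin(det$y_max, image_size[2]))
  det
}

`%||%` <- function(a, b) if (is.null(a)) b else a
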