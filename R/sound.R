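#' Speed of sound in fresh water
#'
#' Fifth-order polynomial in temperature for fresh water at atmospheric
#' pressure, adequate for the fully mixed, shallow lakes this package
#' simulates (no thermocline, no salinity).
#'
#' @param temperature_c Water temperature in degrees Celsius, in `[0, 35]`.
#' @return Speed of sound in m/s.
#' @examples
#' sound_speed(17.1)
#' @export
sound_speed <- function(temperature_c) {
  if (any(!is.finite(temperature_c)) ||
      any(temperature_c < 0 | temperature_c > 35)) {
    stop("`temperature_c` must be within [0, 35] degrees C", call. = FALSE)
  }
  t <- temperature_c
  1402.385 + 5.038813 * t - 5.799136e-2 * t^2 + 3.287156e-4 * t^3 -
    1.398845e-6 * t^4 + 2.787860e-9 * t^5
}

# Deterministic 32-bit substream seed from a master seed and a string id,
# so every trial gets its own reproducible stream.
substream_seed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

require_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed)) {
    stop("an explicit integer `seed` is required for reproducibility",
         call. = FALSE)
  }
  invisible(as.integer(seed))
}
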