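#' Sensor specification
#'
#' Describes one inertial sensor channel triplet: its full-scale range and
#' ADC resolution determine the units-per-count scale used to convert raw
#' integer counts to physical units, via the two's-complement full-scale
#' mapping \code{scale = 2 * range / 2^adc_bits}.
#'
#' @param name Short identifier (e.g. \code{"acc1"}).
#' @param kind \code{"accelerometer"} or \code{"gyroscope"}.
#' @param range Full-scale magnitude (g for accelerometers, deg/s for the
#'   gyroscope). Must be positive.
#' @param adc_bits ADC resolution in bits, between 8 and 16.
#' @return An object of class \code{sensor_spec}: a list with fields
#'   \code{name}, \code{kind}, \code{range}, \code{adc_bits} and the
#'   derived \code{scale} (units per count).
#' @examples
#' sensor_spec("acc1", "accelerometer", range = 16, adc_bits = 13)$scale
#' @export
sensor_spec <- function(name, kind = c("accelerometer", "gyroscope"),
                        range, adc_bits) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(range), length(range) == 1L, range > 0,
            is.numeric(adc_bits), length(adc_bits) == 1L,
            adc_bits == round(adc_bits), adc_bits >= 8, adc_bits <= 16)
  structure(
    list(name = name, kind = kind, range = as.numeric(range),
         adc_bits = as.integer(adc_bits),
         scale = 2 * range / 2^adc_bits),
    class = "sensor_spec"
  )
}

#' Default sensor suite of the recording device
#'
#' The device carries two accelerometers and a gyroscope: the primary
#' accelerometer configured for +/-16 g at 13 bits (the only sensor used
#' for feature extraction, chosen for its larger span and low power), a
#' secondary +/-8 g 14-bit accelerometer, and a +/-2000 deg/s 16-bit
#' gyroscope. All are sampled at 200 Hz.
#'
#' @return Named list of three \code{sensor_spec} objects:
#'   \code{acc1}, \code{gyro}, \code{acc2} in the channel order of the
#'   trial files.
#' @export
default_sensors <- function() {
  list(
    acc1 = sensor_spec("acc1", "accelerometer", range = 16, adc_bits = 13),
    gyro = sensor_spec("gyro", "gyroscope", range = 2000, adc_bits = 16),
    acc2 = sensor_spec("acc2", "accelerometer", range = 8, adc_bits = 14)
  )
}

#' Convert raw ADC counts to physical units
#'
#' Applies the linear two's-complement full-scale mapping
#' \code{out = raw * (2 * range) / 2^adc_bits}, so for the +/-16 g 13-bit
#' accelerometer one count is 32/8192 g and a count of -4096 maps to
#' exactly -16 g.
#'
#' @param raw Integer-valued vector of raw ADC counts.
#' @param spec A \code{\link{sensor_spec}}.
#' @return Numeric vector of the same length, in the sensor's physical
#'   units (g or deg/s).
#' @examples
#' raw_to_units(c(0L, 256L, -4096L), default_sensors()$acc1)
#' @export
raw_to_units <- function(raw, spec) {
  stopifnot(inherits(spec, "sensor_spec"))
  if (!is.numeric(raw)) {
    stop("raw counts must be numeric integers")
  }
  if (length(raw) > 0 && any(raw != round(raw))) {
    stop("raw counts must be integer-valued")
  }
  as.numeric(raw) * spec$scale
}

#' @export
print.sensor_spec <- function(x, ...) {
  unit <- if (x$kind == "accelerometer") "g" else "deg/s"
  cat(sprintf("<sensor_spec> %s (%s): +/-%g %s, %d bits, %.6g %s/count\n",
              x$name, x$kind, x$range, unit, x$adc_bits, x$scale, unit))
  invisible(x)
}
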