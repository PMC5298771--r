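#' Low-pass filter specification
#'
#' The preprocessing stage is a 4th-order IIR Butterworth low-pass filter
#' with a 5 Hz cut-off, applied causally per axis (single forward pass,
#' zero initial state), matching an online embedded detector. It can be
#' switched off to run the raw-data arm of the filtering experiment.
#'
#' @param order Filter order (default 4).
#' @param cutoff_hz -3 dB cut-off frequency in Hz (default 5); must be
#'   below the Nyquist frequency \code{fs/2}.
#' @param fs Sampling rate in Hz (default 200).
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 5, fs = 200) {
  stopifnot(is.numeric(order), length(order) == 1L, order >= 1,
            order == round(order),
            is.numeric(cutoff_hz), length(cutoff_hz) == 1L, cutoff_hz > 0,
            is.numeric(fs), length(fs) == 1L, fs > 0)
  if (cutoff_hz >= fs / 2) {
    stop("cutoff_hz must be below the Nyquist frequency fs/2 = ", fs / 2)
  }
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 fs = fs, mode = "causal"),
            class = "filter_spec")
}

#' Design the Butterworth low-pass filter
#'
#' Returns the recursive (IIR) coefficients of the Butterworth low-pass
#' realizing \code{spec}: unit DC gain, magnitude 1/sqrt(2) at the
#' cut-off, monotonically decreasing magnitude response.
#'
#' @param spec A \code{\link{filter_spec}}.
#' @return A list of class \code{lowpass_filter} with numerator \code{b},
#'   denominator \code{a} and the \code{spec}.
#' @export
design_lowpass <- function(spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  bf <- signal::butter(spec$order, W = spec$cutoff_hz / (spec$fs / 2),
                       type = "low")
  structure(list(b = as.numeric(bf$b), a = as.numeric(bf$a), spec = spec),
            class = "lowpass_filter")
}

#' Magnitude response of a designed filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| at the requested frequencies by direct
#' polynomial evaluation of the transfer function.
#'
#' @param filt A \code{\link{design_lowpass}} result.
#' @param freq_hz Numeric vector of frequencies in Hz.
#' @return Numeric vector of magnitude gains (linear, not dB).
#' @export
filter_gain <- function(filt, freq_hz) {
  stopifnot(inherits(filt, "lowpass_filter"))
  w <- 2 * pi * freq_hz / filt$spec$fs
  hpoly <- function(coef, w) {
    k <- seq_along(coef) - 1
    vapply(w, function(wi) sum(coef * exp(-1i * wi * k)), complex(1))
  }
  Mod(hpoly(filt$b, w) / hpoly(filt$a, w))
}

#' Low-pass filter an acceleration trace
#'
#' Each axis is filtered causally (single forward pass, zero initial
#' state); length and sampling rate are preserved. The start-up transient
#' of the zero initial state is accepted, as on a device powering on.
#'
#' @param trace An \code{\link{new_accel_trace}} object.
#' @param spec A \code{\link{filter_spec}} (or a pre-designed
#'   \code{lowpass_filter}).
#' @return The filtered \code{accel_trace}.
#' @export
filter_trace <- function(trace, spec = filter_spec()) {
  stopifnot(inherits(trace, "accel_trace"))
  filt <- if (inherits(spec, "lowpass_filter")) spec else design_lowpass(spec)
  n <- length(trace$ax)
  if (n <= 3 * filt$spec$order) {
    stop("trace too short to filter: need more than ",
         3 * filt$spec$order, " samples, got ", n)
  }
  run <- function(x) as.numeric(signal::filter(filt$b, filt$a, x))
  new_accel_trace(trace$fs, run(trace$ax), run(trace$ay), run(trace$az))
}
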