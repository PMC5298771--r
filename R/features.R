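#' Sliding-window specification
#'
#' Dynamic features are computed over full-overlap sliding windows: the
#' window of length \code{nv} samples advances one sample at a time. The
#' defaults follow the windows that performed best in validation: 500 ms
#' for the signal-magnitude-area features C10/C11 and the velocity
#' approximation C14, 1 s (200 samples at 200 Hz) for the other dynamic
#' features. C1, C2 and C4 are per-sample (no window).
#'
#' @param nv Window length in samples (>= 2 for windowed features).
#' @param fs Sampling rate in Hz.
#' @param stride Window advance in samples; 1 = full overlap (default and
#'   only supported value).
#' @return An object of class \code{window_spec}.
#' @export
window_spec <- function(nv, fs = 200, stride = 1L) {
  stopifnot(is.numeric(nv), length(nv) == 1L, nv >= 1, nv == round(nv),
            fs > 0, identical(as.integer(stride), 1L))
  structure(list(nv = as.integer(nv), fs = fs, stride = 1L),
            class = "window_spec")
}

#' Feature codes
#' @return Character vector \code{"C1"} ... \code{"C14"}.
#' @export
feature_codes <- function() paste0("C", 1:14)

# Default window length in seconds per feature code; NA = per-sample.
feature_default_window_s <- function(code) {
  switch(code,
         C1 = NA_real_, C2 = NA_real_, C4 = NA_real_,
         C10 = 0.5, C11 = 0.5, C14 = 0.5,
         C3 = 1, C5 = 1, C6 = 1, C7 = 1, C8 = 1, C9 = 1, C12 = 1, C13 = 1,
         stop("unknown feature code: ", code))
}

#' Features that scale linearly with the acceleration amplitude
#'
#' Scaling the trace by a > 0 scales these features by a; the orientation
#' features C4/C5 are scale-invariant and C6 scales quadratically.
#'
#' @return Character vector of amplitude-equivariant feature codes.
#' @export
amplitude_equivariant_features <- function() {
  setdiff(feature_codes(), c("C4", "C5", "C6"))
}

new_feature_series <- function(code, values, valid_from, window, fs,
                               filtered = NA) {
  if (!all(is.finite(values))) stop("feature values must be finite")
  structure(list(code = code, values = as.numeric(values),
                 valid_from = as.integer(valid_from), window = window,
                 fs = fs, filtered = filtered),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  w <- if (is.null(x$window)) "per-sample" else
    sprintf("nv=%d (%.3g s)", x$window$nv, x$window$nv / x$fs)
  cat(sprintf("<feature_series> %s: %d values, valid from sample %d, %s\n",
              x$code, length(x$values), x$valid_from, w))
  invisible(x)
}

#' Trapezoid integral of a sampled sequence
#'
#' \code{dt * (sum(values) - (values[1] + values[n]) / 2)} with
#' \code{dt = 1/fs}; exact for linear sequences.
#'
#' @param values Numeric vector of length >= 2.
#' @param fs Sampling rate in Hz (so \code{dt = 1/fs}).
#' @return The integral (a scalar).
#' @export
trapezoid_integral <- function(values, fs) {
  n <- length(values)
  if (n < 2) stop("trapezoid integral needs at least 2 samples")
  (sum(values) - (values[1] + values[n]) / 2) / fs
}

check_window <- function(trace, nv, code) {
  n <- length(trace$ax)
  if (nv < 2) stop(code, ": window must have nv >= 2 samples")
  if (n < nv) {
    stop(code, ": trace (", n, " samples) shorter than window (", nv, ")")
  }
}

#' Amplitude features C1, C2, C3
#'
#' C1 is the sum vector magnitude \code{sqrt(ax^2 + ay^2 + az^2)} per
#' sample; C2 its horizontal-plane variant \code{sqrt(ax^2 + az^2)}
#' (omitting the gravity axis y); C3 the maximum peak-to-peak amplitude
#' over the window, computed by default as the Euclidean norm of the three
#' per-axis ranges (\code{max - min} within the window), or alternatively
#' as the range of the magnitude signal C1.
#'
#' @param trace An \code{\link{new_accel_trace}}.
#' @param window A \code{\link{window_spec}} (C3 only).
#' @param c3_mode \code{"per_axis"} (default) or \code{"magnitude"}.
#' @return A list of \code{feature_series} named C1, C2, C3.
#' @export
amplitude_features <- function(trace, window = NULL,
                               c3_mode = c("per_axis", "magnitude")) {
  c3_mode <- match.arg(c3_mode)
  c1 <- sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
  c2 <- sqrt(trace$ax^2 + trace$az^2)
  out <- list(
    C1 = new_feature_series("C1", c1, 1L, NULL, trace$fs),
    C2 = new_feature_series("C2", c2, 1L, NULL, trace$fs)
  )
  if (!is.null(window)) {
    nv <- window$nv
    check_window(trace, nv, "C3")
    if (c3_mode == "per_axis") {
      rx <- roll_max(trace$ax, nv) - roll_min(trace$ax, nv)
      ry <- roll_max(trace$ay, nv) - roll_min(trace$ay, nv)
      rz <- roll_max(trace$az, nv) - roll_min(trace$az, nv)
      c3 <- sqrt(rx^2 + ry^2 + rz^2)
    } else {
      c3 <- roll_max(c1, nv) - roll_min(c1, nv)
    }
    out$C3 <- new_feature_series("C3", c3, nv, window, trace$fs)
  }
  out
}

#' Orientation features C4, C5, C6
#'
#' C4 is the per-sample tilt angle \code{atan2(sqrt(ax^2 + az^2), -ay)}
#' (as printed, referenced to the negative gravity axis); C5 the standard
#' deviation over the window of the instantaneous trunk-tilt angle
#' \code{atan2(sqrt(ax^2 + az^2), ay)}; C6 the dot product of the mean
#' horizontal vector (ax, az) over the previous window with that over the
#' current window (adjacent, non-overlapping windows).
#'
#' @param trace An \code{\link{new_accel_trace}}.
#' @param window A \code{\link{window_spec}} (C5, C6).
#' @return A list of \code{feature_series} named C4, C5, C6 (C5/C6 only
#'   when a window is given; C6 needs at least \code{2 * nv} samples).
#' @export
orientation_features <- function(trace, window = NULL) {
  c4 <- atan2(sqrt(trace$ax^2 + trace$az^2), -trace$ay)
  out <- list(C4 = new_feature_series("C4", c4, 1L, NULL, trace$fs))
  if (!is.null(window)) {
    nv <- window$nv
    check_window(trace, nv, "C5")
    tilt <- atan2(sqrt(trace$ax^2 + trace$az^2), trace$ay)
    out$C5 <- new_feature_series("C5", sqrt(roll_var_pop(tilt, nv)), nv,
                                 window, trace$fs)
    n <- length(trace$ax)
    if (n >= 2 * nv) {
      mx <- roll_mean(trace$ax, nv)
      mz <- roll_mean(trace$az, nv)
      L <- length(mx)
      cur <- (nv + 1):L
      prev <- seq_len(L - nv)
      c6 <- mx[prev] * mx[cur] + mz[prev] * mz[cur]
      out$C6 <- new_feature_series("C6", c6, 2L * nv, window, trace$fs)
    }
  }
  out
}

#' Jerk feature C7
#'
#' Rate of acceleration change across the window:
#' \code{|a(k) - a(k - nv + 1)| / (t(k) - t(k - nv + 1))}, using the full
#' 3-axis difference vector by default (\code{mode = "horizontal"} omits
#' the y axis).
#'
#' @param trace An \code{\link{new_accel_trace}}.
#' @param window A \code{\link{window_spec}}.
#' @param mode \code{"xyz"} (default) or \code{"horizontal"}.
#' @return A \code{feature_series} in g/s.
#' @export
jerk_feature <- function(trace, window, mode = c("xyz", "horizontal")) {
  mode <- match.arg(mode)
  nv <- window$nv
  check_window(trace, nv, "C7")
  n <- length(trace$ax)
  i0 <- seq_len(n - nv + 1)
  i1 <- i0 + nv - 1
  dt <- (nv - 1) / trace$fs
  dx <- trace$ax[i1] - trace$ax[i0]
  dz <- trace$az[i1] - trace$az[i0]
  sq <- dx^2 + dz^2
  if (mode == "xyz") sq <- sq + (trace$ay[i1] - trace$ay[i0])^2
  new_feature_series("C7", sqrt(sq) / dt, nv, window, trace$fs)
}

#' Standard-deviation magnitude features C8, C9
#'
#' Per-axis population standard deviations over the window combined in
#' quadrature: C8 on the horizontal plane \code{sqrt(sd_x^2 + sd_z^2)},
#' C9 over all three axes.
#'
#' @param trace An \code{\link{new_accel_trace}}.
#' @param window A \code{\link{window_spec}} with \code{nv >= 2}.
#' @return A list of \code{feature_series} named C8, C9.
#' @export
std_features <- function(trace, window) {
  nv <- window$nv
  check_window(trace, nv, "C8/C9")
  vx <- roll_var_pop(trace$ax, nv)
  vy <- roll_var_pop(trace$ay, nv)
  vz <- roll_var_pop(trace$az, nv)
  list(
    C8 = new_feature_series("C8", sqrt(vx + vz), nv, window, trace$fs),
    C9 = new_feature_series("C9", sqrt(vx + vy + vz), nv, window, trace$fs)
  )
}

#' Signal-magnitude-area features C10--C13
#'
#' C10 is the signal magnitude area
#' \code{(1/N) (int |ax| + int |ay| + int |az|) dt} over the window (N =
#' nv, dt = 1/fs, trapezoid rule); C11 its horizontal-plane variant. C12
#' and C13 are the "activity" variants integrating the magnitude signals
#' \code{sqrt(ax^2+ay^2+az^2)} and \code{sqrt(ax^2+az^2)} over the sample
#' index n (dn = 1, units g*samples), as printed.
#'
#' @param trace An \code{\link{new_accel_trace}}.
#' @param window A \code{\link{window_spec}} with \code{nv >= 2}.
#' @return A list of \code{feature_series} named C10, C11, C12, C13.
#' @export
area_features <- function(trace, window) {
  nv <- window$nv
  check_window(trace, nv, "C10-C13")
  dt <- 1 / trace$fs
  ix <- roll_trapz(abs(trace$ax), nv, dt)
  iy <- roll_trapz(abs(trace$ay), nv, dt)
  iz <- roll_trapz(abs(trace$az), nv, dt)
  m3 <- sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
  m2 <- sqrt(trace$ax^2 + trace$az^2)
  list(
    C10 = new_feature_series("C10", (ix + iy + iz) / nv, nv, window,
                             trace$fs),
    C11 = new_feature_series("C11", (ix + iz) / nv, nv, window, trace$fs),
    C12 = new_feature_series("C12", roll_trapz(m3, nv, 1), nv, window,
                             trace$fs),
    C13 = new_feature_series("C13", roll_trapz(m2, nv, 1), nv, window,
                             trace$fs)
  )
}

#' Approximate-velocity feature C14
#'
#' \code{(1/N) sqrt((int ax dt)^2 + (int az dt)^2)} with trapezoid
#' integrals of the signed horizontal axes over the window; the printed
#' 1/N normalization can be disabled for a physical velocity reading.
#'
#' @param trace An \code{\link{new_accel_trace}}.
#' @param window A \code{\link{window_spec}} with \code{nv >= 2}.
#' @param normalize Keep the printed 1/N factor (default TRUE).
#' @return A \code{feature_series}.
#' @export
velocity_feature <- function(trace, window, normalize = TRUE) {
  nv <- window$nv
  check_window(trace, nv, "C14")
  dt <- 1 / trace$fs
  ix <- roll_trapz(trace$ax, nv, dt)
  iz <- roll_trapz(trace$az, nv, dt)
  v <- sqrt(ix^2 + iz^2)
  if (normalize) v <- v / nv
  new_feature_series("C14", v, nv, window, trace$fs)
}

#' Extract one feature from a trace
#'
#' Dispatches to the feature-family functions with each feature's default
#' window (500 ms for C10, C11, C14; 1 s for the other dynamic features;
#' per-sample for C1, C2, C4).
#'
#' @param trace An \code{\link{new_accel_trace}}.
#' @param code One of \code{"C1"} ... \code{"C14"}.
#' @param window Optional \code{\link{window_spec}} override.
#' @param ... Passed to the family function (e.g. \code{c3_mode},
#'   \code{mode}, \code{normalize}).
#' @return A \code{feature_series}.
#' @examples
#' tr <- new_accel_trace(200, rnorm(600, 0, 0.1), 1 + rnorm(600, 0, 0.1),
#'                       rnorm(600, 0, 0.1))
#' extract_feature(tr, "C8")
#' @export
extract_feature <- function(trace, code, window = NULL, ...) {
  code <- match.arg(code, feature_codes())
  ws <- feature_default_window_s(code)
  if (is.null(window) && !is.na(ws)) {
    window <- window_spec(round(ws * trace$fs), fs = trace$fs)
  }
  out <- switch(code,
    C1 = ,
    C2 = ,
    C3 = amplitude_features(trace, window = window, ...)[[code]],
    C4 = ,
    C5 = ,
    C6 = orientation_features(trace, window = window)[[code]],
    C7 = jerk_feature(trace, window, ...),
    C8 = ,
    C9 = std_features(trace, window)[[code]],
    C10 = ,
    C11 = ,
    C12 = ,
    C13 = area_features(trace, window)[[code]],
    C14 = velocity_feature(trace, window, ...)
  )
  if (is.null(out)) stop(code, ": trace too short for this feature")
  out
}
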