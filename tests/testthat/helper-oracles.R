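# Independent oracles used by the feature and classifier tests. These
# deliberately recompute everything naively, window by window, without
# touching the package's rolling-window implementation.

random_trace <- function(n = 400, fs = 200, sd = 0.5) {
  new_accel_trace(fs,
                  rnorm(n, 0, sd),
                  1 + rnorm(n, 0, sd),
                  rnorm(n, 0, sd))
}

# Naive trapezoid over a window of values.
trapz_naive <- function(v, dt) (sum(v) - (v[1] + v[length(v)]) / 2) * dt

sd_pop <- function(v) sqrt(mean((v - mean(v))^2))

# Naive per-window recomputation of one feature series (valid ends only).
naive_feature <- function(trace, code, nv) {
  ax <- trace$ax; ay <- trace$ay; az <- trace$az
  fs <- trace$fs
  n <- length(ax)
  per_window <- function(first_end, f) {
    vapply(first_end:n, f, numeric(1))
  }
  switch(code,
    C1 = sqrt(ax^2 + ay^2 + az^2),
    C2 = sqrt(ax^2 + az^2),
    C3 = per_window(nv, function(k) {
      i <- (k - nv + 1):k
      sqrt(diff(range(ax[i]))^2 + diff(range(ay[i]))^2 +
             diff(range(az[i]))^2)
    }),
    C4 = atan2(sqrt(ax^2 + az^2), -ay),
    C5 = per_window(nv, function(k) {
      i <- (k - nv + 1):k
      sd_pop(atan2(sqrt(ax[i]^2 + az[i]^2), ay[i]))
    }),
    C6 = per_window(2 * nv, function(k) {
      cur <- (k - nv + 1):k
      prev <- (k - 2 * nv + 1):(k - nv)
      mean(ax[prev]) * mean(ax[cur]) + mean(az[prev]) * mean(az[cur])
    }),
    C7 = per_window(nv, function(k) {
      j <- k - nv + 1
      sqrt((ax[k] - ax[j])^2 + (ay[k] - ay[j])^2 + (az[k] - az[j])^2) /
        ((nv - 1) / fs)
    }),
    C8 = per_window(nv, function(k) {
      i <- (k - nv + 1):k
      sqrt(sd_pop(ax[i])^2 + sd_pop(az[i])^2)
    }),
    C9 = per_window(nv, function(k) {
      i <- (k - nv + 1):k
      sqrt(sd_pop(ax[i])^2 + sd_pop(ay[i])^2 + sd_pop(az[i])^2)
    }),
    C10 = per_window(nv, function(k) {
      i <- (k - nv + 1):k
      (trapz_naive(abs(ax[i]), 1 / fs) + trapz_naive(abs(ay[i]), 1 / fs) +
         trapz_naive(abs(az[i]), 1 / fs)) / nv
    }),
    C11 = per_window(nv, function(k) {
      i <- (k - nv + 1):k
      (trapz_naive(abs(ax[i]), 1 / fs) +
         trapz_naive(abs(az[i]), 1 / fs)) / nv
    }),
    C12 = per_window(nv, function(k) {
      i <- (k - nv + 1):k
      trapz_naive(sqrt(ax[i]^2 + ay[i]^2 + az[i]^2), 1)
    }),
    C13 = per_window(nv, function(k) {
      i <- (k - nv + 1):k
      trapz_naive(sqrt(ax[i]^2 + az[i]^2), 1)
    }),
    C14 = per_window(nv, function(k) {
      i <- (k - nv + 1):k
      sqrt(trapz_naive(ax[i], 1 / fs)^2 + trapz_naive(az[i], 1 / fs)^2) / nv
    }),
    stop("unknown code ", code)
  )
}

# Exhaustive threshold scan: best achievable training accuracy over a
# dense candidate grid (all midpoints plus outer sentinels).
best_ac_scan <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  is_fall <- labels == "fall"
  acs <- vapply(cand, function(t) {
    se <- sum(scores[is_fall] > t) / sum(is_fall)
    sp <- sum(scores[!is_fall] <= t) / sum(!is_fall)
    (se + sp) / 2
  }, numeric(1))
  max(acs)
}

# Small synthetic config for fast unit tests (short trials, same
# structure as the defaults).
quick_config <- function(...) {
  synth_config(durations = c(walk = 15, jog = 15, sit = 12, jump = 12,
                             lie = 12, fall = 15), ...)
}

# Random two-class score sets for threshold-fit tests.
random_scores <- function(n, overlap = 0.5) {
  labels <- sample(c("fall", "adl"), n, replace = TRUE, prob = c(0.4, 0.6))
  scores <- ifelse(labels == "fall",
                   rnorm(n, 1, overlap), rnorm(n, 0, overlap))
  list(scores = scores, labels = labels)
}
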