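# Internal O(n) sliding-window primitives for full-overlap (stride 1)
# windows of length k over a vector of length n. All return a vector of
# length n - k + 1 whose element j covers samples [j, j + k - 1].

roll_sum <- function(x, k) {
  n <- length(x)
  stopifnot(k >= 1, k <= n)
  s <- cumsum(x)
  s[k:n] - c(0, s[seq_len(n - k)])
}

roll_mean <- function(x, k) roll_sum(x, k) / k

# Population variance (divide by k). The input is centred by its global
# mean first: variance is shift-invariant, and centring avoids the
# catastrophic cancellation of the raw sum-of-squares formula.
roll_var_pop <- function(x, k) {
  xc <- x - mean(x)
  m <- roll_sum(xc, k) / k
  q <- roll_sum(xc * xc, k) / k
  pmax(q - m * m, 0)
}

# Sliding maximum by the van Herk/Gil-Werman block algorithm: O(n)
# regardless of window length.
roll_max <- function(x, k) {
  n <- length(x)
  stopifnot(k >= 1, k <= n)
  if (k == 1) return(x)
  nb <- ceiling(n / k)
  pad <- nb * k - n
  xp <- c(x, rep(-Inf, pad))
  m <- matrix(xp, nrow = k)
  pref <- as.vector(apply(m, 2, cummax))
  suff <- as.vector(apply(m[k:1, , drop = FALSE], 2,
                          cummax)[k:1, , drop = FALSE])
  i <- seq_len(n - k + 1)
  pmax(suff[i], pref[i + k - 1])
}

roll_min <- function(x, k) -roll_max(-x, k)

# Sliding trapezoid integral with step dt: dt * (sum - (first + last)/2).
roll_trapz <- function(x, k, dt) {
  n <- length(x)
  stopifnot(k >= 2, k <= n)
  i <- seq_len(n - k + 1)
  (roll_sum(x, k) - (x[i] + x[i + k - 1]) / 2) * dt
}
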