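test_that("trapezoid integral matches closed forms and a naive oracle", {
  expect_equal(trapezoid_integral(rep(1, 201), 200), 1)
  ramp <- seq(0, 1, length.out = 201)      # 1 s ramp at 200 Hz
  expect_equal(trapezoid_integral(ramp, 200), 0.5)
  set.seed(7)
  v <- rnorm(333)
  expect_equal(trapezoid_integral(v, 200), trapz_naive(v, 1 / 200),
               tolerance = 1e-12)
  expect_error(trapezoid_integral(1, 200), "at least 2")
})

test_that("amplitude features follow their per-sample definitions", {
  tr <- new_accel_trace(200, c(3, 0), c(0, 1), c(4, 0))
  f <- amplitude_features(tr)
  expect_equal(f$C1$values, c(5, 1))
  expect_equal(f$C2$values, c(5, 0))
  # constant window -> zero peak-to-peak
  trc <- new_accel_trace(200, rep(1, 50), rep(2, 50), rep(3, 50))
  f3 <- amplitude_features(trc, window_spec(10))$C3
  expect_equal(f3$values, rep(0, 41))
  expect_equal(f3$valid_from, 10L)
})

test_that("C3 magnitude-range variant differs from the per-axis default", {
  set.seed(8)
  tr <- random_trace(300)
  w <- window_spec(50)
  a <- amplitude_features(tr, w, c3_mode = "per_axis")$C3
  b <- amplitude_features(tr, w, c3_mode = "magnitude")$C3
  expect_false(isTRUE(all.equal(a$values, b$values)))
  # magnitude-range equals naive range of the C1 signal
  c1 <- sqrt(tr$ax^2 + tr$ay^2 + tr$az^2)
  naive <- vapply(50:300, function(k) diff(range(c1[(k - 49):k])), 0)
  expect_equal(b$values, naive, tolerance = 1e-12)
})

test_that("orientation features encode tilt and heading change", {
  n <- 100
  standing <- new_accel_trace(200, rep(0, n), rep(1, n), rep(0, n))
  f <- orientation_features(standing, window_spec(10))
  expect_equal(f$C4$values, rep(pi, n))   # atan2(0, -1)
  expect_equal(f$C5$values, rep(0, n - 9))
  # orthogonal mean horizontal vectors give a zero dot product
  tr <- new_accel_trace(200, c(rep(1, 10), rep(0, 10)), rep(0, 20),
                        c(rep(0, 10), rep(1, 10)))
  c6 <- orientation_features(tr, window_spec(10))$C6
  expect_equal(c6$values[length(c6$values)], 0, tolerance = 1e-12)
  expect_equal(c6$valid_from, 20L)
})

test_that("jerk is the windowed difference quotient", {
  n <- 500
  const <- new_accel_trace(200, rep(2, n), rep(-1, n), rep(0.5, n))
  expect_equal(jerk_feature(const, window_spec(200))$values,
               rep(0, n - 199))
  # 1 g step spanning a window of exactly 1 s (201 samples)
  step <- new_accel_trace(200, c(rep(0, 250), rep(1, 250)), rep(0, 500),
                          rep(0, 500))
  j <- jerk_feature(step, window_spec(201))
  expect_equal(max(j$values), 1)
  # horizontal mode drops the vertical axis
  set.seed(9)
  tr <- random_trace(300)
  jh <- jerk_feature(tr, window_spec(100), mode = "horizontal")
  i0 <- 1:(300 - 99); i1 <- i0 + 99
  expect_equal(jh$values,
               sqrt((tr$ax[i1] - tr$ax[i0])^2 + (tr$az[i1] - tr$az[i0])^2) /
                 (99 / 200), tolerance = 1e-12)
})

test_that("standard-deviation magnitudes split the horizontal plane", {
  n <- 200
  const <- new_accel_trace(200, rep(1, n), rep(1, n), rep(1, n))
  f <- std_features(const, window_spec(50))
  expect_equal(f$C8$values, rep(0, n - 49))
  expect_equal(f$C9$values, rep(0, n - 49))
  # vertical alternation is invisible on the horizontal plane
  alt <- new_accel_trace(200, rep(0, n), rep(c(1, -1), n / 2), rep(0, n))
  f2 <- std_features(alt, window_spec(50))
  expect_equal(f2$C8$values, rep(0, n - 49))
  expect_equal(f2$C9$values, rep(1, n - 49))
})

test_that("area and velocity features integrate the stated quantities", {
  n <- 400
  tr <- new_accel_trace(200, rep(0, n), rep(1, n), rep(0, n))
  f <- area_features(tr, window_spec(200))
  # unit vertical: C10 = trapezoid(1)/N ~ 1/200 (199 intervals of 1/200)
  expect_equal(f$C10$values, rep(199 / 200 / 200, n - 199))
  expect_equal(f$C10$values[1], 1 / 200, tolerance = 0.006)
  expect_equal(f$C11$values, rep(0, n - 199))
  expect_equal(f$C12$values, rep(199, n - 199))
  zero <- new_accel_trace(200, rep(0, n), rep(0, n), rep(0, n))
  fz <- area_features(zero, window_spec(200))
  for (nm in c("C10", "C11", "C12", "C13")) {
    expect_equal(fz[[nm]]$values, rep(0, n - 199))
  }
  # constant horizontal: C14 = (1/N) * 0.5 s integral
  trx <- new_accel_trace(200, rep(1, n), rep(0, n), rep(0, n))
  v <- velocity_feature(trx, window_spec(100))
  expect_equal(v$values, rep((99 / 200) / 100, n - 99))
  expect_equal(v$values[1], 0.5 / 100, tolerance = 0.011)
  expect_equal(velocity_feature(trx, window_spec(100),
                                normalize = FALSE)$values[1], 99 / 200)
  expect_equal(velocity_feature(tr, window_spec(100))$values,
               rep(0, n - 99))
})

test_that("extract_feature applies the published default windows", {
  tr <- random_trace(500)
  expect_equal(extract_feature(tr, "C8")$window$nv, 200L)
  expect_equal(extract_feature(tr, "C10")$window$nv, 100L)
  expect_equal(extract_feature(tr, "C14")$window$nv, 100L)
  c1 <- extract_feature(tr, "C1")
  expect_length(c1$values, 500)
  expect_null(c1$window)
  expect_error(extract_feature(tr, "C99"))
  short <- random_trace(50)
  expect_error(extract_feature(short, "C8"), "shorter than window")
})

test_that("every feature matches its naive window-by-window oracle", {
  set.seed(11)
  for (rep in 1:5) {
    tr <- random_trace(400)
    for (code in feature_codes()) {
      nv <- if (code %in% c("C10", "C11", "C14")) 100L else 200L
      got <- extract_feature(tr, code, window = window_spec(nv))
      want <- naive_feature(tr, code, nv)
      expect_equal(got$values, want, tolerance = 1e-9,
                   label = paste("feature", code))
    }
  }
})

test_that("horizontal-plane features are dominated by their 3-axis versions", {
  set.seed(12)
  for (rep in 1:5) {
    tr <- random_trace(400)
    f <- lapply(feature_codes(), function(code)
      extract_feature(tr, code))
    names(f) <- feature_codes()
    expect_true(all(f$C2$values <= f$C1$values + 1e-12))
    expect_true(all(f$C8$values <= f$C9$values + 1e-12))
    expect_true(all(f$C11$values <= f$C10$values + 1e-12))
    expect_true(all(f$C13$values <= f$C12$values + 1e-12))
    # nonnegativity (C6, a signed dot product, is exempt)
    for (code in setdiff(feature_codes(), "C6")) {
      expect_true(all(f[[code]]$values >= -1e-12), label = code)
    }
  }
})

test_that("features scale and shift the way their formulas dictate", {
  set.seed(13)
  tr <- random_trace(400)
  a <- 2.5
  scaled <- new_accel_trace(tr$fs, a * tr$ax, a * tr$ay, a * tr$az)
  equivariant <- amplitude_equivariant_features()
  for (code in equivariant) {
    expect_equal(extract_feature(scaled, code)$values,
                 a * extract_feature(tr, code)$values,
                 tolerance = 1e-9, label = code)
  }
  expect_equal(extract_feature(scaled, "C6")$values,
               a^2 * extract_feature(tr, "C6")$values, tolerance = 1e-9)
  for (code in c("C4", "C5")) {
    expect_equal(extract_feature(scaled, code)$values,
                 extract_feature(tr, code)$values,
                 tolerance = 1e-9, label = code)
  }
  # constant offsets vanish in range, difference and deviation features
  shift <- new_accel_trace(tr$fs, tr$ax + 0.7, tr$ay - 1.2, tr$az + 3)
  for (code in c("C3", "C7", "C8", "C9")) {
    expect_equal(extract_feature(shift, code)$values,
                 extract_feature(tr, code)$values,
                 tolerance = 1e-9, label = code)
  }
})
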