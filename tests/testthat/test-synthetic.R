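test_that("postures read the gravity vector exactly without noise", {
  cfg <- synth_config(noise_sd = 0)
  tr <- make_posture("standing", 2, cfg)
  expect_true(all(tr$ax == 0) && all(tr$ay == 1) && all(tr$az == 0))
  expect_equal(sqrt(tr$ax^2 + tr$ay^2 + tr$az^2), rep(1, 400))
  sup <- make_posture("lying-supine", 1, cfg)
  expect_true(all(sup$az == 1) && all(sup$ay == 0))
})

test_that("posture noise averages to the nominal vector", {
  set.seed(51)
  cfg <- synth_config(noise_sd = 0.05, quantize = FALSE)
  tr <- make_posture("lying-lateral", 10, cfg)
  n <- length(tr$ax)
  expect_lt(abs(mean(abs(tr$ax)) - 1), 3 * 0.05 / sqrt(n) + 1e-3)
  expect_lt(abs(mean(tr$ay)), 3 * 0.05 / sqrt(n))
  expect_error(make_posture("headstand", 1, cfg))
})

test_that("walking with zero gait amplitude degenerates to standing", {
  cfg <- quick_config(noise_sd = 0, walk_amp = c(0, 0))
  set.seed(52)
  w <- make_adl("walk", cfg)
  expect_true(all(w$trace$ay == 1) && all(w$trace$ax == 0))
  expect_equal(w$label, "adl")
  expect_equal(w$record$activity_code, "D01")
})

test_that("gait trials oscillate at their drawn fundamental frequency", {
  cfg <- quick_config(noise_sd = 0.01)
  set.seed(53)
  j <- make_adl("jog", cfg)
  y <- j$trace$ay - mean(j$trace$ay)
  n <- length(y)
  spec <- Mod(stats::fft(y))[2:(n %/% 2)]
  peak_hz <- which.max(spec) * j$trace$fs / n
  expect_equal(peak_hz, j$params$gait_freq, tolerance = j$trace$fs / n * 1.5)
})

test_that("cohort scale multiplies the dynamic excursion linearly", {
  cfg1 <- quick_config(noise_sd = 0, cohort_scale = 1)
  cfg2 <- quick_config(noise_sd = 0, cohort_scale = 0.5)
  set.seed(54); w1 <- make_adl("walk", cfg1)
  set.seed(54); w2 <- make_adl("walk", cfg2)
  p2p <- function(x) diff(range(x))
  expect_equal(p2p(w2$trace$ay), 0.5 * p2p(w1$trace$ay), tolerance = 0.02)
  expect_equal(w1$params$gait_freq, w2$params$gait_freq)
})

test_that("jumps contain a near-weightless flight before the landing", {
  cfg <- quick_config(noise_sd = 0)
  set.seed(55)
  j <- make_adl("jump", cfg)
  mag <- sqrt(j$trace$ax^2 + j$trace$ay^2 + j$trace$az^2)
  expect_lt(min(mag), 0.05)
  flight <- sum(mag < 0.05) / j$trace$fs
  expect_gte(flight, 0.1)
  expect_lte(flight, 0.35)
  expect_gt(max(j$trace$ay), 0.9 * j$params$landing_amp)
})

test_that("falls realize the drawn critical-phase parameters", {
  cfg <- synth_config(noise_sd = 0, dip_level = c(0, 0), quantize = FALSE)
  set.seed(56)
  f <- make_fall("forward", "stand", cfg)
  mag <- sqrt(f$trace$ax^2 + f$trace$ay^2 + f$trace$az^2)
  expect_equal(min(mag), 0)                       # complete free fall
  expect_equal(mag[f$impact_index], f$params$impact_amp, tolerance = 1e-12)
  expect_equal(f$trace$az[f$impact_index], f$params$impact_amp,
               tolerance = 1e-12)                 # forward = +z impact
  expect_gte(f$params$critical_s, 0.3)
  expect_lte(f$params$critical_s, 0.5)
  expect_equal(f$label, "fall")
})

test_that("after the fall the sensor rests in the lying orientation", {
  cfg <- synth_config(noise_sd = 0.01)
  lying <- list(forward = c(0, 0, -1), backward = c(0, 0, 1))
  for (dir in names(lying)) {
    set.seed(57)
    f <- make_fall(dir, "walk", cfg)
    n <- trial_length(f$record)
    tail_idx <- (n - 2 * f$trace$fs + 1):n        # final 2 s
    m <- c(mean(f$trace$ax[tail_idx]), mean(f$trace$ay[tail_idx]),
           mean(f$trace$az[tail_idx]))
    expect_equal(m, lying[[dir]], tolerance = 0.02)
  }
  set.seed(58)
  fl <- make_fall("lateral", "sit", cfg)
  n <- trial_length(fl$record)
  tail_idx <- (n - 2 * fl$trace$fs + 1):n
  expect_equal(abs(mean(fl$trace$ax[tail_idx])), 1, tolerance = 0.02)
})

test_that("elderly scaling never amplifies any dynamic excursion", {
  for (fam in c("walk", "jog", "sit", "jump", "lie")) {
    cfg1 <- quick_config(noise_sd = 0, cohort_scale = 1)
    cfg2 <- quick_config(noise_sd = 0, cohort_scale = 0.7)
    set.seed(59); a1 <- make_adl(fam, cfg1)
    set.seed(59); a2 <- make_adl(fam, cfg2)
    dev1 <- max(abs(a1$trace$ay - 1) + abs(a1$trace$ax) + abs(a1$trace$az))
    dev2 <- max(abs(a2$trace$ay - 1) + abs(a2$trace$ax) + abs(a2$trace$az))
    expect_lte(dev2, dev1 + 1e-9)
  }
})

test_that("quantization emits integer counts within the ADC range", {
  cfg <- quick_config()
  set.seed(60)
  f <- make_fall("lateral", "jog", cfg)
  for (nm in names(f$record$channels)) {
    ch <- f$record$channels[[nm]]
    expect_true(is.integer(ch))
    half <- if (startsWith(nm, "acc2")) 2^13 else 2^12
    expect_true(all(ch >= -half & ch <= half - 1) || all(ch == 0))
  }
  # gyroscope channels are emitted as zeros
  expect_true(all(f$record$channels$gyro_x == 0))
})

test_that("dataset generation is deterministic and correctly labelled", {
  cfg <- quick_config()
  d1 <- generate_dataset(12, 8, cfg, seed = 7)
  d2 <- generate_dataset(12, 8, cfg, seed = 7)
  expect_identical(lapply(d1$trials, function(x) x$record$channels),
                   lapply(d2$trials, function(x) x$record$channels))
  d3 <- generate_dataset(12, 8, cfg, seed = 8)
  expect_false(identical(d1$trials[[1]]$record$channels,
                         d3$trials[[1]]$record$channels))
  expect_equal(nrow(d1$manifest), 20)
  expect_equal(as.vector(table(d1$manifest$label)[c("adl", "fall")]),
               c(12L, 8L))
  expect_true(all(d1$truth$impact_index[d1$truth$label == "fall"] > 0))
  expect_true(all(is.na(d1$truth$impact_index[d1$truth$label == "adl"])))
})

test_that("written synthetic datasets round-trip through the manifest", {
  dir <- withr::local_tempdir()
  cfg <- quick_config()
  ds <- generate_dataset(4, 3, cfg, seed = 9, dir = dir)
  expect_true(all(file.exists(ds$manifest$path)))
  man <- scan_dataset(dir)
  expect_equal(nrow(man), 7)
  back <- read_trial(ds$manifest$path[1])
  expect_identical(back$channels, ds$trials[[1]]$record$channels)
  expect_true(file.exists(file.path(dir, "truth.csv")))
})

test_that("elderly cohort respects the protocol's activity exclusions", {
  cfg <- quick_config()
  ds <- generate_dataset(40, 5, cfg, cohort_mix = c(elderly = 1),
                         seed = 10)
  expect_true(all(ds$manifest$cohort == "elderly"))
  expect_false(any(ds$manifest$activity %in%
                     elderly_excluded_activities()))
})
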