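#' Synthetic-trial generator configuration
#'
#' Parameters of the seeded waveform generator that emulates the
#' statistical structure the detection pipeline relies on: a
#' gravity-referenced baseline posture, periodic gait, smooth sit
#' transients, jumps with a short free-fall flight and a landing spike,
#' and falls with a 300--500 ms critical phase (free-fall dip, impact
#' spike, posture change to lying). Waveforms are parametric closed forms
#' (sinusoids, raised cosines), not biomechanical simulation: the aim is
#' class structure, not realism.
#'
#' All amplitudes are in g, durations in seconds, and two-element vectors
#' are uniform draw ranges. \code{cohort_scale} multiplies every dynamic
#' (voluntary-motion, non-gravity) component; 1 models young adults,
#' values below 1 model the lower movement amplitudes of elderly
#' participants (0.7 is the package's elderly default).
#'
#' @param fs Sampling rate in Hz (default 200).
#' @param noise_sd Additive white sensor noise sd in g (default 0.01).
#' @param quantize Emulate the 13-bit/+/-16 g ADC: when TRUE (default)
#'   the returned trace is the quantized read-back of the raw counts.
#' @param cohort_scale Dynamic-amplitude multiplier in (0, 1].
#' @param durations Named trial durations in s per activity family,
#'   following the recording protocol (long gait trials 100 s, sit and
#'   jump 12 s, falls 15 s).
#' @param walk_freq,jog_freq Gait fundamental frequency ranges in Hz.
#' @param walk_amp,jog_amp Vertical gait amplitude ranges in g.
#' @param sit_amp Sit/stand transient amplitude range in g (kept below
#'   2 g).
#' @param jump_flight Jump flight-phase duration range in s.
#' @param jump_amp Jump landing-spike amplitude range in g.
#' @param impact_amp Fall impact-spike amplitude range in g.
#' @param critical_phase Fall critical-phase duration range in s.
#' @param dip_level Free-fall dip floor range in g (acceleration
#'   magnitude at the bottom of the dip).
#' @param seed Default root seed for \code{\link{generate_dataset}}.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(fs = 200,
                         noise_sd = 0.01,
                         quantize = TRUE,
                         cohort_scale = 1.0,
                         durations = c(walk = 100, jog = 100, sit = 12,
                                       jump = 12, lie = 12, fall = 15),
                         walk_freq = c(1.4, 2.0),
                         jog_freq = c(2.2, 3.0),
                         walk_amp = c(0.15, 0.35),
                         jog_amp = c(0.5, 0.9),
                         sit_amp = c(0.4, 1.2),
                         jump_flight = c(0.15, 0.30),
                         jump_amp = c(1.0, 2.5),
                         impact_amp = c(1.5, 6.0),
                         critical_phase = c(0.3, 0.5),
                         dip_level = c(0.05, 0.35),
                         seed = 1L) {
  rng2 <- function(r) length(r) == 2L && r[1] <= r[2] && all(r >= 0)
  stopifnot(fs > 0, noise_sd >= 0, is.logical(quantize),
            cohort_scale > 0, cohort_scale <= 1,
            all(c("walk", "jog", "sit", "jump", "lie", "fall") %in%
                  names(durations)),
            all(durations > 0),
            rng2(walk_freq), rng2(jog_freq), rng2(walk_amp),
            rng2(jog_amp), rng2(sit_amp), rng2(jump_flight),
            rng2(jump_amp), rng2(impact_amp), rng2(critical_phase),
            rng2(dip_level))
  structure(list(fs = fs, noise_sd = noise_sd, quantize = quantize,
                 cohort_scale = cohort_scale, durations = durations,
                 walk_freq = walk_freq, jog_freq = jog_freq,
                 walk_amp = walk_amp, jog_amp = jog_amp,
                 sit_amp = sit_amp, jump_flight = jump_flight,
                 jump_amp = jump_amp, impact_amp = impact_amp,
                 critical_phase = critical_phase, dip_level = dip_level,
                 seed = seed),
            class = "synth_config")
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

posture_vector <- function(posture) {
  switch(posture,
         "standing" = c(0, 1, 0),
         "lying-supine" = c(0, 0, 1),
         "lying-prone" = c(0, 0, -1),
         "lying-lateral" = c(1, 0, 0),
         "lying-lateral-left" = c(-1, 0, 0),
         stop("unknown posture: ", posture))
}

# Assemble a trace from a 3 x n gravity path, a 3 x n dynamic path (the
# latter scaled by cohort_scale) and additive noise; optionally pass the
# result through the ADC quantizer.
assemble_trace <- function(grav, dyn, config) {
  n <- ncol(grav)
  a <- grav + config$cohort_scale * dyn
  if (config$noise_sd > 0) {
    a <- a + matrix(stats::rnorm(3 * n, 0, config$noise_sd), nrow = 3)
  }
  tr <- new_accel_trace(config$fs, a[1, ], a[2, ], a[3, ])
  if (config$quantize) {
    spec <- default_sensors()$acc1
    q <- function(x) quantize_counts(x, spec) * spec$scale
    tr <- new_accel_trace(config$fs, q(tr$ax), q(tr$ay), q(tr$az))
  }
  tr
}

quantize_counts <- function(x, spec) {
  lo <- -2^(spec$adc_bits - 1)
  hi <- 2^(spec$adc_bits - 1) - 1
  pmin(pmax(round(x / spec$scale), lo), hi)
}

#' Generate a constant-posture trace
#'
#' A constant gravity vector plus sensor noise: standing reads (0, +1, 0)
#' g, lying supine (0, 0, +1), lying lateral (+/-1, 0, 0).
#'
#' @param posture \code{"standing"}, \code{"lying-supine"} or
#'   \code{"lying-lateral"}.
#' @param duration Duration in s (> 0).
#' @param config A \code{\link{synth_config}}.
#' @return An \code{\link{new_accel_trace}}. Uses the current RNG state;
#'   seed with \code{set.seed} for reproducibility.
#' @export
make_posture <- function(posture = c("standing", "lying-supine",
                                     "lying-lateral"),
                         duration, config = synth_config()) {
  posture <- match.arg(posture)
  stopifnot(duration > 0)
  n <- round(duration * config$fs)
  g <- posture_vector(posture)
  grav <- matrix(g, nrow = 3, ncol = n)
  assemble_trace(grav, matrix(0, 3, n), config)
}

family_activity_code <- function(family) {
  switch(family, walk = "D01", jog = "D04", sit = "D07", jump = "D19",
         lie = "D12",
         stop("unknown ADL family: ", family))
}

fall_activity_code <- function(direction, pre_activity) {
  if (pre_activity == "jog") return("F05")
  if (pre_activity == "sit") {
    return(switch(direction, forward = "F13", backward = "F14",
                  lateral = "F15"))
  }
  if (pre_activity == "stand") {
    return(switch(direction, forward = "F08", backward = "F11",
                  lateral = "F09"))
  }
  switch(direction, forward = "F01", backward = "F02", lateral = "F03")
}

new_synthetic_trial <- function(trace, config, label, family,
                                subject_code, activity_code, trial_index,
                                direction = NA_character_,
                                impact_index = NA_integer_,
                                params = list()) {
  sensors <- default_sensors()
  channels <- list(
    acc1_x = quantize_counts(trace$ax, sensors$acc1),
    acc1_y = quantize_counts(trace$ay, sensors$acc1),
    acc1_z = quantize_counts(trace$az, sensors$acc1),
    gyro_x = integer(length(trace$ax)),
    gyro_y = integer(length(trace$ax)),
    gyro_z = integer(length(trace$ax)),
    acc2_x = quantize_counts(trace$ax, sensors$acc2),
    acc2_y = quantize_counts(trace$ay, sensors$acc2),
    acc2_z = quantize_counts(trace$az, sensors$acc2)
  )
  record <- trial_record(subject_code, activity_code, trial_index,
                         channels, fs = config$fs, sensors = sensors)
  structure(list(record = record, trace = trace, label = label,
                 family = family, direction = direction,
                 impact_index = impact_index, params = params,
                 cohort = subject_cohort(subject_code)),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> %s (%s%s) %s %s trial %d, %d samples\n",
              x$family, x$label,
              if (is.na(x$direction)) "" else paste0(", ", x$direction),
              x$record$subject_code, x$record$activity_code,
              x$record$trial_index, trial_length(x$record)))
  invisible(x)
}

# Raised-cosine pulse of given width (samples), exact 1 at its centre.
raised_cosine <- function(m) {
  if (m < 3) m <- 3
  if (m %% 2 == 0) m <- m + 1
  0.5 * (1 - cos(2 * pi * seq(0, m - 1) / (m - 1)))
}

gait_dynamic <- function(n, fs, f0, amp) {
  t <- (seq_len(n) - 1) / fs
  phi_z <- stats::runif(1, 0, 2 * pi)
  phi_x <- stats::runif(1, 0, 2 * pi)
  rbind(
    0.25 * amp * sin(2 * pi * f0 * t + phi_x),
    amp * sin(2 * pi * f0 * t) + 0.3 * amp * sin(4 * pi * f0 * t),
    0.5 * amp * sin(2 * pi * f0 * t + phi_z)
  )
}

#' Generate a synthetic activity-of-daily-living trial
#'
#' Walk and jog are gravity plus a fundamental-plus-harmonic gait
#' sinusoid at a drawn frequency; sit is a pair of smooth raised-cosine
#' transients (sit down, stand up) with the standing posture preserved;
#' jump has a short free-fall flight (near-zero magnitude) followed by a
#' vertical landing spike. Dynamic amplitudes are multiplied by
#' \code{config$cohort_scale}.
#'
#' @param family \code{"walk"}, \code{"jog"}, \code{"sit"},
#'   \code{"jump"} or \code{"lie"} (lie down laterally and get back up,
#'   as in the protocol's lying ADLs: the lying episode gives ADLs the
#'   same horizontal gravity signature a completed fall has, so posture
#'   alone cannot separate the classes).
#' @param config A \code{\link{synth_config}}.
#' @param subject_code,trial_index Metadata for the embedded
#'   \code{\link{trial_record}}.
#' @return A \code{synthetic_trial} with \code{label = "adl"} and the
#'   drawn parameters in \code{$params}. Uses the current RNG state.
#' @export
make_adl <- function(family = c("walk", "jog", "sit", "jump", "lie"),
                     config = synth_config(), subject_code = "SA01",
                     trial_index = 1) {
  family <- match.arg(family)
  fs <- config$fs
  n <- round(config$durations[[family]] * fs)
  grav <- matrix(c(0, 1, 0), nrow = 3, ncol = n)
  dyn <- matrix(0, 3, n)
  params <- list()

  if (family %in% c("walk", "jog")) {
    f0 <- runif1(if (family == "walk") config$walk_freq else config$jog_freq)
    amp <- runif1(if (family == "walk") config$walk_amp else config$jog_amp)
    dyn <- gait_dynamic(n, fs, f0, amp)
    params <- list(gait_freq = f0, gait_amp = amp)
  } else if (family == "sit") {
    amp <- runif1(config$sit_amp)
    m <- round(1.2 * fs)
    pulse <- raised_cosine(m)
    down <- round(0.25 * n)
    up <- round(0.70 * n)
    for (start in c(down, up)) {
      idx <- start + seq_along(pulse) - 1
      idx <- idx[idx <= n]
      dyn[2, idx] <- dyn[2, idx] + amp * pulse[seq_along(idx)]
      dyn[3, idx] <- dyn[3, idx] + 0.3 * amp * pulse[seq_along(idx)]
    }
    params <- list(sit_amp = amp)
  } else if (family == "lie") {
    amp <- runif1(config$sit_amp)
    side <- sample(c(1, -1), 1)
    lie_vec <- c(side, 0, 0)
    n_tr <- round(2.5 * fs)               # voluntary, slow transition
    down0 <- round(0.25 * n)
    up0 <- round(0.70 * n)
    frac <- rep(0, n)
    frac[down0 + seq_len(n_tr)] <- seq_len(n_tr) / n_tr
    frac[(down0 + n_tr):up0] <- 1
    frac[up0 + seq_len(n_tr)] <- 1 - seq_len(n_tr) / n_tr
    frac <- frac[seq_len(n)]
    gdir <- outer(c(0, 1, 0), 1 - frac) + outer(lie_vec, frac)
    gnorm <- pmax(sqrt(colSums(gdir^2)), 1e-9)
    grav <- gdir / rep(gnorm, each = 3)
    pulse <- raised_cosine(round(1.0 * fs))
    for (start in c(down0, up0)) {
      idx <- start + seq_along(pulse) - 1
      idx <- idx[idx <= n]
      dyn[2, idx] <- dyn[2, idx] + 0.3 * amp * pulse[seq_along(idx)]
      dyn[1, idx] <- dyn[1, idx] +
        side * 0.1 * amp * pulse[seq_along(idx)]
    }
    params <- list(lie_amp = amp, side = side)
  } else { # jump
    flight <- runif1(config$jump_flight)
    amp <- runif1(config$jump_amp)
    t_to <- round(0.4 * n)                 # take-off sample
    nf <- round(flight * fs)
    edge <- round(0.03 * fs)               # 30 ms free-fall edges
    # gravity envelope: 1 -> 0 across the flight, exact 0 in the interior
    env <- rep(1, n)
    fl <- t_to + seq_len(nf)
    fl <- fl[fl <= n]
    env[fl] <- 0
    ramp <- seq(1, 0, length.out = edge)
    pre <- t_to - edge + seq_len(edge)
    env[pre[pre >= 1]] <- ramp[seq_along(pre[pre >= 1])]
    post <- max(fl) + seq_len(edge)
    post <- post[post <= n]
    env[post] <- rev(ramp)[seq_along(post)]
    grav <- grav * rep(env, each = 3)
    # crouch before take-off
    crouch <- raised_cosine(round(0.4 * fs))
    cidx <- t_to - length(crouch) + seq_along(crouch) - edge
    keep <- cidx >= 1 & cidx <= n
    dyn[2, cidx[keep]] <- dyn[2, cidx[keep]] - 0.3 * crouch[keep]
    # landing spike (vertical, small forward leak)
    spike <- raised_cosine(round(0.08 * fs))
    sidx <- max(post) + seq_along(spike)
    sidx <- sidx[sidx <= n]
    dyn[2, sidx] <- dyn[2, sidx] + amp * spike[seq_along(sidx)]
    dyn[3, sidx] <- dyn[3, sidx] + 0.2 * amp * spike[seq_along(sidx)]
    params <- list(flight_s = flight, landing_amp = amp)
  }
  trace <- assemble_trace(grav, dyn, config)
  new_synthetic_trial(trace, config, "adl", family, subject_code,
                      family_activity_code(family), trial_index,
                      params = params)
}

#' Generate a synthetic fall trial
#'
#' A pre-fall activity segment (walk, jog, stand or quiet sit), then a
#' critical phase of drawn duration in the configured 300--500 ms range:
#' a free-fall dip in which the acceleration magnitude drops to the drawn
#' dip level, followed by an impact spike of drawn amplitude (times
#' \code{cohort_scale}) oriented by fall direction (forward +z, backward
#' -z, lateral +/-x); afterwards the gravity vector settles on the lying
#' posture for that direction. The impact peak sample index is annotated.
#'
#' @param direction \code{"forward"}, \code{"backward"} or
#'   \code{"lateral"}.
#' @param pre_activity \code{"walk"}, \code{"jog"}, \code{"stand"} or
#'   \code{"sit"}.
#' @param config A \code{\link{synth_config}}.
#' @param subject_code,trial_index Metadata for the embedded record.
#' @return A \code{synthetic_trial} with \code{label = "fall"},
#'   \code{$impact_index} and the drawn parameters. Uses the current RNG
#'   state.
#' @export
make_fall <- function(direction = c("forward", "backward", "lateral"),
                      pre_activity = c("walk", "jog", "stand", "sit"),
                      config = synth_config(), subject_code = "SA01",
                      trial_index = 1) {
  direction <- match.arg(direction)
  pre_activity <- match.arg(pre_activity)
  if (max(config$impact_amp) < max(config$jog_amp)) {
    warning("impact amplitudes below gait amplitudes: fall and ADL ",
            "classes may overlap by design")
  }
  fs <- config$fs
  n <- round(config$durations[["fall"]] * fs)

  t_pre <- stats::runif(1, 4, 8)           # pre-fall segment length, s
  tc <- runif1(config$critical_phase)      # critical phase, s
  dip <- runif1(config$dip_level)
  amp <- runif1(config$impact_amp)
  side <- sample(c(1, -1), 1)

  i0 <- round(t_pre * fs)                  # last pre-fall sample
  n_dip <- round(0.5 * tc * fs)
  # impact deceleration of the trunk occupies the second half of the
  # critical phase (150-250 ms at the waist, well inside the filter band)
  n_imp <- round(0.5 * tc * fs)
  if (n_imp %% 2 == 0) n_imp <- n_imp + 1
  n_settle <- round(1.2 * fs)   # body comes to rest gradually

  dir_vec <- switch(direction,
                    forward = c(0, 0, 1),
                    backward = c(0, 0, -1),
                    lateral = c(side, 0, 0))
  lie_vec <- switch(direction,
                    forward = c(0, 0, -1),
                    backward = c(0, 0, 1),
                    lateral = c(side, 0, 0))

  # gravity path: standing, half-cosine dip to `dip`, zero under the
  # impact peak, settle to the lying vector
  grav <- matrix(c(0, 1, 0), nrow = 3, ncol = n)
  env <- rep(1, n)
  dip_idx <- i0 + seq_len(n_dip)
  env[dip_idx] <- dip + (1 - dip) * (1 + cos(pi * seq_len(n_dip) / n_dip)) / 2
  spike <- raised_cosine(n_imp)
  imp_idx <- i0 + n_dip + seq_along(spike)
  env[imp_idx] <- dip * (1 - spike)
  i_settle0 <- max(imp_idx)
  settle_idx <- i_settle0 + seq_len(n_settle)
  settle_idx <- settle_idx[settle_idx <= n]
  env[settle_idx] <- dip +
    (1 - dip) * seq_along(settle_idx) / n_settle
  frac <- pmin(pmax((seq_len(n) - i_settle0) / n_settle, 0), 1)
  gdir <- outer(c(0, 1, 0), 1 - frac) + outer(lie_vec, frac)
  gnorm <- sqrt(colSums(gdir^2))
  gdir <- gdir / rep(pmax(gnorm, 1e-9), each = 3)
  grav <- gdir * rep(env, each = 3)

  # dynamics: pre-fall activity up to i0, then the impact spike. The
  # spike is stored unscaled here and scaled (with the rest of the
  # dynamics) by cohort_scale in assemble_trace.
  dyn <- matrix(0, 3, n)
  params <- list(pre_s = t_pre, critical_s = tc, dip_level = dip,
                 impact_amp = amp, pre_activity = pre_activity)
  if (pre_activity %in% c("walk", "jog")) {
    f0 <- runif1(if (pre_activity == "walk") config$walk_freq
                 else config$jog_freq)
    ga <- runif1(if (pre_activity == "walk") config$walk_amp
                 else config$jog_amp)
    gd <- gait_dynamic(i0, fs, f0, ga)
    taper <- pmin(seq_len(i0) / (0.5 * fs), 1)   # soft start
    dyn[, seq_len(i0)] <- gd * rep(taper, each = 3)
    params$gait_freq <- f0
    params$gait_amp <- ga
  }
  dyn[, imp_idx] <- dyn[, imp_idx] +
    outer(dir_vec, amp * spike)
  # post-impact ringdown: the body bounces and settles at a few Hz, with
  # amplitude proportional to (and scaling with) the impact severity
  ring_idx <- max(imp_idx) + seq_len(min(round(4 * fs), n - max(imp_idx)))
  tr <- (seq_along(ring_idx) - 1) / fs
  ring <- exp(-tr / 0.6) * sin(2 * pi * 4 * tr)
  # one-sided settling bias: ground reaction only pushes, so the
  # aftermath is not mean-neutral along the impact direction
  press <- 0.055 * amp * exp(-tr / 1.5)
  dyn[, ring_idx] <- dyn[, ring_idx] +
    outer(dir_vec, 0.5 * amp * ring) +
    outer(c(0, 1, 0), 0.25 * amp * ring) +
    outer(lie_vec, press)

  trace <- assemble_trace(grav, dyn, config)
  impact_index <- as.integer(imp_idx[which.max(spike)])
  new_synthetic_trial(trace, config, "fall", "fall", subject_code,
                      fall_activity_code(direction, pre_activity),
                      trial_index, direction = direction,
                      impact_index = impact_index, params = params)
}

# Deterministic per-trial child seed below 2^31.
child_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(i) * 104729
  as.integer(s %% 2147483647)
}

#' Generate a labelled synthetic dataset
#'
#' Draws \code{n_adl} ADL trials and \code{n_fall} fall trials with
#' activity families drawn uniformly within each cohort (the elderly
#' cohort never draws the jump family, which the recording protocol
#' excluded for elderly participants, and performs no falls in real
#' recordings; synthetic elderly falls are still generated here because
#' the cohort-transfer analysis needs them). Generation is fully
#' deterministic given (\code{config}, \code{seed}): each trial uses a
#' child seed derived from the root seed and the trial index.
#'
#' @param n_adl,n_fall Trial counts (>= 0).
#' @param config A \code{\link{synth_config}}.
#' @param cohort_mix Named proportions over \code{young}/\code{elderly}
#'   (default all young).
#' @param cohort_scales Dynamic-amplitude multiplier per cohort.
#' @param seed Root seed (default \code{config$seed}).
#' @param dir Optional directory: when given, trial files (via
#'   \code{\link{write_trial}}), \code{manifest.csv} and a ground-truth
#'   \code{truth.csv} are written there.
#' @return A list with \code{trials} (list of \code{synthetic_trial}),
#'   \code{manifest} (data frame as in \code{\link{scan_dataset}}) and
#'   \code{truth} (per-trial label, family, direction, impact index and
#'   drawn parameters).
#' @export
generate_dataset <- function(n_adl, n_fall, config = synth_config(),
                             cohort_mix = c(young = 1),
                             cohort_scales = c(young = 1,
                                               elderly = 0.7),
                             seed = config$seed, dir = NULL) {
  stopifnot(n_adl >= 0, n_fall >= 0, all(cohort_mix >= 0),
            sum(cohort_mix) > 0)
  cohort_mix <- cohort_mix / sum(cohort_mix)
  n <- n_adl + n_fall
  labels <- c(rep("adl", n_adl), rep("fall", n_fall))

  plan <- with_seed(seed, {
    ci <- pmin(1L + findInterval(stats::runif(n), cumsum(cohort_mix)),
               length(cohort_mix))
    cohorts <- names(cohort_mix)[ci]
    fam <- character(n)
    dir_ <- rep(NA_character_, n)
    pre <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      if (labels[i] == "adl") {
        fams <- if (cohorts[i] == "elderly") {
          c("walk", "jog", "sit", "lie")
        } else {
          c("walk", "jog", "sit", "jump", "lie")
        }
        fam[i] <- sample(fams, 1)
      } else {
        fam[i] <- "fall"
        dir_[i] <- sample(c("forward", "backward", "lateral"), 1)
        pre[i] <- sample(c("walk", "jog", "stand", "sit"), 1)
      }
    }
    list(cohorts = cohorts, fam = fam, dir = dir_, pre = pre)
  })

  n_young_subj <- 23L
  n_elder_subj <- 15L
  subj_counter <- c(young = 0L, elderly = 0L)
  trial_counter <- new.env(parent = emptyenv())
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    co <- plan$cohorts[i]
    subj_counter[co] <- subj_counter[co] + 1L
    subj <- if (co == "young") {
      sprintf("SA%02d", 1L + (subj_counter[co] - 1L) %% n_young_subj)
    } else {
      sprintf("SE%02d", 1L + (subj_counter[co] - 1L) %% n_elder_subj)
    }
    cfg <- config
    cfg$cohort_scale <- unname(cohort_scales[co])
    act <- if (labels[i] == "adl") family_activity_code(plan$fam[i])
           else fall_activity_code(plan$dir[i], plan$pre[i])
    key <- paste(subj, act)
    idx <- (if (is.null(trial_counter[[key]])) 0L
            else trial_counter[[key]]) + 1L
    trial_counter[[key]] <- idx
    trials[[i]] <- with_seed(child_seed(seed, i), {
      if (labels[i] == "adl") {
        make_adl(plan$fam[i], cfg, subject_code = subj, trial_index = idx)
      } else {
        make_fall(plan$dir[i], plan$pre[i], cfg, subject_code = subj,
                  trial_index = idx)
      }
    })
  }

  manifest <- data.frame(
    subject = vapply(trials, function(x) x$record$subject_code, ""),
    cohort = vapply(trials, function(x) x$cohort, ""),
    activity = vapply(trials, function(x) x$record$activity_code, ""),
    label = vapply(trials, function(x) x$label, ""),
    trial = vapply(trials, function(x) x$record$trial_index, 0L),
    path = NA_character_,
    duration_s = vapply(trials, function(x)
      trial_length(x$record) / x$record$fs, 0),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    trial_id = vapply(trials, function(x) trial_filename(x$record), ""),
    label = manifest$label, family = vapply(trials, `[[`, "", "family"),
    direction = vapply(trials, `[[`, "", "direction"),
    impact_index = vapply(trials, `[[`, 0L, "impact_index"),
    cohort = manifest$cohort, stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$path <- vapply(trials, function(x)
      write_trial(x$record, dir), "")
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(trials = trials, manifest = manifest, truth = truth)
}
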