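#' Score a set of trials on one or more features
#'
#' The per-trial pipeline: take the primary-accelerometer trace,
#' optionally low-pass filter it, extract each requested feature over its
#' default window, and reduce the feature series to the trial-level
#' maximum.
#'
#' @param trials List of \code{synthetic_trial} or
#'   \code{\link{trial_record}} objects (or \code{accel_trace}s, in which
#'   case \code{labels} must be supplied).
#' @param features Character vector of feature codes (default the five
#'   best-performing features C2, C3, C8, C9, C13).
#' @param filter Apply the Butterworth preprocessing (default TRUE).
#' @param fspec A \code{\link{filter_spec}}.
#' @param labels Optional label override vector.
#' @return A long-format data frame: one row per trial and feature, with
#'   \code{trial_id}, \code{feature}, \code{score}, \code{label},
#'   \code{cohort}, \code{activity}.
#' @export
score_trials <- function(trials,
                         features = c("C2", "C3", "C8", "C9", "C13"),
                         filter = TRUE, fspec = filter_spec(),
                         labels = NULL) {
  features <- match.arg(features, feature_codes(), several.ok = TRUE)
  filt <- if (filter) design_lowpass(fspec) else NULL
  rows <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    x <- trials[[i]]
    if (inherits(x, "synthetic_trial")) {
      trace <- x$trace
      rec <- x$record
    } else if (inherits(x, "trial_record")) {
      trace <- accel_trace(x)
      rec <- x
    } else {
      trace <- x
      rec <- NULL
    }
    if (!is.null(filt)) trace <- filter_trace(trace, filt)
    label <- if (!is.null(labels)) labels[i]
             else activity_label(rec$activity_code)
    id <- if (is.null(rec)) sprintf("trial%04d", i) else trial_filename(rec)
    cohort <- if (is.null(rec)) NA_character_
              else subject_cohort(rec$subject_code)
    activity <- if (is.null(rec)) NA_character_ else rec$activity_code
    rows[[i]] <- do.call(rbind, lapply(features, function(code) {
      trial_score(extract_feature(trace, code), label, id,
                  cohort = cohort, activity = activity)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effect of the preprocessing filter on detection accuracy
#'
#' Runs the full pipeline twice on the same synthetic dataset — once on
#' raw traces, once after the Butterworth low-pass — and cross-validates
#' the T1 threshold per feature in each arm.
#'
#' @param n_adl,n_fall Trial counts.
#' @param config A \code{\link{synth_config}}.
#' @param features Feature codes to compare.
#' @param k Cross-validation folds.
#' @param seed Root seed (dataset generation and fold assignment).
#' @param fspec A \code{\link{filter_spec}}.
#' @return A data frame with one row per feature and arm
#'   (\code{"raw"}/\code{"filtered"}) and columns \code{mean_ac},
#'   \code{sd_ac}, \code{mean_se}, \code{mean_sp}.
#' @export
run_filter_effect <- function(n_adl = 200, n_fall = 100,
                              config = synth_config(),
                              features = c("C2", "C3", "C8", "C9", "C13"),
                              k = 10, seed = 1, fspec = filter_spec()) {
  ds <- generate_dataset(n_adl, n_fall, config, seed = seed)
  out <- list()
  for (arm in c("raw", "filtered")) {
    sc <- score_trials(ds$trials, features, filter = arm == "filtered",
                       fspec = fspec)
    for (code in features) {
      si <- sc[sc$feature == code, ]
      cv <- cross_validate(si, policy = "T1", k = k, seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        feature = code, arm = arm,
        mean_ac = cv$mean[["ac"]], sd_ac = cv$sd[["ac"]],
        mean_se = cv$mean[["se"]], mean_sp = cv$mean[["sp"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Young-to-elderly cohort transfer
#'
#' Mirrors the cohort experiment: (a) cross-validation within the young
#' cohort; (b) the T1 threshold trained on all young trials applied to
#' the elderly cohort; (c) cross-validation within the elderly cohort.
#' The elderly cohort is the same generator with dynamic amplitudes
#' multiplied by \code{elderly_scale}.
#'
#' @param n_adl,n_fall Trial counts per cohort.
#' @param config A \code{\link{synth_config}} (young conditions).
#' @param elderly_scale Dynamic-amplitude multiplier for the elderly
#'   cohort (default 0.7).
#' @param features Feature codes.
#' @param k Folds; \code{seed} the root seed.
#' @param seed Integer seed.
#' @param filter Apply preprocessing (default TRUE).
#' @return A data frame with one row per feature and arm
#'   (\code{young_cv}, \code{young_to_elderly}, \code{elderly_cv}):
#'   SE/SP/AC (mean and sd over folds; single values for the transfer
#'   arm) and the mean fitted threshold.
#' @export
run_cohort_transfer <- function(n_adl = 200, n_fall = 100,
                                config = synth_config(),
                                elderly_scale = 0.7,
                                features = c("C2", "C3", "C8", "C9", "C13"),
                                k = 10, seed = 1, filter = TRUE) {
  young <- generate_dataset(n_adl, n_fall, config,
                            cohort_mix = c(young = 1), seed = seed)
  elderly <- generate_dataset(n_adl, n_fall, config,
                              cohort_mix = c(elderly = 1),
                              cohort_scales = c(young = 1,
                                                elderly = elderly_scale),
                              seed = seed + 1)
  sy <- score_trials(young$trials, features, filter = filter)
  se_ <- score_trials(elderly$trials, features, filter = filter)
  out <- list()
  for (code in features) {
    ys <- sy[sy$feature == code, ]
    es <- se_[se_$feature == code, ]
    cv_y <- cross_validate(ys, policy = "T1", k = k, seed = seed)
    tr <- transfer_evaluate(ys, es, policy = "T1")
    cv_e <- cross_validate(es, policy = "T1", k = k, seed = seed)
    arms <- list(young_cv = cv_y, young_to_elderly = tr, elderly_cv = cv_e)
    for (arm in names(arms)) {
      a <- arms[[arm]]
      out[[length(out) + 1L]] <- data.frame(
        feature = code, arm = arm,
        se = a$mean[["se"]], sp = a$mean[["sp"]], ac = a$mean[["ac"]],
        sd_ac = a$sd[["ac"]], threshold = mean(a$folds$threshold),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Maximum-sensitivity operation (T2) vs maximum accuracy (T1)
#'
#' Cross-validates both threshold policies on identical folds of the same
#' synthetic dataset, reporting the specificity price paid for placing
#' the threshold just below the minimum fall score.
#'
#' @param n_adl,n_fall Trial counts.
#' @param config A \code{\link{synth_config}}; pass overlapping fall and
#'   jump amplitude ranges to reproduce the low-specificity regime.
#' @param features Feature codes.
#' @param k Folds; \code{seed} the root seed.
#' @param seed Integer seed.
#' @param filter Apply preprocessing (default TRUE).
#' @return A data frame with one row per feature and policy: mean/sd
#'   SE, SP, AC across folds.
#' @export
run_zero_fn <- function(n_adl = 200, n_fall = 100,
                        config = synth_config(),
                        features = c("C2", "C3", "C8", "C9", "C13"),
                        k = 10, seed = 1, filter = TRUE) {
  ds <- generate_dataset(n_adl, n_fall, config, seed = seed)
  sc <- score_trials(ds$trials, features, filter = filter)
  out <- list()
  for (code in features) {
    si <- sc[sc$feature == code, ]
    folds <- stratified_kfold(si$label, k = k, seed = seed)
    for (policy in c("T1", "T2")) {
      cv <- cross_validate(si, policy = policy, folds = folds)
      out[[length(out) + 1L]] <- data.frame(
        feature = code, policy = policy,
        mean_se = cv$mean[["se"]], sd_se = cv$sd[["se"]],
        mean_sp = cv$mean[["sp"]], sd_sp = cv$sd[["sp"]],
        mean_ac = cv$mean[["ac"]], sd_ac = cv$sd[["ac"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-activity distribution of trial maxima
#'
#' Box-plot statistics of the trial-level feature maxima per activity
#' code, with a flag for activities whose maximum crosses a fitted
#' threshold — the activity-by-activity view of where a threshold
#' detector fails.
#'
#' @param scores Score data frame for one feature (from
#'   \code{\link{score_trials}}).
#' @param model Optional \code{\link{threshold_model}}; fitted with T1 on
#'   all scores when missing.
#' @return A data frame with one row per activity: \code{n},
#'   \code{min}/\code{q1}/\code{median}/\code{q3}/\code{max} of the trial
#'   maxima, the threshold and \code{crosses} (max > threshold).
#' @export
per_activity_summary <- function(scores, model = NULL) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0)
  if (length(unique(scores$feature)) > 1) {
    stop("per_activity_summary expects scores of a single feature")
  }
  if (is.null(model)) model <- fit_t1(scores)
  acts <- sort(unique(scores$activity))
  rows <- lapply(acts, function(a) {
    s <- scores$score[scores$activity == a]
    q <- stats::quantile(s, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(activity = a, label = activity_label(a), n = length(s),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4],
               max = q[5], threshold = model$threshold,
               crosses = q[5] > model$threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Grid search over window lengths for one feature
#'
#' Utility for the heuristic window-length exploration: cross-validated
#' T1 accuracy of one feature at each window length in a grid (default
#' 200 ms to 2 s).
#'
#' @param trials Trial list (as in \code{\link{score_trials}}).
#' @param feature One feature code.
#' @param windows_s Numeric vector of window lengths in seconds.
#' @param k,seed Cross-validation setup.
#' @param filter Apply preprocessing.
#' @return A data frame: \code{window_s}, \code{mean_ac}, \code{sd_ac}.
#' @export
window_grid_search <- function(trials, feature,
                               windows_s = c(0.2, 0.5, 1, 1.5, 2),
                               k = 10, seed = 1, filter = TRUE) {
  feature <- match.arg(feature, setdiff(feature_codes(),
                                        c("C1", "C2", "C4")))
  filt <- if (filter) design_lowpass() else NULL
  rows <- lapply(windows_s, function(ws) {
    sc <- do.call(rbind, lapply(seq_along(trials), function(i) {
      x <- trials[[i]]
      trace <- if (inherits(x, "synthetic_trial")) x$trace
               else accel_trace(x)
      rec <- if (inherits(x, "synthetic_trial")) x$record else x
      if (!is.null(filt)) trace <- filter_trace(trace, filt)
      w <- window_spec(round(ws * trace$fs), fs = trace$fs)
      trial_score(extract_feature(trace, feature, window = w),
                  activity_label(rec$activity_code),
                  trial_filename(rec))
    }))
    cv <- cross_validate(sc, policy = "T1", k = k, seed = seed)
    data.frame(window_s = ws, mean_ac = cv$mean[["ac"]],
               sd_ac = cv$sd[["ac"]])
  })
  do.call(rbind, rows)
}
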