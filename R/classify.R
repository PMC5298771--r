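#' Reduce a feature series to a trial-level score
#'
#' A trial is classified by whether its feature series ever crosses the
#' threshold, so the trial-level statistic is the maximum of the series
#' over its valid indices.
#'
#' @param series A \code{feature_series} (or bare numeric vector).
#' @param label \code{"fall"} or \code{"adl"}.
#' @param trial_id Identifier string.
#' @param cohort Optional cohort tag (\code{"young"}/\code{"elderly"}).
#' @param activity Optional activity code.
#' @return A one-row data frame with columns \code{trial_id},
#'   \code{feature}, \code{score}, \code{label}, \code{cohort},
#'   \code{activity}.
#' @export
trial_score <- function(series, label, trial_id, cohort = NA_character_,
                        activity = NA_character_) {
  label <- match.arg(label, c("fall", "adl"))
  values <- if (inherits(series, "feature_series")) series$values else series
  if (length(values) == 0L) stop("empty feature series")
  code <- if (inherits(series, "feature_series")) series$code
          else NA_character_
  data.frame(trial_id = trial_id, feature = code, score = max(values),
             label = label, cohort = cohort, activity = activity,
             stringsAsFactors = FALSE)
}

#' Threshold model
#'
#' A fitted decision threshold for one feature: a trial is called a fall
#' iff its score strictly exceeds the threshold (ties are ADL, since the
#' maximum-sensitivity threshold sits just below the minimum fall score).
#'
#' @param threshold Finite threshold value.
#' @param policy \code{"T1"} (maximum training accuracy) or \code{"T2"}
#'   (maximum sensitivity).
#' @param feature Feature code (optional).
#' @param filtered Logical: scores computed on filtered traces?
#' @param window The \code{\link{window_spec}} used (optional).
#' @return An object of class \code{threshold_model}.
#' @export
threshold_model <- function(threshold, policy = c("T1", "T2"),
                            feature = NA_character_, filtered = NA,
                            window = NULL) {
  policy <- match.arg(policy)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  structure(list(threshold = threshold, policy = policy,
                 feature = feature, filtered = filtered, window = window),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> %s threshold = %.6g (feature %s)\n",
              x$policy, x$threshold, x$feature))
  invisible(x)
}

#' Classify trial scores against a threshold
#'
#' @param scores Numeric vector of trial scores, or a score data frame
#'   from \code{\link{trial_score}}.
#' @param model A \code{\link{threshold_model}}.
#' @return Character vector \code{"fall"}/\code{"adl"}: fall iff
#'   \code{score > threshold} (strict; ties are ADL).
#' @export
classify <- function(scores, model) {
  stopifnot(inherits(model, "threshold_model"))
  if (is.data.frame(scores)) {
    if (!is.na(model$feature) && any(!is.na(scores$feature)) &&
        !all(scores$feature[!is.na(scores$feature)] == model$feature)) {
      stop("feature mismatch: model is for ", model$feature)
    }
    scores <- scores$score
  }
  ifelse(scores > model$threshold, "fall", "adl")
}

#' Confusion counts for predicted vs true labels
#'
#' @param predicted,truth Character vectors of \code{"fall"}/\code{"adl"}.
#' @return Named integer vector \code{tp}, \code{tn}, \code{fp},
#'   \code{fn} (falls are the positive class).
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  c(tp = sum(predicted == "fall" & truth == "fall"),
    tn = sum(predicted == "adl" & truth == "adl"),
    fp = sum(predicted == "fall" & truth == "adl"),
    fn = sum(predicted == "adl" & truth == "fall"))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' \code{SE = TP/(TP+FN)}, \code{SP = TN/(TN+FP)},
#' \code{AC = (SE+SP)/2}. The balanced accuracy makes the metric
#' insensitive to unbalanced fall/ADL counts. Empty classes are an error,
#' never a silent zero.
#'
#' @param counts Named vector with \code{tp}, \code{tn}, \code{fp},
#'   \code{fn} (e.g. from \code{\link{confusion_counts}}).
#' @return Named numeric vector \code{se}, \code{sp}, \code{ac}.
#' @examples
#' classifier_metrics(c(tp = 9, fn = 1, tn = 8, fp = 2))
#' @export
classifier_metrics <- function(counts) {
  counts <- counts[c("tp", "tn", "fp", "fn")]
  stopifnot(!anyNA(counts), all(counts >= 0))
  if (counts["tp"] + counts["fn"] == 0) {
    stop("sensitivity undefined: no fall trials scored")
  }
  if (counts["tn"] + counts["fp"] == 0) {
    stop("specificity undefined: no ADL trials scored")
  }
  se <- unname(counts["tp"] / (counts["tp"] + counts["fn"]))
  sp <- unname(counts["tn"] / (counts["tn"] + counts["fp"]))
  c(se = se, sp = sp, ac = (se + sp) / 2)
}

# Candidate thresholds: midpoints between consecutive distinct sorted
# scores plus finite sentinels outside the range. The decision rule is
# piecewise constant in the threshold, so this set is exhaustive.
t1_candidates <- function(scores) {
  s <- sort(unique(scores))
  delta <- 1e-6 * max(diff(range(s)), 1)
  m <- length(s)
  if (m == 1) return(c(s - delta, s + delta))
  c(s[1] - delta, (s[-1] + s[-m]) / 2, s[m] + delta)
}

#' Fit the maximum-accuracy threshold (T1)
#'
#' Scans every candidate threshold (midpoints between consecutive
#' distinct sorted scores plus sentinels beyond the range) and returns the
#' one maximizing training accuracy \code{AC = (SE+SP)/2}; accuracy ties
#' are broken toward the higher sensitivity, then the lower threshold.
#'
#' @param scores Numeric vector of trial scores, or a score data frame
#'   (with \code{score} and \code{label} columns).
#' @param labels Character vector of \code{"fall"}/\code{"adl"} (ignored
#'   when \code{scores} is a data frame).
#' @param feature,filtered,window Metadata stored in the model.
#' @return A \code{\link{threshold_model}} with attributes
#'   \code{train_se}, \code{train_sp}, \code{train_ac}.
#' @export
fit_t1 <- function(scores, labels = NULL, feature = NA_character_,
                   filtered = NA, window = NULL) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    if (is.na(feature) && any(!is.na(scores$feature))) {
      feature <- scores$feature[!is.na(scores$feature)][1]
    }
    scores <- scores$score
  }
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  is_fall <- labels == "fall"
  if (!any(is_fall) || all(is_fall)) {
    stop("T1 fit needs both fall and ADL trials in training")
  }
  cand <- t1_candidates(scores)
  nf <- sum(is_fall)
  na <- sum(!is_fall)
  se <- vapply(cand, function(t) sum(scores[is_fall] > t) / nf, 0)
  sp <- vapply(cand, function(t) sum(scores[!is_fall] <= t) / na, 0)
  ac <- (se + sp) / 2
  best <- which(ac == max(ac))
  best <- best[se[best] == max(se[best])]
  best <- best[which.min(cand[best])]
  model <- threshold_model(cand[best], "T1", feature = feature,
                           filtered = filtered, window = window)
  attr(model, "train_se") <- se[best]
  attr(model, "train_sp") <- sp[best]
  attr(model, "train_ac") <- ac[best]
  model
}

#' Fit the maximum-sensitivity threshold (T2)
#'
#' Places the threshold just below the minimum fall score
#' (\code{min(fall) - 1e-6 * max(score spread, 1)}), so training
#' sensitivity is exactly 1 by construction; specificity follows from
#' whichever ADL scores exceed that level.
#'
#' @inheritParams fit_t1
#' @return A \code{\link{threshold_model}} with the same training-metric
#'   attributes as \code{\link{fit_t1}}.
#' @export
fit_t2 <- function(scores, labels = NULL, feature = NA_character_,
                   filtered = NA, window = NULL) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    if (is.na(feature) && any(!is.na(scores$feature))) {
      feature <- scores$feature[!is.na(scores$feature)][1]
    }
    scores <- scores$score
  }
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  is_fall <- labels == "fall"
  if (!any(is_fall)) stop("T2 fit needs at least one fall in training")
  eps <- 1e-6 * max(diff(range(scores)), 1)
  thr <- min(scores[is_fall]) - eps
  model <- threshold_model(thr, "T2", feature = feature,
                           filtered = filtered, window = window)
  pred <- classify(scores, model)
  attr(model, "train_se") <- sum(pred == "fall" & is_fall) / sum(is_fall)
  if (any(!is_fall)) {
    sp <- sum(pred == "adl" & !is_fall) / sum(!is_fall)
    attr(model, "train_sp") <- sp
    attr(model, "train_ac") <- (attr(model, "train_se") + sp) / 2
  }
  model
}
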