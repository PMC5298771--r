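#' Activity protocol for the waist-sensor fall/ADL recording campaign
#'
#' The recording protocol distinguishes 19 activities of daily living
#' (codes \code{D01}--\code{D19}) and 15 fall types (codes
#' \code{F01}--\code{F15}). Each activity has a prescribed number of trials
#' per subject and a prescribed trial duration. Falls last 15 s; long
#' locomotion activities (slow/quick walking and jogging) last 100 s and
#' are recorded once per subject; the remaining ADLs last 12 or 25 s with
#' five trials each.
#'
#' @return A data frame with one row per activity code and columns
#'   \code{code}, \code{label} (\code{"adl"} or \code{"fall"}),
#'   \code{description}, \code{n_trials} (trials per subject) and
#'   \code{duration_s}.
#' @examples
#' prot <- activity_protocol()
#' table(prot$label)
#' @export
activity_protocol <- function() {
  adl <- data.frame(
    code = sprintf("D%02d", 1:19),
    label = "adl",
    description = c(
      "Walking slowly",
      "Walking quickly",
      "Jogging slowly",
      "Jogging quickly",
      "Walking upstairs and downstairs slowly",
      "Walking upstairs and downstairs quickly",
      "Slowly sit in a half height chair, wait a moment, and up slowly",
      "Quickly sit in a half height chair, wait a moment, and up quickly",
      "Slowly sit in a low height chair, wait a moment, and up slowly",
      "Quickly sit in a low height chair, wait a moment, and up quickly",
      "Sitting a moment, trying to get up, and collapse into a chair",
      "Sitting a moment, lying slowly, wait a moment, and sit again",
      "Sitting a moment, lying quickly, wait a moment, and sit again",
      "Being on one's back change to lateral position, wait a moment, and change to one's back",
      "Standing, slowly bending at knees, and getting up",
      "Standing, slowly bending without bending knees, and getting up",
      "Standing, get into a car, remain seated and get out of the car",
      "Stumble while walking",
      "Gently jump without falling (trying to reach a high object)"
    ),
    n_trials = c(1, 1, 1, 1, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5),
    duration_s = c(100, 100, 100, 100, 25, 25, 12, 12, 12, 12, 12, 12, 12,
                   12, 12, 12, 25, 12, 12),
    stringsAsFactors = FALSE
  )
  fall <- data.frame(
    code = sprintf("F%02d", 1:15),
    label = "fall",
    description = c(
      "Fall forward while walking caused by a slip",
      "Fall backward while walking caused by a slip",
      "Lateral fall while walking caused by a slip",
      "Fall forward while walking caused by a trip",
      "Fall forward while jogging caused by a trip",
      "Vertical fall while walking caused by fainting",
      "Fall while walking, with use of hands in a table to dampen fall, caused by fainting",
      "Fall forward when trying to get up",
      "Lateral fall when trying to get up",
      "Fall forward when trying to sit down",
      "Fall backward when trying to sit down",
      "Lateral fall when trying to sit down",
      "Fall forward while sitting, caused by fainting or falling asleep",
      "Fall backward while sitting, caused by fainting or falling asleep",
      "Lateral fall while sitting, caused by fainting or falling asleep"
    ),
    n_trials = 5,
    duration_s = 15,
    stringsAsFactors = FALSE
  )
  rbind(adl, fall)
}

#' Valid activity codes
#'
#' @param label Optional filter: \code{"adl"}, \code{"fall"} or
#'   \code{NULL} (all 34 codes).
#' @return Character vector of activity codes.
#' @export
activity_codes <- function(label = NULL) {
  prot <- activity_protocol()
  if (!is.null(label)) {
    label <- match.arg(label, c("adl", "fall"))
    prot <- prot[prot$label == label, ]
  }
  prot$code
}

#' Activities the elderly cohort did not perform
#'
#' Falls were performed only by one elderly subject; on medical advice the
#' elderly group also skipped the quick-stairs, quick-lying, stumble and
#' jump activities.
#'
#' @return Character vector of ADL codes excluded for the elderly cohort.
#' @export
elderly_excluded_activities <- function() {
  c("D06", "D13", "D18", "D19")
}

#' Infer fall/ADL label from an activity code
#'
#' @param code Character vector of activity codes.
#' @return Character vector, \code{"fall"} or \code{"adl"}.
#' @export
activity_label <- function(code) {
  bad <- setdiff(code, activity_codes())
  if (length(bad) > 0) {
    stop("unknown activity code(s): ", paste(bad, collapse = ", "))
  }
  ifelse(startsWith(code, "F"), "fall", "adl")
}

#' Infer cohort from a subject code
#'
#' Subject codes use an `SA` prefix for young adults and `SE` for elderly
#' participants, followed by a two-digit index (e.g. \code{"SE06"}).
#'
#' @param subject_code Character vector of subject codes.
#' @return Character vector, \code{"young"} or \code{"elderly"}.
#' @export
subject_cohort <- function(subject_code) {
  ok <- grepl("^S[AE][0-9]{2}$", subject_code)
  if (!all(ok)) {
    stop("malformed subject code(s): ",
         paste(subject_code[!ok], collapse = ", "))
  }
  ifelse(substr(subject_code, 2, 2) == "A", "young", "elderly")
}
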