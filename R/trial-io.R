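#' Trial file dialect
#'
#' The released trial files contain one line per 200 Hz sample with nine
#' comma-separated signed integers: accelerometer-1 x,y,z, gyroscope
#' x,y,z, accelerometer-2 x,y,z. A trailing semicolon on a line is
#' tolerated. Trial identity is encoded in the file name as
#' \code{ACTIVITY_SUBJECT_Rnn.txt} (e.g. \code{F05_SA03_R02.txt}).
#'
#' @param sep Field separator (default \code{","}).
#' @param channel_names Names of the nine channels, in file column order.
#' @param name_pattern Regular expression with three capture groups
#'   (activity, subject, trial index) applied to the file base name.
#' @return An object of class \code{trial_dialect}.
#' @export
trial_dialect <- function(sep = ",",
                          channel_names = c("acc1_x", "acc1_y", "acc1_z",
                                            "gyro_x", "gyro_y", "gyro_z",
                                            "acc2_x", "acc2_y", "acc2_z"),
                          name_pattern = "^([DF][0-9]{2})_(S[AE][0-9]{2})_R([0-9]{2})(\\.txt)?$") {
  stopifnot(length(channel_names) == 9L)
  structure(list(sep = sep, channel_names = channel_names,
                 name_pattern = name_pattern),
            class = "trial_dialect")
}

#' One waist-sensor recording
#'
#' A trial is one recording of one activity by one subject: nine raw
#' integer channels of equal length (two accelerometers and a gyroscope,
#' three axes each) at a fixed sampling rate, with the activity code,
#' subject code and trial index as metadata. The sensor axis convention is
#' +z forward, +y along gravity, +x to the subject's right.
#'
#' @param subject_code Subject code, \code{"SAnn"} (young) or
#'   \code{"SEnn"} (elderly).
#' @param activity_code One of the 34 protocol codes
#'   (\code{\link{activity_codes}}).
#' @param trial_index Positive integer.
#' @param channels Named list of nine equal-length integer-valued vectors
#'   (names as in \code{\link{trial_dialect}}).
#' @param fs Sampling rate in Hz (default 200).
#' @param sensors Named list of \code{\link{sensor_spec}} objects
#'   (\code{acc1}, \code{gyro}, \code{acc2}).
#' @return An object of class \code{trial_record}.
#' @export
trial_record <- function(subject_code, activity_code, trial_index,
                         channels, fs = 200, sensors = default_sensors()) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0,
            is.numeric(trial_index), length(trial_index) == 1L,
            trial_index == round(trial_index), trial_index >= 1)
  subject_cohort(subject_code)            # validates the code format
  activity_label(activity_code)           # validates against the protocol
  if (!is.list(channels) || length(channels) != 9L) {
    stop("channels must be a list of 9 integer vectors")
  }
  lens <- lengths(channels)
  if (length(unique(lens)) != 1L || lens[1] < 1L) {
    stop("all 9 channels must have identical length >= 1")
  }
  for (ch in channels) {
    if (!is.numeric(ch) || any(ch != round(ch))) {
      stop("channels must contain integer-valued samples")
    }
  }
  dialect <- trial_dialect()
  if (is.null(names(channels))) names(channels) <- dialect$channel_names
  channels <- lapply(channels, function(ch) as.integer(round(ch)))
  structure(
    list(subject_code = subject_code, activity_code = activity_code,
         trial_index = as.integer(trial_index), fs = fs,
         channels = channels, sensors = sensors),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s %s trial %d: %d samples @ %g Hz (%s, %s)\n",
              x$subject_code, x$activity_code, x$trial_index,
              length(x$channels[[1]]), x$fs,
              activity_label(x$activity_code),
              subject_cohort(x$subject_code)))
  invisible(x)
}

#' Number of samples in a trial
#' @param record A \code{\link{trial_record}}.
#' @return Integer sample count.
#' @export
trial_length <- function(record) {
  stopifnot(inherits(record, "trial_record"))
  length(record$channels[[1]])
}

parse_trial_name <- function(name, dialect = trial_dialect()) {
  base <- sub("\\.txt$", "", basename(name))
  m <- regmatches(base, regexec(dialect$name_pattern, base))[[1]]
  if (length(m) < 4L) return(NULL)
  list(activity_code = m[2], subject_code = m[3],
       trial_index = as.integer(m[4]))
}

#' Read a trial file
#'
#' Parses one plain-text trial file (see \code{\link{trial_dialect}}).
#' Trial identity is taken from the file name; when the name does not
#' match the pattern, \code{subject_code}, \code{activity_code} and
#' \code{trial_index} must be supplied explicitly.
#'
#' @param path Path to the trial file.
#' @param dialect A \code{\link{trial_dialect}}.
#' @param subject_code,activity_code,trial_index Metadata overrides used
#'   when the file name does not encode them.
#' @param fs Sampling rate in Hz (default 200).
#' @param sensors Sensor suite (default \code{\link{default_sensors}}).
#' @return A \code{\link{trial_record}}.
#' @export
read_trial <- function(path, dialect = trial_dialect(),
                       subject_code = NULL, activity_code = NULL,
                       trial_index = NULL, fs = 200,
                       sensors = default_sensors()) {
  if (!file.exists(path)) stop("no such trial file: ", path)
  meta <- parse_trial_name(path, dialect)
  if (is.null(subject_code)) subject_code <- meta$subject_code
  if (is.null(activity_code)) activity_code <- meta$activity_code
  if (is.null(trial_index)) trial_index <- meta$trial_index
  if (is.null(subject_code) || is.null(activity_code) ||
      is.null(trial_index)) {
    stop("file name '", basename(path), "' does not encode trial ",
         "identity; pass subject_code, activity_code and trial_index")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty trial file: ", path)
  lines <- sub(";\\s*$", "", lines)
  parts <- strsplit(lines, dialect$sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    stop("parse error in ", path, " line ", bad, ": expected 9 fields, ",
         "found ", nf[bad])
  }
  vals <- suppressWarnings(as.numeric(trimws(unlist(parts))))
  if (anyNA(vals) || any(vals != round(vals))) {
    bad <- which(apply(matrix(is.na(vals) | vals != round(vals),
                              nrow = 9L), 2, any))[1]
    stop("parse error in ", path, " line ", bad,
         ": non-integer field")
  }
  mat <- matrix(as.integer(vals), nrow = 9L)
  channels <- lapply(seq_len(9L), function(i) mat[i, ])
  names(channels) <- dialect$channel_names
  trial_record(subject_code, activity_code, trial_index, channels,
               fs = fs, sensors = sensors)
}

#' Write a trial file
#'
#' Emits the same dialect \code{\link{read_trial}} accepts, so that
#' write-then-read round-trips a \code{\link{trial_record}} exactly.
#'
#' @param record A \code{\link{trial_record}}.
#' @param path Output path; when \code{path} is a directory the canonical
#'   \code{ACTIVITY_SUBJECT_Rnn.txt} name is used inside it.
#' @param dialect A \code{\link{trial_dialect}}.
#' @return The path written, invisibly.
#' @export
write_trial <- function(record, path, dialect = trial_dialect()) {
  stopifnot(inherits(record, "trial_record"))
  if (dir.exists(path)) {
    path <- file.path(path, trial_filename(record))
  }
  mat <- do.call(rbind, record$channels)
  lines <- apply(mat, 2, paste, collapse = dialect$sep)
  writeLines(lines, path)
  invisible(path)
}

#' Canonical file name for a trial
#' @param record A \code{\link{trial_record}}.
#' @return \code{ACTIVITY_SUBJECT_Rnn.txt}.
#' @export
trial_filename <- function(record) {
  sprintf("%s_%s_R%02d.txt", record$activity_code, record$subject_code,
          record$trial_index)
}

#' Three-axis acceleration trace in g
#'
#' @param fs Sampling rate in Hz.
#' @param ax,ay,az Equal-length finite numeric vectors in g. Axis
#'   convention: +z forward, +y along gravity, +x to the subject's right.
#' @return An object of class \code{accel_trace}.
#' @export
new_accel_trace <- function(fs, ax, ay, az) {
  stopifnot(fs > 0, length(ax) == length(ay), length(ay) == length(az))
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az))) {
    stop("accel_trace values must be finite")
  }
  structure(list(fs = fs, ax = as.numeric(ax), ay = as.numeric(ay),
                 az = as.numeric(az)),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$ax), x$fs, length(x$ax) / x$fs))
  invisible(x)
}

#' Extract an acceleration trace from a trial
#'
#' Selects the three channels of one accelerometer and converts the raw
#' counts to g. The primary (+/-16 g) accelerometer is the default and the
#' only sensor used for feature extraction; the gyroscope cannot be
#' converted to an acceleration trace.
#'
#' @param record A \code{\link{trial_record}}.
#' @param sensor \code{"acc1"} (default, the +/-16 g device) or
#'   \code{"acc2"}.
#' @return An \code{\link{new_accel_trace}} object at \code{record$fs}.
#' @export
accel_trace <- function(record, sensor = "acc1") {
  stopifnot(inherits(record, "trial_record"))
  if (identical(sensor, "gyro")) {
    stop("unsupported sensor: the gyroscope is not an accelerometer")
  }
  sensor <- match.arg(sensor, c("acc1", "acc2"))
  spec <- record$sensors[[sensor]]
  chans <- paste0(sensor, c("_x", "_y", "_z"))
  new_accel_trace(record$fs,
                  raw_to_units(record$channels[[chans[1]]], spec),
                  raw_to_units(record$channels[[chans[2]]], spec),
                  raw_to_units(record$channels[[chans[3]]], spec))
}

#' Scan a directory of trial files into a manifest
#'
#' Builds one manifest row per dialect-conformant file found under
#' \code{root}, with cohort and fall/ADL label inferred from the file
#' name.
#'
#' @param root Directory containing trial files.
#' @param dialect A \code{\link{trial_dialect}}.
#' @param fs Sampling rate used to convert line counts to durations.
#' @return A data frame with columns \code{subject}, \code{cohort},
#'   \code{activity}, \code{label}, \code{trial}, \code{path},
#'   \code{duration_s}.
#' @export
scan_dataset <- function(root, dialect = trial_dialect(), fs = 200) {
  stopifnot(dir.exists(root))
  files <- list.files(root, recursive = TRUE, full.names = TRUE)
  keep <- !vapply(files, function(f) is.null(parse_trial_name(f, dialect)),
                  logical(1))
  files <- files[keep]
  if (length(files) == 0L) {
    warning("no trial files found under ", root)
    return(data.frame(subject = character(), cohort = character(),
                      activity = character(), label = character(),
                      trial = integer(), path = character(),
                      duration_s = numeric(), stringsAsFactors = FALSE))
  }
  meta <- lapply(files, parse_trial_name, dialect = dialect)
  man <- data.frame(
    subject = vapply(meta, `[[`, "", "subject_code"),
    activity = vapply(meta, `[[`, "", "activity_code"),
    trial = vapply(meta, `[[`, 0L, "trial_index"),
    path = files, stringsAsFactors = FALSE
  )
  man$cohort <- subject_cohort(man$subject)
  man$label <- activity_label(man$activity)
  key <- paste(man$subject, man$activity, man$trial)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (subject, activity, trial) triple: ",
         paste(man$path[key == d], collapse = " and "))
  }
  nlines <- vapply(files, function(f) length(readLines(f)), 0L)
  man$duration_s <- nlines / fs
  man <- man[order(man$subject, man$activity, man$trial),
             c("subject", "cohort", "activity", "label", "trial", "path",
               "duration_s")]
  rownames(man) <- NULL
  man
}
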