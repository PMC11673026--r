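#' Construct a continuous EEG recording
#'
#' The basic container for one person's continuous multichannel EEG plus the
#' condition schedule. Samples are stored channels x time in microvolts; the
#' schedule uses 0-based sample indices and half-open intervals
#' `[start_sample, start_sample + n_samples)`.
#'
#' @param samples Numeric matrix, channels x time (microvolts).
#' @param channel_labels Character vector, one label per row of `samples`.
#' @param sampling_rate_hz Sampling rate in Hz (positive).
#' @param subject_id,dyad_id Identifiers.
#' @param schedule Data frame with columns `condition`, `start_sample`
#'   (0-based), `n_samples`; segments must be non-overlapping and lie within
#'   the recording.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, channel_labels, sampling_rate_hz,
                          subject_id, dyad_id, schedule) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (length(channel_labels) != nrow(samples)) {
    stop("channel_labels length (", length(channel_labels),
         ") must equal the number of channel rows (", nrow(samples), ")")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be positive")
  }
  schedule <- validate_schedule(schedule, ncol(samples))
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples,
         channel_labels = as.character(channel_labels),
         sampling_rate_hz = sampling_rate_hz,
         subject_id = as.character(subject_id),
         dyad_id = as.character(dyad_id),
         schedule = schedule),
    class = "raw_recording")
}

validate_schedule <- function(schedule, n_total) {
  req <- c("condition", "start_sample", "n_samples")
  if (!is.data.frame(schedule) || !all(req %in% names(schedule))) {
    stop("schedule must be a data frame with columns ",
         paste(req, collapse = ", "))
  }
  if (nrow(schedule) == 0) stop("schedule is empty")
  schedule <- schedule[order(schedule$start_sample), req, drop = FALSE]
  schedule$condition <- as.character(schedule$condition)
  schedule$start_sample <- as.integer(schedule$start_sample)
  schedule$n_samples <- as.integer(schedule$n_samples)
  if (any(schedule$start_sample < 0) || any(schedule$n_samples <= 0)) {
    stop("schedule segments must have start_sample >= 0 and n_samples > 0")
  }
  ends <- schedule$start_sample + schedule$n_samples
  if (any(ends > n_total)) {
    stop("schedule references samples beyond the end of the recording")
  }
  if (nrow(schedule) > 1 &&
      any(schedule$start_sample[-1] < ends[-nrow(schedule)])) {
    stop("schedule segments overlap")
  }
  rownames(schedule) <- NULL
  schedule
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s (dyad %s): %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$dyad_id, nrow(x$samples), ncol(x$samples),
              x$sampling_rate_hz))
  cat(sprintf("  schedule: %d segments (%s)\n", nrow(x$schedule),
              paste(x$schedule$condition, collapse = ", ")))
  invisible(x)
}

#' Convert a schedule given in seconds to sample indices
#'
#' Seconds are converted to 0-based sample indices by half-up rounding
#' (`floor(x * fs + 0.5)`).
#'
#' @param schedule_s Data frame with columns `condition`, `start_s`,
#'   `duration_s`.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Data frame with columns `condition`, `start_sample`, `n_samples`.
#' @export
schedule_to_samples <- function(schedule_s, sampling_rate_hz) {
  req <- c("condition", "start_s", "duration_s")
  if (!is.data.frame(schedule_s) || !all(req %in% names(schedule_s))) {
    stop("schedule must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(schedule_s) == 0) stop("schedule is empty")
  half_up <- function(x) floor(x + 0.5)
  start <- half_up(schedule_s$start_s * sampling_rate_hz)
  end <- half_up((schedule_s$start_s + schedule_s$duration_s) * sampling_rate_hz)
  data.frame(condition = as.character(schedule_s$condition),
             start_sample = as.integer(start),
             n_samples = as.integer(end - start),
             stringsAsFactors = FALSE)
}

# internal: sample indices (1-based) of one schedule segment
segment_index <- function(seg) {
  seq.int(seg$start_sample + 1L, seg$start_sample + seg$n_samples)
}
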