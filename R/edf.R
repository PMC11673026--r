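# Minimal classic EDF (16-bit) reader/writer for continuous multichannel EEG.
# One data record per second; the true sample count is stored in the reserved
# header field ("NSAMP=") so recordings whose length is not a whole number of
# seconds survive a round trip exactly (the trailing record is zero-padded on
# disk and trimmed on read).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  digits <- 15
  while (nchar(s) > width && digits > 0) {
    digits <- digits - 1
    s <- format(signif(x, digits), scientific = FALSE, trim = TRUE)
  }
  if (nchar(s) > width) stop("numeric field does not fit in ", width, " bytes")
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Classic EDF, 16-bit samples, one data record per second. Physical
#' minima/maxima are taken from the data per channel, so quantization error
#' is at most `(max - min) / 65535 / 2` per channel.
#'
#' @param rec A [raw_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate_hz
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  fs <- as.integer(fs)
  n_ch <- nrow(rec$samples)
  n_total <- ncol(rec$samples)
  n_rec <- as.integer(ceiling(n_total / fs))

  phys_min <- apply(rec$samples, 1, min)
  phys_max <- apply(rec$samples, 1, max)
  too_flat <- (phys_max - phys_min) < 1e-6
  phys_min[too_flat] <- phys_min[too_flat] - 1
  phys_max[too_flat] <- phys_max[too_flat] + 1
  dig_min <- -32768L; dig_max <- 32767L
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)

  header_bytes <- 256L + 256L * n_ch
  wr(edf_pad("0", 8))
  wr(edf_pad(sprintf("subject=%s dyad=%s", rec$subject_id, rec$dyad_id), 80))
  wr(edf_pad(sprintf("dyadsync fs=%d", fs), 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_num(header_bytes, 8))
  wr(edf_pad(sprintf("NSAMP=%d", n_total), 44))
  wr(edf_num(n_rec, 8))
  wr(edf_num(1, 8))
  wr(edf_num(n_ch, 4))

  for (lab in rec$channel_labels) wr(edf_pad(lab, 16))
  for (i in seq_len(n_ch)) wr(edf_pad("AgAgCl electrode", 80))
  for (i in seq_len(n_ch)) wr(edf_pad("uV", 8))
  for (i in seq_len(n_ch)) wr(edf_num(phys_min[i], 8))
  for (i in seq_len(n_ch)) wr(edf_num(phys_max[i], 8))
  for (i in seq_len(n_ch)) wr(edf_num(dig_min, 8))
  for (i in seq_len(n_ch)) wr(edf_num(dig_max, 8))
  for (i in seq_len(n_ch)) wr(edf_pad("", 80))
  for (i in seq_len(n_ch)) wr(edf_num(fs, 8))
  for (i in seq_len(n_ch)) wr(edf_pad("", 32))

  pad_n <- n_rec * fs - n_total
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):min(r * fs, n_total)
    for (i in seq_len(n_ch)) {
      x <- rec$samples[i, idx]
      d <- as.integer(round((x - phys_min[i]) / gain[i]) + dig_min)
      d <- pmin(pmax(d, dig_min), dig_max)
      if (r == n_rec && pad_n > 0) d <- c(d, integer(pad_n))
      writeBin(d, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any classic EDF)
#'
#' @param path EDF file path.
#' @return A list with `samples` (channels x time matrix, physical units),
#'   `channel_labels`, `sampling_rate_hz`, `subject_id`, `dyad_id`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rstrip <- function(s) sub("\\s+$", "", s)

  rd(8)                                   # version
  patient <- rstrip(rd(80))
  rd(80)                                  # recording id
  rd(8); rd(8)                            # date, time
  rd(8)                                   # header bytes
  reserved <- rstrip(rd(44))
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))

  labels <- rstrip(vapply(seq_len(n_ch), function(i) rd(16), ""))
  for (i in seq_len(n_ch)) rd(80)         # transducer
  for (i in seq_len(n_ch)) rd(8)          # unit
  phys_min <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  for (i in seq_len(n_ch)) rd(80)         # prefiltering
  spr <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), ""))
  for (i in seq_len(n_ch)) rd(32)         # reserved per signal

  if (length(unique(spr)) != 1) {
    stop("read_edf: signals with differing sampling rates are not supported")
  }
  fs <- spr[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  samples <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_ch)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      samples[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (d - dig_min[i]) * gain[i] + phys_min[i]
    }
  }

  n_true <- if (grepl("^NSAMP=", reserved)) {
    as.integer(sub("^NSAMP=", "", reserved))
  } else ncol(samples)
  samples <- samples[, seq_len(n_true), drop = FALSE]
  rownames(samples) <- labels

  subj <- if (grepl("subject=", patient)) {
    sub("^.*subject=(\\S+).*$", "\\1", patient)
  } else patient
  dyad <- if (grepl("dyad=", patient)) {
    sub("^.*dyad=(\\S+).*$", "\\1", patient)
  } else NA_character_

  list(samples = samples, channel_labels = labels, sampling_rate_hz = fs,
       subject_id = subj, dyad_id = dyad)
}

#' Read a recording from EDF plus a condition-schedule CSV
#'
#' The schedule CSV has columns `condition`, `start_s`, `duration_s` (seconds);
#' seconds are converted to samples by half-up rounding.
#'
#' @param edf_path Path to the EDF file.
#' @param schedule_path Path to the schedule CSV.
#' @param clusters Optional [cluster_spec()]; if given, reading fails when any
#'   cluster channel is absent from the file's montage.
#' @param expected_rate_hz Optional sampling rate; reading fails on mismatch.
#' @return A [raw_recording()].
#' @export
read_recording <- function(edf_path, schedule_path, clusters = NULL,
                           expected_rate_hz = NULL) {
  edf <- read_edf(edf_path)
  if (!is.null(expected_rate_hz) &&
      abs(edf$sampling_rate_hz - expected_rate_hz) > 1e-9) {
    stop("sampling rate in file (", edf$sampling_rate_hz,
         " Hz) does not match the configured rate (", expected_rate_hz, " Hz)")
  }
  if (!is.null(clusters)) check_clusters_present(clusters, edf$channel_labels)
  sched_s <- utils::read.csv(schedule_path, stringsAsFactors = FALSE)
  if ("label" %in% names(sched_s) && !"condition" %in% names(sched_s)) {
    names(sched_s)[names(sched_s) == "label"] <- "condition"
  }
  schedule <- schedule_to_samples(sched_s, edf$sampling_rate_hz)
  raw_recording(edf$samples, edf$channel_labels, edf$sampling_rate_hz,
                subject_id = edf$subject_id, dyad_id = edf$dyad_id,
                schedule = schedule)
}
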