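# Continuous-EEG cleaning: zero-phase bandpass, correlation-based bad-channel
# detection, spectral-threshold segment rejection, neighbor interpolation and
# average re-referencing. Stage order (filter -> channel rejection -> segment
# rejection -> interpolation -> average reference) is fixed in preprocess().

#' Zero-phase bandpass filter
#'
#' Applies the magnitude response of a two-pass (forward-backward)
#' Butterworth cascade -- order-2 high-pass at `low_hz`, order-6 low-pass at
#' `high_hz` -- in the frequency domain. The gain is real and even in
#' frequency, so the filter is exactly zero-phase and free of the edge
#' transients of time-domain forward-backward filtering (channels are
#' demeaned first to limit circular wrap-around). The two-pass response
#' attenuates by well over 20 dB one octave outside the passband on both
#' sides (about -72 dB at `2 * high_hz`, about -25 dB at `low_hz / 2`).
#'
#' @param rec A [raw_recording()].
#' @param low_hz,high_hz Passband edges (Hz), `0 < low < high < Nyquist`.
#' @return The recording with filtered samples.
#' @export
bandpass <- function(rec, low_hz = 0.1, high_hz = 40) {
  stopifnot(inherits(rec, "raw_recording"))
  nyq <- rec$sampling_rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (high_hz >= nyq) {
    stop("high_hz (", high_hz, ") must be below the Nyquist frequency (", nyq, ")")
  }
  n <- ncol(rec$samples)
  f <- rec$sampling_rate_hz * (seq_len(n) - 1) / n
  f <- pmin(f, rec$sampling_rate_hz - f)     # two-sided frequency axis
  gain <- 1 / (1 + (f / high_hz)^12)         # two-pass order-6 low-pass
  pos <- f > 0
  gain[pos] <- gain[pos] / (1 + (low_hz / f[pos])^4)  # two-pass order-2 high-pass
  gain[!pos] <- 0
  x <- rec$samples - rowMeans(rec$samples)
  X <- stats::mvfft(t(x)) * gain
  rec$samples[] <- t(Re(stats::mvfft(X, inverse = TRUE))) / n
  rec
}

#' Detect bad channels by neighbor predictability
#'
#' A channel is flagged when the median, across 1 s windows, of its
#' correlation with a prediction from neighboring channels falls below
#' `threshold`. The prediction is the inverse-distance-weighted mean of the
#' `k` nearest other channels on the montage layout (a documented,
#' correlation-based reading of the published 0.9 channel-rejection
#' criterion). Flat channels (near-zero variance) are always flagged.
#'
#' @param rec A [raw_recording()].
#' @param threshold Correlation threshold in `(0, 1]`.
#' @param k Number of neighbor channels used for the prediction.
#' @return List with `recording` (unchanged samples) and `bad_labels`.
#' @export
reject_channels <- function(rec, threshold = 0.9, k = 8) {
  stopifnot(inherits(rec, "raw_recording"), threshold > 0, threshold <= 1)
  x <- rec$samples
  n_ch <- nrow(x)
  if (n_ch < 2) stop("reject_channels needs at least 2 channels")
  fs <- rec$sampling_rate_hz
  win <- max(2L, round(fs))
  n_win <- floor(ncol(x) / win)
  if (n_win < 1) stop("recording shorter than one 1 s window")
  k <- min(k, n_ch - 1L)

  pos <- montage_positions(rec$channel_labels)
  dmat <- as.matrix(stats::dist(pos))

  sds <- apply(x, 1, stats::sd)
  flat <- sds < 1e-9

  score_pass <- function(excluded) {
    score <- rep(NA_real_, n_ch)
    for (i in seq_len(n_ch)) {
      if (flat[i]) next
      nb <- order(dmat[i, ])
      nb <- nb[nb != i & !excluded[nb]]
      nb <- utils::head(nb, k)
      if (length(nb) == 0) { score[i] <- 0; next }
      w <- 1 / pmax(dmat[i, nb], 1e-6)
      pred <- as.numeric(crossprod(x[nb, , drop = FALSE], w)) / sum(w)
      cors <- vapply(seq_len(n_win), function(j) {
        idx <- ((j - 1L) * win + 1L):(j * win)
        suppressWarnings(stats::cor(x[i, idx], pred[idx]))
      }, numeric(1))
      score[i] <- stats::median(abs(cors), na.rm = TRUE)
    }
    score
  }
  # two passes: channels flagged on the first pass are excluded from every
  # predictor set on the second, so one corrupt channel cannot drag its
  # neighbors below threshold
  s1 <- score_pass(flat)
  bad1 <- flat | (!is.na(s1) & s1 < threshold)
  score <- if (any(bad1 & !flat)) score_pass(bad1) else s1
  bad <- flat | (!is.na(score) & score < threshold)
  if (mean(bad) > 0.5) {
    stop("more than half of the channels look bad (",
         sum(bad), "/", n_ch, "); inspect the recording before proceeding")
  }
  list(recording = rec, bad_labels = rec$channel_labels[bad],
       score = stats::setNames(score, rec$channel_labels))
}

#' Reject segments by band-power threshold
#'
#' Sliding 0.5 s windows (50% overlap); a window is rejected when its mean
#' power in `band_hz`, averaged over channels, exceeds the median window
#' band power by at least `threshold_db` dB. Medians are computed per
#' condition segment by default (`scope = "condition"`) or over the whole
#' recording (`scope = "recording"`). Windows overlapping previously
#' rejected samples (via `prior_mask`) stay rejected and are excluded from
#' the median, so re-running on already-masked data adds no new rejections.
#'
#' @param rec A [raw_recording()].
#' @param band_hz Frequency band inspected (Hz).
#' @param threshold_db Threshold above the median, in dB.
#' @param scope `"condition"` or `"recording"`.
#' @param prior_mask Optional logical vector (TRUE = kept) from a previous run.
#' @param exclude_labels Channels (e.g., flagged bad channels) ignored when
#'   computing window band power.
#' @return Logical kept-mask at sample resolution (TRUE = retained).
#' @export
reject_segments <- function(rec, band_hz = c(20, 40), threshold_db = 10,
                            scope = c("condition", "recording"),
                            prior_mask = NULL, exclude_labels = character(0)) {
  stopifnot(inherits(rec, "raw_recording"))
  scope <- match.arg(scope)
  keep_ch <- !(rec$channel_labels %in% exclude_labels)
  if (!any(keep_ch)) stop("all channels excluded from segment rejection")
  rec$samples <- rec$samples[keep_ch, , drop = FALSE]
  rec$channel_labels <- rec$channel_labels[keep_ch]
  fs <- rec$sampling_rate_hz
  n <- ncol(rec$samples)
  win <- round(0.5 * fs)
  hop <- max(1L, win %/% 2L)
  if (is.null(prior_mask)) prior_mask <- rep(TRUE, n)
  stopifnot(length(prior_mask) == n)

  ranges <- if (scope == "condition") {
    lapply(seq_len(nrow(rec$schedule)), function(i) segment_index(rec$schedule[i, ]))
  } else list(seq_len(n))

  keep <- prior_mask
  for (idx in ranges) {
    len <- length(idx)
    if (len < win) next
    starts <- seq.int(1L, len - win + 1L, by = hop)
    if (starts[length(starts)] + win - 1L < len) starts <- c(starts, len - win + 1L)
    pow <- numeric(length(starts))
    clean <- logical(length(starts))
    for (j in seq_along(starts)) {
      widx <- idx[starts[j]:(starts[j] + win - 1L)]
      pow[j] <- window_band_power(rec$samples[, widx, drop = FALSE], fs, band_hz)
      clean[j] <- all(prior_mask[widx])
    }
    med <- stats::median(pow[clean])
    if (!is.finite(med) || med <= 0) next   # no clean power anywhere: keep all
    rej <- clean & (10 * log10(pow / med) >= threshold_db)
    for (j in which(rej)) keep[idx[starts[j]:(starts[j] + win - 1L)]] <- FALSE
  }
  keep
}

# mean periodogram power within band (Hann taper), averaged over channels
window_band_power <- function(x, fs, band_hz) {
  n <- ncol(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  X <- stats::mvfft(t(x - rowMeans(x)) * w)
  p <- Mod(X)^2 / sum(w^2)
  f <- (seq_len(n) - 1) * fs / n
  sel <- f <= fs / 2 & f >= band_hz[1] & f <= band_hz[2]
  if (!any(sel)) return(0)
  mean(p[sel, ])
}

#' Interpolate bad channels and re-reference to average
#'
#' Bad channels are replaced by the inverse-distance-weighted mean of their
#' nearest good neighbors on the montage layout (a pragmatic stand-in for
#' spherical-spline interpolation; the difference is immaterial to
#' cluster-averaged band power). All channels are then re-referenced to the
#' per-sample channel mean.
#'
#' @param rec A [raw_recording()].
#' @param bad_labels Labels flagged by [reject_channels()].
#' @param kept_mask Optional sample kept-mask from [reject_segments()].
#' @param k Number of good neighbors used.
#' @param radius Maximum neighbor chord distance on the unit-hemisphere
#'   layout; a bad channel with no good neighbor within it is an error.
#' @return An object of class `clean_recording`: a [raw_recording()] plus
#'   `kept_mask`, `interpolated_labels` and `reference = "average"`.
#' @export
interpolate_and_rereference <- function(rec, bad_labels = character(0),
                                        kept_mask = NULL, k = 6,
                                        radius = 1.2) {
  stopifnot(inherits(rec, "raw_recording"))
  x <- rec$samples
  labels <- rec$channel_labels
  if (is.null(kept_mask)) kept_mask <- rep(TRUE, ncol(x))
  bad_labels <- intersect(bad_labels, labels)
  if (length(bad_labels) > 0) {
    pos <- montage_positions(labels)
    dmat <- as.matrix(stats::dist(pos))
    good <- setdiff(labels, bad_labels)
    if (length(good) == 0) stop("no good channels left to interpolate from")
    for (lab in bad_labels) {
      d <- dmat[lab, good]
      near <- names(sort(d))[seq_len(min(k, length(good)))]
      near <- near[d[near] <= radius]
      if (length(near) == 0) {
        stop("channel ", lab, " has no good neighbor within radius ", radius)
      }
      w <- 1 / pmax(d[near], 1e-6)
      x[lab, ] <- as.numeric(crossprod(x[near, , drop = FALSE], w)) / sum(w)
    }
  }
  x <- sweep(x, 2, colMeans(x), "-")
  out <- rec
  out$samples <- x
  out$kept_mask <- kept_mask
  out$interpolated_labels <- bad_labels
  out$reference <- "average"
  class(out) <- c("clean_recording", "raw_recording")
  out
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed stage order: bandpass filter, bad-channel detection,
#' spectral-threshold segment rejection, interpolation of bad channels,
#' average re-reference.
#'
#' @param rec A [raw_recording()].
#' @param config A [pipeline_config()].
#' @return List with `recording` (a `clean_recording`) and `qc` (data frame:
#'   bad channels, fraction of samples rejected per condition, post-reference
#'   channel-mean check).
#' @export
preprocess <- function(rec, config = pipeline_config()) {
  filt <- bandpass(rec, config$band_hz[1], config$band_hz[2])
  chan <- reject_channels(filt, config$channel_reject_threshold,
                          k = config$neighbor_k)
  mask <- reject_segments(filt, config$artifact_band_hz,
                          config$artifact_threshold_db,
                          scope = config$segment_scope,
                          exclude_labels = chan$bad_labels)
  clean <- interpolate_and_rereference(filt, chan$bad_labels, mask,
                                       k = config$neighbor_k)
  rej_by_cond <- vapply(seq_len(nrow(rec$schedule)), function(i) {
    idx <- segment_index(rec$schedule[i, ])
    mean(!mask[idx])
  }, numeric(1))
  qc <- data.frame(
    subject_id = rec$subject_id,
    condition = rec$schedule$condition,
    frac_rejected = rej_by_cond,
    n_bad_channels = length(chan$bad_labels),
    bad_channels = paste(chan$bad_labels, collapse = ";"),
    max_abs_channel_mean = max(abs(colMeans(clean$samples))),
    stringsAsFactors = FALSE)
  list(recording = clean, qc = qc)
}
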