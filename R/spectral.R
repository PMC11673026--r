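# Epoching, per-epoch alpha power, and frontal alpha asymmetry (FAA).

#' Epoch a recording into fixed windows per condition
#'
#' Non-overlapping, contiguous windows of `epoch_s` seconds from each
#' condition's start; a trailing partial window is dropped. An epoch is
#' invalid when any of its samples is masked as rejected.
#'
#' @param rec A `clean_recording` (or [raw_recording()]; then all samples
#'   count as kept).
#' @param epoch_s Epoch length in seconds; `epoch_s * sampling_rate` must be
#'   a whole number.
#' @return Data frame: `condition`, `epoch_index` (0-based within condition),
#'   `start_sample` (0-based), `valid`.
#' @export
epoch_recording <- function(rec, epoch_s = 0.5) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate_hz
  ep_n <- epoch_s * fs
  if (abs(ep_n - round(ep_n)) > 1e-9) {
    stop("epoch_s * sampling_rate must be an integer number of samples")
  }
  ep_n <- as.integer(round(ep_n))
  mask <- rec$kept_mask
  if (is.null(mask)) mask <- rep(TRUE, ncol(rec$samples))
  out <- lapply(seq_len(nrow(rec$schedule)), function(i) {
    seg <- rec$schedule[i, ]
    n_ep <- floor(seg$n_samples / ep_n)
    if (n_ep == 0) {
      warning("condition '", seg$condition, "' is shorter than one epoch")
      return(NULL)
    }
    starts <- seg$start_sample + (seq_len(n_ep) - 1L) * ep_n
    valid <- vapply(starts, function(s) all(mask[(s + 1L):(s + ep_n)]), logical(1))
    data.frame(condition = seg$condition, epoch_index = seq_len(n_ep) - 1L,
               start_sample = as.integer(starts), valid = valid,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Hann-tapered zero-padded periodogram of an epoch (channels x samples).
# Returns power (arbitrary but consistent units) per channel x frequency and
# the frequency grid (grid_hz spacing).
epoch_periodogram <- function(x, fs, grid_hz = 0.5) {
  n <- ncol(x)
  nfft <- max(n, round(fs / grid_hz))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  xt <- t(x - rowMeans(x)) * w
  pad <- matrix(0, nfft - n, nrow(x))
  X <- stats::mvfft(rbind(xt, pad))
  p <- t(Mod(X)^2) / sum(w^2)
  f <- (seq_len(nfft) - 1) * fs / nfft
  half <- f <= fs / 2
  list(power = p[, half, drop = FALSE], freq = f[half])
}

#' Per-epoch per-channel alpha power
#'
#' Absolute alpha is the mean periodogram power within `alpha_band_hz`
#' (inclusive) on a 0.5 Hz zero-padded grid with a Hann taper; relative
#' alpha is the summed periodogram power in the alpha band divided by the
#' summed power in `total_band_hz`, hence a fraction in `[0, 1]`.
#'
#' @param rec A `clean_recording`.
#' @param epochs Output of [epoch_recording()].
#' @param alpha_band_hz,total_band_hz Band edges in Hz.
#' @param grid_hz Frequency-grid spacing for the zero-padded periodogram.
#' @param channels Optional subset of channel labels to compute spectra for
#'   (e.g., just the cluster channels when only FAA is needed).
#' @return An object of class `epoch_spectrum`: list with `epochs` (the
#'   epoch table, `valid` updated for degenerate epochs), matrices
#'   `abs_alpha` and `rel_alpha` (channels x epochs), and metadata.
#' @export
epoch_band_power <- function(rec, epochs, alpha_band_hz = c(8, 12),
                             total_band_hz = c(1, 40), grid_hz = 0.5,
                             channels = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!is.null(channels)) {
    missing <- setdiff(channels, rec$channel_labels)
    if (length(missing) > 0) stop("unknown channels: ", paste(missing, collapse = ", "))
    rec$samples <- rec$samples[match(channels, rec$channel_labels), , drop = FALSE]
    rec$channel_labels <- channels
  }
  fs <- rec$sampling_rate_hz
  ep_n <- if (nrow(epochs) > 1) {
    min(diff(sort(unique(epochs$start_sample))))
  } else ncol(rec$samples) - epochs$start_sample[1]
  n_ch <- nrow(rec$samples)
  n_ep <- nrow(epochs)
  abs_a <- matrix(NA_real_, n_ch, n_ep)
  rel_a <- matrix(NA_real_, n_ch, n_ep)
  valid <- epochs$valid
  for (j in seq_len(n_ep)) {
    idx <- (epochs$start_sample[j] + 1L):(epochs$start_sample[j] + ep_n)
    x <- rec$samples[, idx, drop = FALSE]
    if (all(abs(x) < 1e-12)) { valid[j] <- FALSE; next }
    pg <- epoch_periodogram(x, fs, grid_hz)
    a_sel <- pg$freq >= alpha_band_hz[1] & pg$freq <= alpha_band_hz[2]
    t_sel <- pg$freq >= total_band_hz[1] & pg$freq <= total_band_hz[2]
    abs_a[, j] <- rowMeans(pg$power[, a_sel, drop = FALSE])
    tot <- rowSums(pg$power[, t_sel, drop = FALSE])
    rel_a[, j] <- ifelse(tot > 0, rowSums(pg$power[, a_sel, drop = FALSE]) / tot, NA)
  }
  epochs$valid <- valid
  structure(list(subject_id = rec$subject_id, dyad_id = rec$dyad_id,
                 epochs = epochs, abs_alpha = abs_a, rel_alpha = rel_a,
                 channel_labels = rec$channel_labels,
                 alpha_band_hz = alpha_band_hz, total_band_hz = total_band_hz),
            class = "epoch_spectrum")
}

#' Frontal alpha asymmetry per epoch
#'
#' Cluster power is the mean of the chosen alpha measure over the cluster's
#' channels; `faa = ln(right) - ln(left)`. Positive values mean more
#' right-cluster alpha (conventionally read as approach-like motivation).
#' Epochs with a nonpositive cluster power are marked invalid.
#'
#' @param spectra An [epoch_band_power()] result.
#' @param clusters A [cluster_spec()].
#' @param alpha_mode `"relative"` (default, the convention in the asymmetry
#'   literature) or `"absolute"`.
#' @return Data frame: `subject_id`, `dyad_id`, `condition`, `epoch_index`,
#'   `faa`, `valid`, `alpha_mode`.
#' @export
compute_faa <- function(spectra, clusters = cluster_spec(),
                        alpha_mode = c("relative", "absolute")) {
  stopifnot(inherits(spectra, "epoch_spectrum"))
  alpha_mode <- match.arg(alpha_mode)
  check_clusters_present(clusters, spectra$channel_labels)
  m <- if (alpha_mode == "relative") spectra$rel_alpha else spectra$abs_alpha
  rownames(m) <- spectra$channel_labels
  left <- colMeans(m[clusters$left, , drop = FALSE])
  right <- colMeans(m[clusters$right, , drop = FALSE])
  faa <- ifelse(!is.na(left) & !is.na(right) & left > 0 & right > 0,
                log(right) - log(left), NA_real_)
  valid <- spectra$epochs$valid & !is.na(faa)
  data.frame(subject_id = spectra$subject_id, dyad_id = spectra$dyad_id,
             condition = spectra$epochs$condition,
             epoch_index = spectra$epochs$epoch_index,
             faa = ifelse(valid, faa, NA_real_), valid = valid,
             alpha_mode = alpha_mode, stringsAsFactors = FALSE)
}

#' FAA series straight from a cleaned recording
#'
#' Convenience wrapper: [epoch_recording()] then [epoch_band_power()] then
#' [compute_faa()] with the settings in `config`.
#'
#' @param rec A `clean_recording`.
#' @param config A [pipeline_config()].
#' @return The [compute_faa()] data frame.
#' @export
faa_series <- function(rec, config = pipeline_config()) {
  eps <- epoch_recording(rec, config$epoch_s)
  spec <- epoch_band_power(rec, eps, config$alpha_band_hz,
                           config$total_band_hz, config$grid_hz,
                           channels = c(config$clusters$left,
                                        config$clusters$right))
  compute_faa(spec, config$clusters, config$alpha_mode)
}
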