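#' Configuration for the synthetic dyadic-EEG generator
#'
#' Defines the study-like conditions the generator emulates: a five-condition
#' nonverbal-connection schedule (2 min each), 250 Hz sampling on a
#' 128-channel geodesic montage, alpha (8-12 Hz) oscillations whose
#' left/right frontal-cluster amplitudes follow a slowly varying latent
#' asymmetry driver per person, inter-partner coupling of the drivers at a
#' configurable delay, a spatially common slow background, white sensor
#' noise, and optional 20-40 Hz artifact bursts and bad channels.
#'
#' The latent driver `d` is AR(1) on a 2 s bin grid (held constant within a
#' bin). Cluster amplitudes are `alpha_amp * exp(-d/2)` (left) and
#' `alpha_amp * exp(+d/2)` (right), so that on the raw cluster signals
#' `ln(right alpha power) - ln(left alpha power) = 2 d` exactly; the full
#' pipeline estimate of FAA is proportional to `2 d` (attenuated by the
#' relative-power normalization and average reference), which is what the
#' recovery tests rely on.
#'
#' Partner 2's driver is `coupling_strength * d1(t - delay) +
#' (1 - coupling_strength) * independent AR(1)`.
#'
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param channel_labels Montage labels; must contain all cluster channels.
#' @param condition_schedule Data frame `condition`, `duration_s`; conditions
#'   are presented contiguously from time 0 in row order.
#' @param alpha_freq_hz Alpha oscillation center frequency, in `[8, 12]`.
#' @param alpha_bw_hz Spectral linewidth (Lorentzian FWHM, Hz) of the alpha
#'   oscillation. Alpha is a constant-amplitude oscillator whose phase
#'   performs a random walk (as scalp alpha does), not a deterministic
#'   sinusoid: per-epoch power stays stable while phase decoherence makes
#'   estimation biases decorrelate across epochs.
#' @param clusters A [cluster_spec()].
#' @param driver_phi AR(1) coefficient of the latent driver at the 2 s bin
#'   scale, in `(-1, 1)`.
#' @param driver_sd Stationary s.d. of the driver around its condition mean
#'   (0 freezes the driver at the condition mean).
#' @param driver_mean Named vector of per-condition driver means (FAA scale
#'   is about twice this), or a single unnamed value for all conditions.
#' @param driver_bin_s Bin length (s) of the driver grid.
#' @param coupling_delay_s Delay of partner 2's coupled component (s); must
#'   be a multiple of `1/sampling_rate_hz` and shorter than every condition.
#' @param coupling_strength Mixing weight in `[0, 1]`.
#' @param alpha_amp Alpha amplitude scale (microvolts).
#' @param noncluster_alpha_gain Alpha amplitude of non-cluster channels,
#'   relative to `alpha_amp`.
#' @param background_sd,background_phi S.d. (microvolts) and sample-scale
#'   AR(1) coefficient of the slow background shared by all channels.
#' @param background_gain_sd S.d. of the per-channel gain (around 1) applied
#'   to the shared background.
#' @param local_bg_sd,local_bg_phi S.d. (microvolts) and AR(1) coefficient of
#'   an independent slow component per channel. It survives average
#'   re-referencing and keeps relative alpha in a realistic range without
#'   introducing stable between-channel power differences (its variance is
#'   identical across channels).
#' @param noise_sd Per-channel white-noise s.d. (microvolts).
#' @param artifact_rate_per_min Expected artifact bursts per minute.
#' @param artifact_duration_s Burst duration (s).
#' @param artifact_band Frequency range (Hz) bursts are drawn from.
#' @param artifact_snr_db Burst band power above the recording's own
#'   `artifact_band` band power (dB), measured from the generated signal.
#' @param bad_channel_labels Channels to corrupt.
#' @param bad_channel_type `"flat"` or `"noisy"`, recycled over
#'   `bad_channel_labels`.
#' @param bad_noisy_sd S.d. of a `"noisy"` bad channel.
#' @param seed Integer seed; one global seed drives a fixed per-stream seed
#'   sequence (streams, in order: driver p1, independent driver p2, signal
#'   p1, signal p2, artifacts p1, artifacts p2, bad channels p1, bad
#'   channels p2).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(sampling_rate_hz = 250,
                         channel_labels = geodesic_labels(),
                         condition_schedule = data.frame(
                           condition = c("No Connection", "Gaze Only",
                                         "Hands Only", "Gaze and Hands",
                                         "Embrace"),
                           duration_s = 120),
                         alpha_freq_hz = 10,
                         alpha_bw_hz = 1,
                         clusters = cluster_spec(),
                         driver_phi = 0.7,
                         driver_sd = 0.2,
                         driver_mean = c("No Connection" = 0.060,
                                         "Gaze Only" = 0.092,
                                         "Hands Only" = 0.092,
                                         "Gaze and Hands" = 0.091,
                                         "Embrace" = 0.058),
                         driver_bin_s = 2,
                         coupling_delay_s = 4,
                         coupling_strength = 0.5,
                         alpha_amp = 10,
                         noncluster_alpha_gain = 0.5,
                         background_sd = 40,
                         background_phi = 0.95,
                         background_gain_sd = 0.1,
                         local_bg_sd = 10,
                         local_bg_phi = 0.98,
                         noise_sd = 5,
                         artifact_rate_per_min = 1,
                         artifact_duration_s = 0.5,
                         artifact_band = c(20, 40),
                         artifact_snr_db = 15,
                         bad_channel_labels = character(0),
                         bad_channel_type = "flat",
                         bad_noisy_sd = 100,
                         seed = 1) {
  stopifnot(sampling_rate_hz > 0, alpha_freq_hz >= 8, alpha_freq_hz <= 12,
            abs(driver_phi) < 1, driver_sd >= 0, driver_bin_s > 0,
            coupling_delay_s >= 0, coupling_strength >= 0,
            coupling_strength <= 1, alpha_amp > 0, background_sd > 0,
            noise_sd > 0, artifact_rate_per_min >= 0)
  if (!is.data.frame(condition_schedule) ||
      !all(c("condition", "duration_s") %in% names(condition_schedule)) ||
      nrow(condition_schedule) == 0 ||
      any(condition_schedule$duration_s <= 0)) {
    stop("condition_schedule must be a non-empty data frame with columns ",
         "condition, duration_s (positive)")
  }
  check_clusters_present(clusters, channel_labels)
  fs <- sampling_rate_hz
  if (abs(coupling_delay_s * fs - round(coupling_delay_s * fs)) > 1e-8) {
    stop("coupling_delay_s must be a multiple of 1/sampling_rate_hz")
  }
  if (round(coupling_delay_s * fs) >= min(round(condition_schedule$duration_s * fs))) {
    stop("coupling_delay_s (", coupling_delay_s,
         " s) must be shorter than every condition segment")
  }
  conds <- as.character(condition_schedule$condition)
  if (length(driver_mean) == 1 && is.null(names(driver_mean))) {
    driver_mean <- stats::setNames(rep(driver_mean, length(conds)), conds)
  }
  if (!all(conds %in% names(driver_mean))) {
    stop("driver_mean must name every scheduled condition")
  }
  cfg <- list(sampling_rate_hz = fs, channel_labels = channel_labels,
              condition_schedule = condition_schedule,
              alpha_freq_hz = alpha_freq_hz, alpha_bw_hz = alpha_bw_hz,
              clusters = clusters,
              driver_phi = driver_phi, driver_sd = driver_sd,
              driver_mean = driver_mean, driver_bin_s = driver_bin_s,
              coupling_delay_s = coupling_delay_s,
              coupling_strength = coupling_strength,
              alpha_amp = alpha_amp,
              noncluster_alpha_gain = noncluster_alpha_gain,
              background_sd = background_sd, background_phi = background_phi,
              background_gain_sd = background_gain_sd,
              local_bg_sd = local_bg_sd, local_bg_phi = local_bg_phi,
              noise_sd = noise_sd,
              artifact_rate_per_min = artifact_rate_per_min,
              artifact_duration_s = artifact_duration_s,
              artifact_band = artifact_band,
              artifact_snr_db = artifact_snr_db,
              bad_channel_labels = bad_channel_labels,
              bad_channel_type = bad_channel_type,
              bad_noisy_sd = bad_noisy_sd, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# derived per-stream seeds from the one global seed (documented stream order)
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483629)
}

# AR(1) latent driver on the bin grid, restarted at each condition with a
# stationary draw around that condition's mean; returned at sample resolution
# (piecewise constant over bins) together with the schedule in samples.
synth_driver <- function(cfg) {
  fs <- cfg$sampling_rate_hz
  bin_n <- round(cfg$driver_bin_s * fs)
  seg_n <- round(cfg$condition_schedule$duration_s * fs)
  phi <- cfg$driver_phi
  inn_sd <- cfg$driver_sd * sqrt(1 - phi^2)
  out <- numeric(sum(seg_n))
  pos <- 0L
  for (i in seq_len(nrow(cfg$condition_schedule))) {
    mu <- cfg$driver_mean[[as.character(cfg$condition_schedule$condition[i])]]
    nb <- ceiling(seg_n[i] / bin_n)
    d <- numeric(nb)
    d[1] <- stats::rnorm(1, mu, cfg$driver_sd)
    if (nb > 1) {
      for (b in 2:nb) d[b] <- mu + phi * (d[b - 1] - mu) + stats::rnorm(1, 0, inn_sd)
    }
    out[pos + seq_len(seg_n[i])] <- rep(d, each = bin_n)[seq_len(seg_n[i])]
    pos <- pos + seg_n[i]
  }
  out
}

# channel signals for one partner given their sample-level driver
# constant-amplitude oscillation at f0 whose phase random-walks; the
# phase-diffusion rate gives a Lorentzian line of FWHM bw (Hz)
phase_walk_osc <- function(n, fs, f0, bw) {
  theta <- cumsum(stats::rnorm(n, 0, sqrt(2 * pi * bw / fs))) +
    stats::runif(1, 0, 2 * pi)
  sin(2 * pi * f0 * (seq_len(n) - 1) / fs + theta)
}

synth_signals <- function(cfg, d) {
  fs <- cfg$sampling_rate_hz
  n <- length(d)
  labels <- cfg$channel_labels
  n_ch <- length(labels)

  # shared slow background with per-channel gain (draw order within the
  # signal stream: gains, background innovations, then per channel its
  # alpha phase walk, its local slow component, and its white noise)
  gains <- 1 + stats::rnorm(n_ch, 0, cfg$background_gain_sd)
  bg_inn <- stats::rnorm(n + 1000L, 0, cfg$background_sd * sqrt(1 - cfg$background_phi^2))
  bg <- stats::filter(bg_inn, cfg$background_phi, method = "recursive")
  bg <- as.numeric(bg)[1001L:(n + 1000L)]
  gain_left <- exp(-d / 2)
  gain_right <- exp(d / 2)

  x <- matrix(0, n_ch, n)
  for (i in seq_len(n_ch)) {
    gain <- if (labels[i] %in% cfg$clusters$left) gain_left
            else if (labels[i] %in% cfg$clusters$right) gain_right
            else cfg$noncluster_alpha_gain
    alpha <- phase_walk_osc(n, fs, cfg$alpha_freq_hz, cfg$alpha_bw_hz)
    local <- as.numeric(stats::filter(
      stats::rnorm(n, 0, cfg$local_bg_sd * sqrt(1 - cfg$local_bg_phi^2)),
      cfg$local_bg_phi, method = "recursive"))
    x[i, ] <- gains[i] * bg + local +
      cfg$alpha_amp * gain * alpha +
      stats::rnorm(n, 0, cfg$noise_sd)
  }
  rownames(x) <- labels
  x
}

# broadband-exceeding narrowband bursts applied to every channel; returns
# the corrupted matrix plus the ground-truth burst intervals
synth_artifacts <- function(cfg, x) {
  fs <- cfg$sampling_rate_hz
  n <- ncol(x)
  lambda <- cfg$artifact_rate_per_min * n / fs / 60
  n_burst <- stats::rpois(1, lambda)
  none <- data.frame(start_sample = integer(0), end_sample = integer(0),
                     freq_hz = numeric(0))
  if (n_burst == 0) return(list(x = x, bursts = none))
  dur <- round(cfg$artifact_duration_s * fs)
  # burst sinusoid band power amp^2/2 sits artifact_snr_db above the
  # recording's own measured band power (the slow background's spectral
  # tail, not just the white noise, sets that floor)
  win <- max(4L, round(0.5 * fs))
  probe <- seq(1L, max(1L, n - win), length.out = min(40, max(1, n %/% win)))
  band_bg <- stats::median(vapply(round(probe), function(s)
    window_band_power(x[, s:(s + win - 1L), drop = FALSE], fs,
                      cfg$artifact_band), numeric(1)))
  band_bg <- max(band_bg, 1e-12)
  amp <- sqrt(2 * band_bg * 10^(cfg$artifact_snr_db / 10))
  starts <- sort(sample.int(max(1L, n - dur), n_burst, replace = TRUE))
  freqs <- stats::runif(n_burst, cfg$artifact_band[1], cfg$artifact_band[2])
  for (b in seq_len(n_burst)) {
    idx <- starts[b]:(starts[b] + dur - 1L)
    burst <- amp * sin(2 * pi * freqs[b] * (idx - 1) / fs)
    x[, idx] <- sweep(x[, idx, drop = FALSE], 2, burst, "+")
  }
  list(x = x,
       bursts = data.frame(start_sample = as.integer(starts - 1L),
                           end_sample = as.integer(starts - 1L + dur),
                           freq_hz = freqs))
}

synth_bad_channels <- function(cfg, x) {
  if (length(cfg$bad_channel_labels) == 0) return(x)
  types <- rep_len(cfg$bad_channel_type, length(cfg$bad_channel_labels))
  for (i in seq_along(cfg$bad_channel_labels)) {
    lab <- cfg$bad_channel_labels[i]
    if (!lab %in% rownames(x)) stop("bad_channel_labels: unknown channel ", lab)
    x[lab, ] <- if (types[i] == "flat") 0 else stats::rnorm(ncol(x), 0, cfg$bad_noisy_sd)
  }
  x
}

#' Generate one synthetic dyad
#'
#' Produces two sample-aligned recordings whose frontal-cluster alpha
#' amplitudes follow coupled latent asymmetry drivers (see [synth_config()]).
#' Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @param dyad_id Identifier for the dyad.
#' @return An object of class `synth_dyad`: list with recordings `p1`, `p2`
#'   ([raw_recording()]), sample-level latent drivers `latent_p1`,
#'   `latent_p2`, ground-truth artifact intervals `bursts_p1`, `bursts_p2`
#'   (0-based half-open sample ranges), and `config`.
#' @export
generate_dyad <- function(config, dyad_id = "d1") {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  fs <- cfg$sampling_rate_hz
  seg_n <- round(cfg$condition_schedule$duration_s * fs)
  delay_n <- round(cfg$coupling_delay_s * fs)
  if (delay_n >= min(seg_n)) {
    stop("coupling_delay_s (", cfg$coupling_delay_s,
         " s) must be shorter than every condition segment")
  }

  set.seed(stream_seed(cfg$seed, 1)); d1 <- synth_driver(cfg)
  set.seed(stream_seed(cfg$seed, 2)); d_ind <- synth_driver(cfg)
  d1_shift <- if (delay_n > 0) {
    c(rep(d1[1], delay_n), d1[seq_len(length(d1) - delay_n)])
  } else d1
  d2 <- cfg$coupling_strength * d1_shift + (1 - cfg$coupling_strength) * d_ind

  starts <- cumsum(c(0L, seg_n))[seq_len(nrow(cfg$condition_schedule))]
  schedule <- data.frame(condition = as.character(cfg$condition_schedule$condition),
                         start_sample = as.integer(starts),
                         n_samples = as.integer(seg_n),
                         stringsAsFactors = FALSE)

  build <- function(d, sig_stream, art_stream, bad_stream, subj) {
    set.seed(stream_seed(cfg$seed, sig_stream))
    x <- synth_signals(cfg, d)
    set.seed(stream_seed(cfg$seed, art_stream))
    art <- synth_artifacts(cfg, x)
    set.seed(stream_seed(cfg$seed, bad_stream))
    x <- synth_bad_channels(cfg, art$x)
    list(rec = raw_recording(x, cfg$channel_labels, fs, subject_id = subj,
                             dyad_id = dyad_id, schedule = schedule),
         bursts = art$bursts)
  }
  p1 <- build(d1, 3, 5, 7, paste0(dyad_id, "_p1"))
  p2 <- build(d2, 4, 6, 8, paste0(dyad_id, "_p2"))

  structure(list(p1 = p1$rec, p2 = p2$rec, latent_p1 = d1, latent_p2 = d2,
                 bursts_p1 = p1$bursts, bursts_p2 = p2$bursts,
                 config = cfg, dyad_id = dyad_id),
            class = "synth_dyad")
}

#' @export
print.synth_dyad <- function(x, ...) {
  cat(sprintf("<synth_dyad> %s: %d channels x %d samples @ %g Hz, %d conditions\n",
              x$dyad_id, nrow(x$p1$samples), ncol(x$p1$samples),
              x$config$sampling_rate_hz, nrow(x$p1$schedule)))
  invisible(x)
}

#' Bin-averaged latent driver of a synthetic dyad
#'
#' Averages each partner's sample-level latent driver over the same 2 s bin
#' grid the pipeline uses (bins counted from each condition's start, trailing
#' partial bins dropped), for ground-truth recovery checks.
#'
#' @param dyad A [generate_dyad()] result.
#' @param bin_s Bin length in seconds.
#' @return Data frame: `subject_id`, `condition`, `bin_index` (0-based), `d`.
#' @export
latent_bin_series <- function(dyad, bin_s = 2) {
  stopifnot(inherits(dyad, "synth_dyad"))
  fs <- dyad$config$sampling_rate_hz
  bin_n <- round(bin_s * fs)
  one <- function(d, subj) {
    res <- lapply(seq_len(nrow(dyad$p1$schedule)), function(i) {
      seg <- dyad$p1$schedule[i, ]
      nb <- floor(seg$n_samples / bin_n)
      if (nb == 0) return(NULL)
      vals <- vapply(seq_len(nb) - 1L, function(b) {
        mean(d[seg$start_sample + b * bin_n + seq_len(bin_n)])
      }, numeric(1))
      data.frame(subject_id = subj, condition = seg$condition,
                 bin_index = seq_len(nb) - 1L, d = vals,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  rbind(one(dyad$latent_p1, dyad$p1$subject_id),
        one(dyad$latent_p2, dyad$p2$subject_id))
}

#' Write a synthetic dyad to disk
#'
#' One EDF per partner, the schedule as CSV (`condition,start_s,duration_s`),
#' and a JSON sidecar holding the generating configuration and the
#' bin-averaged latent drivers (ground truth for recovery tests).
#'
#' @param dyad A [generate_dyad()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_dyad <- function(dyad, dir) {
  stopifnot(inherits(dyad, "synth_dyad"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- dyad$config$sampling_rate_hz
  p1 <- file.path(dir, "p1.edf"); write_edf(dyad$p1, p1)
  p2 <- file.path(dir, "p2.edf"); write_edf(dyad$p2, p2)
  sched <- data.frame(condition = dyad$p1$schedule$condition,
                      start_s = dyad$p1$schedule$start_sample / fs,
                      duration_s = dyad$p1$schedule$n_samples / fs)
  sp <- file.path(dir, "schedule.csv")
  utils::write.csv(sched, sp, row.names = FALSE)
  cfg <- dyad$config
  cfg$clusters <- unclass(cfg$clusters)
  cfg$condition_schedule <- as.list(cfg$condition_schedule)
  truth <- list(config = unclass(cfg),
                latent_bins = latent_bin_series(dyad))
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list(p1 = p1, p2 = p2, schedule = sp, truth = tp))
}

#' Generate a subject-covariate table
#'
#' Two rows per dyad with demographic, relationship, and weekly-diary style
#' variables on the scales used in dyadic EEG studies of romantic partners:
#' survey constructs on 1-10 (strongly disagree to strongly agree), times in
#' hours. Dyad-level variables (relationship duration, shared time) are
#' identical within a dyad. Reproducible given `seed`.
#'
#' @param n_dyads Number of dyads (>= 1).
#' @param seed Integer seed.
#' @return Data frame with one row per subject.
#' @export
generate_covariates <- function(n_dyads, seed = 1) {
  stopifnot(n_dyads >= 1)
  set.seed(as.integer(seed))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  n <- 2L * n_dyads
  dyad_id <- rep(paste0("d", seq_len(n_dyads)), each = 2)
  subject_id <- paste0(dyad_id, "_p", rep(1:2, n_dyads))
  dy <- function(mean, sd, lo, hi)   # dyad-level, shared by both partners
    rep(clamp(stats::rnorm(n_dyads, mean, sd), lo, hi), each = 2)
  su <- function(mean, sd, lo, hi) clamp(stats::rnorm(n, mean, sd), lo, hi)
  data.frame(
    dyad_id = dyad_id, subject_id = subject_id,
    age_years = su(28, 5, 18, 40),
    relationship_years = dy(7.4, 6, 1, 20),
    weekday_hours = dy(40.8, 19.2, 0, 112),
    weekend_hours = dy(75.9, 19.1, 0, 120),
    perceived_love = su(9.0, 1.0, 1, 10),
    wellbeing = su(6.7, 1.4, 1, 10),
    weekly_perceived_love = su(8.3, 1.3, 1, 10),
    weekly_loving_feelings = su(7.1, 1.5, 1, 10),
    weekly_negative_feelings = su(1.9, 0.7, 1, 10),
    weekly_positive_feelings = su(6.9, 1.7, 1, 10),
    weekly_wellbeing = su(6.1, 0.9, 1, 10),
    weekly_shared_time_hours = dy(5.8, 2.3, 0, 24),
    stringsAsFactors = FALSE)
}
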