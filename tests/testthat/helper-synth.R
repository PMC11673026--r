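# Shared fixtures: reduced montages and quick generator configs so tests run
# in seconds. Cluster channels are always present; extra channels pad the
# montage for reference/interpolation realism.

small_montage <- function() {
  c(cluster_spec()$left, cluster_spec()$right, "E50", "E60")
}

# ~34 channels: used where average-reference interference must be small
mid_montage <- function() {
  unique(c(cluster_spec()$left, cluster_spec()$right,
           paste0("E", seq(5, 120, by = 5))))
}

quick_config <- function(duration_s = c(20, 20), conditions = c("A", "B"),
                         labels = small_montage(), seed = 1, ...) {
  args <- utils::modifyList(
    list(driver_mean = 0.1, artifact_rate_per_min = 0), list(...))
  do.call(synth_config, c(
    list(channel_labels = labels,
         condition_schedule = data.frame(condition = conditions,
                                         duration_s = duration_s),
         seed = seed),
    args))
}

# a flat multi-channel recording with one condition, for constructed signals
tone_recording <- function(x, fs = 250, n_ch = NULL, labels = NULL) {
  if (is.null(labels)) labels <- small_montage()[seq_len(n_ch)]
  samples <- matrix(rep(x, each = length(labels)), nrow = length(labels))
  raw_recording(samples, labels, fs, "s1", "d1",
                data.frame(condition = "A", start_sample = 0L,
                           n_samples = length(x)))
}

# independent brute-force concordance oracle (explicit sums, 1/n moments)
ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0; sx <- 0; sy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sx <- sx + (x[i] - mx)^2
    sy <- sy + (y[i] - my)^2
  }
  2 * (sxy / n) / (sx / n + sy / n + (mx - my)^2)
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
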