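clean_rec <- function(x, fs = 250, labels = small_montage(),
                      schedule = NULL, mask = NULL) {
  n <- length(x)
  samples <- matrix(rep(x, each = length(labels)), nrow = length(labels))
  if (is.null(schedule)) {
    schedule <- data.frame(condition = "A", start_sample = 0L, n_samples = n)
  }
  rec <- raw_recording(samples, labels, fs, "s1", "d1", schedule)
  interpolate_and_rereference(rec, character(0), kept_mask = mask)
}

test_that("epoching yields the expected counts and drops partial windows", {
  fs <- 250
  sched <- data.frame(condition = c("Full", "Short"),
                      start_sample = c(0L, 30000L),
                      n_samples = c(30000L, 22500L))
  rec <- clean_rec(rnorm(52500), schedule = sched)
  eps <- epoch_recording(rec, 0.5)
  expect_identical(sum(eps$condition == "Full"), 240L)   # 120 s -> 240 epochs
  expect_identical(sum(eps$condition == "Short"), 180L)  # 90 s -> 180
  expect_true(all(diff(eps$start_sample[eps$condition == "Full"]) == 125L))

  # a 90 s condition with a 0.3 s remainder still yields 180 epochs
  sched2 <- data.frame(condition = "A", start_sample = 0L, n_samples = 22575L)
  rec2 <- clean_rec(rnorm(22575), schedule = sched2)
  expect_identical(nrow(epoch_recording(rec2, 0.5)), 180L)

  # condition shorter than one epoch: zero epochs, warning
  sched3 <- data.frame(condition = "A", start_sample = 0L, n_samples = 100L)
  rec3 <- clean_rec(rnorm(100), schedule = sched3)
  expect_warning(eps3 <- epoch_recording(rec3, 0.5), "shorter than one epoch")
  expect_null(eps3)
})

test_that("epochs overlapping rejected samples are invalid", {
  mask <- rep(TRUE, 5000)
  mask[1251:1600] <- FALSE              # covers epochs 10 (0-based) onward
  rec <- clean_rec(rnorm(5000), mask = mask)
  eps <- epoch_recording(rec, 0.5)
  expect_false(any(eps$valid[eps$epoch_index %in% 10:12]))
  expect_true(all(eps$valid[eps$epoch_index %in% c(0:9, 13:39)]))
})

test_that("band power matches the tone-energy oracle", {
  fs <- 250
  t <- (0:124) / fs
  one_epoch <- function(x) {
    rec <- tone_recording(x, n_ch = 3)   # raw recording, no re-reference
    epoch_band_power(rec, epoch_recording(rec, 0.5))
  }
  # pure 10 Hz: nearly all in-band energy (Hann mainlobe tails lose ~4%)
  s10 <- one_epoch(sin(2 * pi * 10 * t + 0.3))
  expect_equal(median(s10$rel_alpha), 0.9563, tolerance = 0.01)
  # pure 30 Hz: essentially no alpha
  s30 <- one_epoch(sin(2 * pi * 30 * t + 1.1))
  expect_lt(median(s30$rel_alpha), 1e-4)
  # two tones: relative alpha = (in-band fraction) * a^2/(a^2+b^2)
  h <- median(s10$rel_alpha)
  for (ab in list(c(2, 1), c(1, 3))) {
    s <- one_epoch(ab[1] * sin(2 * pi * 10 * t + 0.3) +
                   ab[2] * sin(2 * pi * 30 * t + 1.1))
    expect_equal(median(s$rel_alpha), h * ab[1]^2 / sum(ab^2),
                 tolerance = 1e-3)
  }
  # all-zero epoch is marked invalid
  sz <- one_epoch(rep(0, 125))
  expect_false(any(sz$epochs$valid))
})

make_spectrum <- function(left_pow, right_pow, labels = small_montage()) {
  n_ep <- length(left_pow)
  cl <- cluster_spec()
  m <- matrix(1, length(labels), n_ep, dimnames = list(labels, NULL))
  m[cl$left, ] <- matrix(rep(left_pow, each = 5), 5)
  m[cl$right, ] <- matrix(rep(right_pow, each = 5), 5)
  structure(list(subject_id = "s1", dyad_id = "d1",
                 epochs = data.frame(condition = "A",
                                     epoch_index = seq_len(n_ep) - 1L,
                                     start_sample = 0L, valid = TRUE),
                 abs_alpha = m, rel_alpha = m / 2,
                 channel_labels = labels,
                 alpha_band_hz = c(8, 12), total_band_hz = c(1, 40)),
            class = "epoch_spectrum")
}

test_that("FAA is the log cluster ratio with exact closed forms", {
  sp <- make_spectrum(c(1, 1, 2), c(1, 2, 2))
  faa <- compute_faa(sp, alpha_mode = "absolute")
  expect_equal(faa$faa, c(0, log(2), 0))
  # nonpositive cluster power invalidates the epoch
  sp2 <- make_spectrum(c(1, 0), c(1, 1))
  faa2 <- compute_faa(sp2, alpha_mode = "absolute")
  expect_false(faa2$valid[2])
})

test_that("FAA is antisymmetric under cluster swap and scale invariant", {
  set.seed(3)
  sp <- make_spectrum(runif(20, 0.5, 2), runif(20, 0.5, 2))
  cl <- cluster_spec()
  faa <- compute_faa(sp, cl, "absolute")
  swapped <- compute_faa(sp, cluster_spec(left = cl$right, right = cl$left),
                         "absolute")
  expect_identical(faa$faa, -swapped$faa)

  # multiplying every channel by a constant leaves relative-mode FAA as is
  sp_scaled <- sp
  sp_scaled$rel_alpha <- sp$rel_alpha          # relative power is unitless
  sp_scaled$abs_alpha <- sp$abs_alpha * 7.3
  expect_equal(compute_faa(sp, cl, "relative")$faa,
               compute_faa(sp_scaled, cl, "relative")$faa)
})

test_that("FAA recovers 2d from cluster amplitudes exp(+/- d/2)", {
  fs <- 250; n <- 2500; d <- 0.4
  labels <- c(cluster_spec()$left, cluster_spec()$right)
  t <- (0:(n - 1)) / fs
  samples <- matrix(0, 10, n)
  for (i in 1:5) samples[i, ] <- exp(-d / 2) * sin(2 * pi * 10 * t + i)
  for (i in 6:10) samples[i, ] <- exp(d / 2) * sin(2 * pi * 10 * t + i + 3)
  rec <- raw_recording(samples, labels, fs, "s1", "d1",
                       data.frame(condition = "A", start_sample = 0L,
                                  n_samples = n))
  eps <- epoch_recording(rec, 0.5)
  faa <- compute_faa(epoch_band_power(rec, eps), alpha_mode = "absolute")
  expect_equal(mean(faa$faa), 2 * d, tolerance = 0.02)
})
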