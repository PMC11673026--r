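test_that("ccc matches hand-computed values and scale limits", {
  expect_identical(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(ccc(c(1, 0, -1), c(-1, 0, 1)), -1)
  # cov = 2/3, var = 2/3 each, mean shift 1: 2*(2/3)/(2/3+2/3+1) = 4/7
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-15)
  # sample-moment variant weighs the mean-shift term differently
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4), moment = "sample"), 2 / 3,
               tolerance = 1e-15)
})

test_that("ccc agrees with a brute-force moment oracle on random pairs", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 5))
    y <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.1, 5))
    expect_equal(ccc(x, y), ccc_oracle(x, y), tolerance = 1e-12)
    expect_equal(ccc(x, y), ccc(y, x), tolerance = 1e-15)
    # Lin's inequality: concordance never exceeds Pearson correlation
    expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
})

test_that("ccc is penalized by location shifts, monotonically", {
  set.seed(1)
  x <- rnorm(30)
  shifts <- c(0.5, 1, 2, 4)
  vals <- vapply(shifts, function(c) ccc(x, x + c), numeric(1))
  expect_true(all(vals < 1))
  expect_true(all(diff(vals) < 0))
  expect_equal(ccc(x, x), 1)
})

test_that("ccc reports NA for degenerate input", {
  expect_true(is.na(ccc(c(1, 2), c(1, 2))))           # < 3 pairs
  expect_true(is.na(ccc(c(1, NA, 2, 3), c(1, 2, NA, 3))))
  expect_true(is.na(ccc(rep(1, 5), rep(1, 5))))       # zero denominator
})

make_faa <- function(values, valid = rep(TRUE, length(values)),
                     subject = "s1", cond = "A") {
  data.frame(subject_id = subject, dyad_id = "d1", condition = cond,
             epoch_index = seq_along(values) - 1L, faa = values,
             valid = valid, alpha_mode = "relative",
             stringsAsFactors = FALSE)
}

test_that("bin_faa bookkeeping: counts, partial validity, trailing epochs", {
  b240 <- bin_faa(make_faa(rnorm(240)))
  expect_identical(nrow(b240), 60L)
  b180 <- bin_faa(make_faa(rnorm(180)))
  expect_identical(nrow(b180), 45L)

  # bin value is the mean of its valid epochs; invalid only when all 4 are
  faa <- make_faa(c(0.1, 0.3, 0, 0, rep(0, 4)),
                  valid = c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 4)))
  b <- bin_faa(faa)
  expect_equal(b$faa_bin[1], 0.2)
  expect_true(b$valid[1])
  expect_false(b$valid[2])
  expect_identical(b$n_valid_epochs, c(2L, 0L))

  # 10 epochs -> 2 bins, trailing 2 epochs dropped
  expect_identical(nrow(bin_faa(make_faa(rnorm(10)))), 2L)
})

shifted_bins <- function(n = 30, shift = 2, seed = 5) {
  set.seed(seed)
  a <- rnorm(n + shift)
  b1 <- data.frame(subject_id = "p1", dyad_id = "d1", condition = "A",
                   bin_index = 0:(n - 1), faa_bin = a[(shift + 1):(n + shift)],
                   n_valid_epochs = 4L, valid = TRUE)
  # partner 2 follows partner 1 with a `shift`-bin delay
  b2 <- b1
  b2$subject_id <- "p2"
  b2$faa_bin <- a[1:n]
  list(p1 = b1, p2 = b2)
}

test_that("dyad_ccc lag convention: the follower peaks at the true delay", {
  b <- shifted_bins(shift = 2)
  cc <- dyad_ccc(b$p1, b$p2, lags = 0:3)
  # p2's series equals p1's two bins earlier, so p2 "predicted by partner's
  # previous values" is exact at lag 2
  p2 <- cc[cc$subject_id == "p2", ]
  expect_equal(p2$ccc[p2$lag_bins == 2], 1)
  expect_lt(p2$ccc[p2$lag_bins == 1], 1)
  expect_lt(p2$ccc[p2$lag_bins == 3], 1)
  # verify the alignment against a brute-force index oracle
  x <- b$p2$faa_bin; y <- b$p1$faa_bin; n <- length(x); k <- 2
  expect_equal(p2$ccc[p2$lag_bins == 2],
               ccc_oracle(x[(k + 1):n], y[(k + 1):n - k]))
  # lag 0 is identical for the two partners
  expect_equal(cc$ccc[cc$subject_id == "p1" & cc$lag_bins == 0],
               cc$ccc[cc$subject_id == "p2" & cc$lag_bins == 0])
})

test_that("dyad_ccc pair counts and missingness accounting", {
  b <- shifted_bins(n = 60)
  cc <- dyad_ccc(b$p1, b$p2, lags = 0:3)
  for (k in 0:3) {
    expect_true(all(cc$n_pairs[cc$lag_bins == k] == 60 - k))
  }
  # invalidate bins for one partner: jointly valid pairs shrink
  b$p2$faa_bin[1:10] <- NA
  b$p2$valid[1:10] <- FALSE
  cc2 <- dyad_ccc(b$p1, b$p2, lags = 0)
  expect_true(all(cc2$n_pairs == 50))
  # too few pairs is reported as missing with a reason
  b$p2$faa_bin[1:58] <- NA
  cc3 <- dyad_ccc(b$p1, b$p2, lags = 0)
  expect_true(all(is.na(cc3$ccc)))
  expect_match(cc3$reason[1], "fewer than 3")
})

test_that("aggregate_ccc: one dyad pools to the dyad's own value", {
  b <- shifted_bins(n = 40)
  pairs <- lagged_pairs(b$p1, b$p2, lags = 0:1)
  cc <- dyad_ccc(b$p1, b$p2, lags = 0:1)
  agg <- aggregate_ccc(pairs, cc)
  g0 <- agg$group[agg$group$lag_bins == 0, ]
  p0 <- pairs[pairs$lag_bins == 0, ]
  expect_equal(g0$ccc_pooled, ccc(p0$x, p0$y))
  expect_equal(g0$ccc_dyad_mean,
               mean(cc$ccc[cc$lag_bins == 0]))
})

test_that("descriptives table mirrors the condition-by-statistic layout", {
  set.seed(9)
  conds <- c("No Connection", "Gaze Only", "Hands Only", "Gaze and Hands",
             "Embrace")
  sub <- expand.grid(subject_id = paste0("s", 1:10), condition = conds,
                     lag_bins = 0:3, stringsAsFactors = FALSE)
  sub$dyad_id <- rep(paste0("d", 1:5), each = 2)
  sub$ccc <- rnorm(nrow(sub), 0, 0.1)
  pairs <- data.frame(condition = sub$condition, lag_bins = sub$lag_bins,
                      x = rnorm(nrow(sub)), y = rnorm(nrow(sub)))
  d <- aggregate_ccc(pairs, sub)$descriptives
  expect_identical(nrow(d), 5L)
  expect_true(all(c("mean", "sd", "min", "max", "skew", "kurtosis") %in% names(d)))
  # symmetric sample: skew near 0; raw kurtosis = excess + 3
  expect_lt(max(abs(d$skew)), 0.8)
  d_raw <- aggregate_ccc(pairs, sub, excess_kurtosis = FALSE)$descriptives
  expect_equal(d_raw$kurtosis, d$kurtosis + 3)
})
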