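# Model tests run on constructed epoch/CCC tables (no EEG synthesis), so
# parameter recovery is fast and the expected values are known exactly.

sim_faa_epochs <- function(n_subj = 6, n_ep = 120, cond_means = c(A = 0, B = 0.2),
                           slope = 0, sd = 0.3, seed = 1) {
  set.seed(seed)
  conds <- names(cond_means)
  g <- expand.grid(subject_id = paste0("s", seq_len(n_subj)),
                   condition = conds, epoch_index = 0:(n_ep - 1),
                   stringsAsFactors = FALSE)
  subj_int <- stats::setNames(rnorm(n_subj, 0, 0.1), paste0("s", seq_len(n_subj)))
  tt <- g$epoch_index / (n_ep - 1)
  g$faa <- cond_means[g$condition] + subj_int[g$subject_id] + slope * tt +
    rnorm(nrow(g), 0, sd)
  g$valid <- TRUE
  g$dyad_id <- rep(paste0("d", ceiling(seq_len(n_subj) / 2)),
                   length.out = nrow(g))
  g
}

test_that("the FAA model recovers condition means and uses residual df", {
  d <- sim_faa_epochs(cond_means = c(A = 0, B = 0.2), seed = 11)
  fm <- fit_faa_model(d)
  p_cond <- fm$f_table$p[fm$f_table$effect == "condition"]
  expect_lt(p_cond, 1e-6)
  emm <- fm$emm[order(fm$emm$condition), ]
  expect_lt(emm$emmean[emm$condition == "A"], emm$emmean[emm$condition == "B"])
  expect_equal(emm$emmean[emm$condition == "B"] -
                 emm$emmean[emm$condition == "A"], 0.2, tolerance = 0.05)
  # naive denominator df = n - rank(X): 1440 rows, 6 fixed coefficients
  expect_true(all(fm$f_table$df2 == nrow(d) - 6))
  # confidence bounds bracket the estimate
  expect_true(all(fm$emm$asymp.LCL <= fm$emm$emmean &
                  fm$emm$emmean <= fm$emm$asymp.UCL))
})

test_that("trend extraction reports per-increment slopes with coverage", {
  d <- sim_faa_epochs(slope = 0.4, cond_means = c(A = 0, B = 0), seed = 12)
  fm <- fit_faa_model(d, trend_every = 60)
  lin <- fm$trends[fm$trends$degree == "linear", ]
  expect_true(all(c(0, 60) %in% lin$epoch))
  # true slope on the scaled axis equals 0.4 (epoch_s has unit range)
  expect_equal(mean(lin$epoch_s.trend), 0.4, tolerance = 0.2)
  expect_true(all(lin$asymp.LCL < 0.4 & 0.4 < lin$asymp.UCL))

  # under a flat generator the slope CIs cover zero most of the time
  cover <- vapply(1:10, function(s) {
    d0 <- sim_faa_epochs(slope = 0, cond_means = c(A = 0, B = 0), seed = 100 + s)
    f0 <- suppressWarnings(fit_faa_model(d0, trend_every = 60))
    l0 <- f0$trends[f0$trends$degree == "linear", ]
    mean(l0$asymp.LCL <= 0 & 0 <= l0$asymp.UCL)
  }, numeric(1))
  expect_gte(mean(cover), 0.9)
})

test_that("a single-condition table degrades to a time-only model", {
  d <- sim_faa_epochs(cond_means = c(A = 0.1), seed = 13)
  fm <- suppressWarnings(fit_faa_model(d))
  expect_true(fm$one_condition)
  expect_false("condition" %in% fm$f_table$effect)
  expect_identical(nrow(fm$emm), 1L)
})

sim_ccc_subject <- function(n_subj = 20, conds = c("A", "B", "C"),
                            lag_effect = NULL, seed = 3) {
  set.seed(seed)
  g <- expand.grid(subject_id = paste0("s", seq_len(n_subj)),
                   condition = conds, lag_bins = 0:3,
                   stringsAsFactors = FALSE)
  g$dyad_id <- rep(paste0("d", ceiling(seq_len(n_subj) / 2)),
                   length.out = nrow(g))
  g$ccc <- rnorm(nrow(g), 0, 0.1)
  if (!is.null(lag_effect)) {
    sel <- g$condition == lag_effect$condition & g$lag_bins == lag_effect$lag
    g$ccc[sel] <- g$ccc[sel] + lag_effect$delta
  }
  g
}

test_that("the CCC model emits per-lag FDR contrasts of the right shape", {
  d <- sim_ccc_subject(lag_effect = list(condition = "B", lag = 2, delta = 0.25))
  cm <- fit_ccc_model(d)
  expect_setequal(cm$f_table$effect, c("condition", "lag", "condition:lag"))
  # C(3,2) = 3 pairwise condition contrasts within each of 4 lags
  expect_identical(nrow(cm$contrasts), 12L)
  # the injected condition difference shows up at lag 2 only
  at2 <- cm$contrasts[cm$contrasts$lag == "2" &
                      grepl("B", cm$contrasts$contrast), ]
  expect_true(all(at2$p.value < 0.01))
  elsewhere <- cm$contrasts[cm$contrasts$lag %in% c("0", "1"), ]
  expect_gt(min(elsewhere$p.value), 0.05)
  expect_true(all(cm$f_table$df2 == sum(!is.na(d$ccc)) - 12))
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    adj <- p.adjust(p, method = "BH")
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    # monotone nondecreasing in raw-p order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("individual-difference correlations recover a planted slope", {
  set.seed(21)
  n <- 30
  scores <- data.frame(subject_id = paste0("s", 1:n), value = rnorm(n))
  cov <- data.frame(subject_id = scores$subject_id,
                    planted = 2 * scores$value + rnorm(n, 0, 1),
                    noise1 = rnorm(n), noise2 = rnorm(n),
                    constant = 5)
  res <- correlate_individual_differences(scores, cov)
  expect_identical(res$df[res$variable == "planted"], 28L)   # n = 30
  expect_gt(res$r[res$variable == "planted"], 0.7)
  expect_lt(res$p_adj[res$variable == "planted"], 0.01)
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
  # zero-variance covariate is skipped with a reason
  expect_true(is.na(res$r[res$variable == "constant"]))
  expect_match(res$note[res$variable == "constant"], "zero variance")
})

test_that("winsorization tames a planted outlier", {
  set.seed(22)
  n <- 20
  x <- rnorm(n)
  scores <- data.frame(subject_id = paste0("s", 1:n), value = x)
  y <- rnorm(n, 0, 0.5)
  y[1] <- 30                       # outlier dominating the raw correlation
  x[1] <- 10
  scores$value <- x
  cov <- data.frame(subject_id = scores$subject_id, v = y)
  raw <- correlate_individual_differences(scores, cov)
  win <- correlate_individual_differences(scores, cov, winsorize_data = TRUE)
  expect_gt(raw$r[1], 0.8)         # driven by the outlier
  expect_lt(win$r[1], raw$r[1] - 0.2)   # tamed after 5%/95% limits
  expect_lt(win$r[1], 0.6)
  expect_true(win$winsorized[1])
  expect_identical(winsorize(c(0, 100, rep(1, 18)), c(0.05, 0.95))[2],
                   unname(quantile(c(0, 100, rep(1, 18)), 0.95)))
})
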