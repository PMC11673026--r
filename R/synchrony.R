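# Binning of FAA series and within-dyad concurrent/lagged concordance.

#' Average FAA epochs into non-overlapping bins
#'
#' Bins of `bin_epochs` contiguous epochs (2 s at the default 500 ms epoch);
#' the bin value is the mean of the bin's valid epochs, and a bin is invalid
#' only when data are missing across the full bin. Trailing epochs that do
#' not fill a bin are dropped. A full 2 min condition yields 60 bins, 1.5
#' min yields 45.
#'
#' @param faa A [compute_faa()] data frame (one or more subjects).
#' @param bin_epochs Epochs per bin.
#' @return Data frame: `subject_id`, `dyad_id`, `condition`, `bin_index`
#'   (0-based), `faa_bin`, `n_valid_epochs`, `valid`.
#' @export
bin_faa <- function(faa, bin_epochs = 4) {
  stopifnot(bin_epochs >= 1)
  split_by <- interaction(faa$subject_id, faa$condition, drop = TRUE)
  out <- lapply(split(faa, split_by), function(g) {
    g <- g[order(g$epoch_index), ]
    n_bin <- floor(nrow(g) / bin_epochs)
    if (n_bin == 0) return(NULL)
    idx <- rep(seq_len(n_bin) - 1L, each = bin_epochs)
    g <- g[seq_len(n_bin * bin_epochs), ]
    vals <- tapply(ifelse(g$valid, g$faa, NA_real_), idx,
                   function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    nval <- tapply(g$valid, idx, sum)
    data.frame(subject_id = g$subject_id[1], dyad_id = g$dyad_id[1],
               condition = g$condition[1], bin_index = seq_len(n_bin) - 1L,
               faa_bin = as.numeric(vals), n_valid_epochs = as.integer(nval),
               valid = !is.na(as.numeric(vals)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, bounded
#' in `[-1, 1]`; penalizes both decorrelation and location/scale shifts.
#' Population (1/n) moments by default; `moment = "sample"` uses 1/(n-1)
#' moments (the statistic differs only through the mean-shift term's
#' relative weight).
#'
#' Pairs with a missing member are dropped; fewer than 3 complete pairs, or
#' a zero denominator, yields `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param moment `"population"` or `"sample"`.
#' @return A single number in `[-1, 1]`, or `NA` when undefined.
#' @export
ccc <- function(x, y, moment = c("population", "sample")) {
  moment <- match.arg(moment)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  if (moment == "population") {
    sxy <- mean(x * y) - mx * my
    sx <- mean(x^2) - mx^2
    sy <- mean(y^2) - my^2
  } else {
    sxy <- stats::cov(x, y)
    sx <- stats::var(x)
    sy <- stats::var(y)
  }
  den <- sx + sy + (mx - my)^2
  if (den <= 0) return(NA_real_)
  2 * sxy / den
}

# Aligned (reference, partner) bin pairs for one dyad at the requested lags.
# Lag direction: the reference person's FAA at bin t is paired with the
# partner's FAA at bin t - k ("predicted by the partner's previous values").
# Only jointly valid pairs are returned.
lagged_pairs <- function(bins_p1, bins_p2, lags = 0:3) {
  stopifnot(all(lags >= 0))
  conds <- intersect(unique(bins_p1$condition), unique(bins_p2$condition))
  out <- list()
  for (cond in conds) {
    b1 <- bins_p1[bins_p1$condition == cond, ]
    b2 <- bins_p2[bins_p2$condition == cond, ]
    n <- min(nrow(b1), nrow(b2))
    if (n == 0) next
    v1 <- b1$faa_bin[seq_len(n)]; v2 <- b2$faa_bin[seq_len(n)]
    for (k in lags) {
      if (k >= n) next
      t <- (k + 1L):n
      add <- function(ref, par, rv, pv) {
        ok <- !is.na(rv[t]) & !is.na(pv[t - k])
        if (!any(ok)) return(NULL)
        data.frame(dyad_id = b1$dyad_id[1], subject_id = ref, partner_id = par,
                   condition = cond, lag_bins = k, bin_index = t[ok] - 1L,
                   x = rv[t][ok], y = pv[t - k][ok], stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- add(b1$subject_id[1], b2$subject_id[1], v1, v2)
      out[[length(out) + 1L]] <- add(b2$subject_id[1], b1$subject_id[1], v2, v1)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Within-dyad concordance at concurrent and lagged offsets
#'
#' For reference person A at lag k, the CCC is computed over pairs (A at bin
#' t, partner at bin t - k) across the bins where both are valid, per
#' condition. Both persons' perspectives are emitted; at lag 0 the two
#' perspectives have identical values by symmetry of the statistic.
#'
#' @param bins_p1,bins_p2 [bin_faa()] tables for the two partners.
#' @param lags Nonnegative integer lags in bins.
#' @param moment Passed to [ccc()].
#' @return Data frame: `dyad_id`, `subject_id` (reference person),
#'   `condition`, `lag_bins`, `ccc`, `n_pairs`, `reason` (why a value is
#'   missing, else `NA`).
#' @export
dyad_ccc <- function(bins_p1, bins_p2, lags = 0:3, moment = "population") {
  if (!identical(bins_p1$dyad_id[1], bins_p2$dyad_id[1])) {
    stop("dyad_ccc: the two bin series belong to different dyads")
  }
  pairs <- lagged_pairs(bins_p1, bins_p2, lags)
  conds <- intersect(unique(bins_p1$condition), unique(bins_p2$condition))
  subjects <- c(bins_p1$subject_id[1], bins_p2$subject_id[1])
  grid <- expand.grid(subject_id = subjects, condition = conds,
                      lag_bins = lags, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- pairs[pairs$subject_id == g$subject_id &
               pairs$condition == g$condition &
               pairs$lag_bins == g$lag_bins, ]
    n <- nrow(p)
    val <- if (n >= 3) ccc(p$x, p$y, moment) else NA_real_
    reason <- if (n < 3) "fewer than 3 jointly valid bin pairs"
              else if (is.na(val)) "zero denominator" else NA_character_
    data.frame(dyad_id = bins_p1$dyad_id[1], subject_id = g$subject_id,
               condition = g$condition, lag_bins = g$lag_bins,
               ccc = val, n_pairs = n, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$subject_id, out$condition, out$lag_bins), ]
}

#' Group- and subject-level concordance tables
#'
#' Group level: the CCC computed on bin pairs pooled across dyads per
#' condition and lag, each participant taken relative to their partner (the
#' per-dyad mean of subject CCCs is emitted alongside). Subject level: one
#' CCC per person, condition and lag. Descriptives (mean, SD, min, max,
#' skew, excess kurtosis) summarize the subject-level values per condition,
#' collapsed across persons and lags.
#'
#' @param pairs A [lagged_pairs()] table pooled over dyads (rbind).
#' @param subject_ccc A [dyad_ccc()] table pooled over dyads (rbind).
#' @param moment Passed to [ccc()].
#' @param excess_kurtosis If `TRUE` (default) kurtosis is excess (normal =
#'   0); if `FALSE`, raw (normal = 3).
#' @return List with data frames `group`, `subject`, `descriptives`.
#' @export
aggregate_ccc <- function(pairs, subject_ccc, moment = "population",
                          excess_kurtosis = TRUE) {
  grp_by <- interaction(pairs$condition, pairs$lag_bins, drop = TRUE)
  group <- do.call(rbind, lapply(split(pairs, grp_by), function(g) {
    dyad_means <- tapply(
      subject_ccc$ccc[subject_ccc$condition == g$condition[1] &
                      subject_ccc$lag_bins == g$lag_bins[1]],
      subject_ccc$dyad_id[subject_ccc$condition == g$condition[1] &
                          subject_ccc$lag_bins == g$lag_bins[1]],
      mean, na.rm = TRUE)
    data.frame(condition = g$condition[1], lag_bins = g$lag_bins[1],
               ccc_pooled = ccc(g$x, g$y, moment),
               ccc_dyad_mean = mean(dyad_means, na.rm = TRUE),
               n_pairs = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(group) <- NULL
  group <- group[order(group$condition, group$lag_bins), ]

  sub <- subject_ccc[!is.na(subject_ccc$ccc), ]
  descriptives <- do.call(rbind, lapply(split(sub, sub$condition), function(g) {
    data.frame(condition = g$condition[1], mean = mean(g$ccc),
               sd = stats::sd(g$ccc), min = min(g$ccc), max = max(g$ccc),
               skew = e1071::skewness(g$ccc, type = 1),
               kurtosis = e1071::kurtosis(g$ccc, type = 1) +
                 if (excess_kurtosis) 0 else 3,
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(descriptives) <- NULL
  list(group = group, subject = subject_ccc, descriptives = descriptives)
}
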