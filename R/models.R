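# Mixed-effects models on the pipeline outputs: FAA ~ condition x time with
# trend extraction, subject-level CCC ~ condition x lag with FDR-corrected
# contrasts, and individual-difference correlations.

# F table for a lmer fit. "naive" uses the residual-like denominator df
# (n - rank of the fixed-effects design), matching reports where df2 is on
# the order of the number of epochs; "satterthwaite" delegates to lmerTest.
fixed_f_table <- function(fit, ddf = c("naive", "satterthwaite")) {
  ddf <- match.arg(ddf)
  if (ddf == "satterthwaite") {
    a <- stats::anova(lmerTest::as_lmerModLmerTest(fit), ddf = "Satterthwaite")
    return(data.frame(effect = rownames(a), F = a$`F value`,
                      df1 = a$NumDF, df2 = a$DenDF, p = a$`Pr(>F)`,
                      stringsAsFactors = FALSE))
  }
  a <- stats::anova(fit)
  n <- nrow(stats::model.frame(fit))
  p_rank <- ncol(lme4::getME(fit, "X"))
  df2 <- n - p_rank
  data.frame(effect = rownames(a), F = a$`F value`, df1 = a$npar,
             df2 = df2, p = stats::pf(a$`F value`, a$npar, df2, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Mixed model of epoch-level FAA across condition and time
#'
#' REML linear mixed model (Nelder-Mead optimizer) of single-epoch FAA with
#' fixed effects of condition, time (linear and quadratic in the scaled
#' epoch index) and their interactions, and a random intercept per person.
#' Time is the epoch index scaled to `[-0.5, 0.5]` within each condition
#' (centered, unit range), which keeps the polynomial terms well
#' conditioned; the scaling is recorded in the result.
#'
#' @param faa_epochs A [compute_faa()]-style data frame pooled over
#'   subjects (`subject_id`, `condition`, `epoch_index`, `faa`, `valid`).
#' @param ddf Denominator-df method for the F table: `"naive"` residual df
#'   (default) or `"satterthwaite"`.
#' @param trend_every Epoch spacing of trend extraction (60 epochs = 30 s).
#' @return List of class `faa_model`: `fit`, `f_table`, `emm` (per-condition
#'   estimated marginal means with 95% CI), `trends` (linear slope, and the
#'   quadratic trend, at `trend_every`-epoch increments per condition, with
#'   CIs), `scaling`, `singular` flag.
#' @export
fit_faa_model <- function(faa_epochs, ddf = "naive", trend_every = 60) {
  d <- faa_epochs[faa_epochs$valid & !is.na(faa_epochs$faa), ]
  if (length(unique(d$subject_id)) < 2) stop("need at least 2 subjects")
  one_condition <- length(unique(d$condition)) < 2
  max_ep <- stats::ave(d$epoch_index, d$condition, FUN = max)
  d$epoch_s <- d$epoch_index / pmax(max_ep, 1) - 0.5
  d$condition <- factor(d$condition, levels = unique(faa_epochs$condition))

  form <- if (one_condition) {
    faa ~ epoch_s + I(epoch_s^2) + (1 | subject_id)
  } else {
    faa ~ condition * (epoch_s + I(epoch_s^2)) + (1 | subject_id)
  }
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(optimizer = "Nelder_Mead",
                                                calc.derivs = FALSE))
  singular <- lme4::isSingular(fit)
  if (singular) warning("random-intercept fit is singular; results flagged")

  ftab <- fixed_f_table(fit, ddf)
  spec <- if (one_condition) ~1 else ~condition
  emm <- as.data.frame(emmeans::emmeans(fit, spec, at = list(epoch_s = 0),
                                        lmer.df = "asymptotic"))
  # linear trend (d faa / d epoch_s, includes the quadratic contribution)
  # at trend_every-epoch increments, plus the quadratic trend per condition
  grid_ep <- seq(0, max(d$epoch_index), by = trend_every)
  grid_s <- sort(unique(grid_ep / max(d$epoch_index) - 0.5))
  spec_tr <- if (one_condition) ~epoch_s else ~condition | epoch_s
  tr <- emmeans::emtrends(fit, spec_tr, var = "epoch_s", max.degree = 2,
                          at = list(epoch_s = grid_s),
                          lmer.df = "asymptotic")
  trends <- as.data.frame(summary(tr, infer = c(TRUE, FALSE)))
  trends$epoch <- round((trends$epoch_s + 0.5) * max(d$epoch_index))
  structure(list(fit = fit, f_table = ftab, emm = emm, trends = trends,
                 scaling = "epoch_s = epoch_index / max(epoch_index per condition) - 0.5",
                 one_condition = one_condition, singular = singular,
                 ddf = ddf),
            class = "faa_model")
}

#' @export
print.faa_model <- function(x, ...) {
  cat("FAA mixed model (REML, Nelder-Mead; ddf =", x$ddf, ")\n\n")
  print(x$f_table, row.names = FALSE)
  cat("\nEstimated marginal means at mid-condition:\n")
  print(x$emm, row.names = FALSE)
  invisible(x)
}

#' Mixed model of subject-level CCC across condition and lag
#'
#' REML mixed model of each person's per-condition, per-lag concordance with
#' fixed effects of condition, lag (categorical) and their interaction, and
#' a random intercept per person; pairwise condition contrasts within each
#' lag are FDR-adjusted (Benjamini-Hochberg).
#'
#' @param ccc_subject A [dyad_ccc()]-style table pooled over dyads.
#' @param ddf Denominator-df method, as in [fit_faa_model()].
#' @return List of class `ccc_model`: `fit`, `f_table`, `emm`, `contrasts`.
#' @export
fit_ccc_model <- function(ccc_subject, ddf = "naive") {
  d <- ccc_subject[!is.na(ccc_subject$ccc), ]
  if (length(unique(d$condition)) < 2 || length(unique(d$lag_bins)) < 2) {
    stop("need subject-level CCCs for at least 2 conditions and 2 lags")
  }
  d$condition <- factor(d$condition, levels = unique(ccc_subject$condition))
  d$lag <- factor(d$lag_bins)
  fit <- lme4::lmer(ccc ~ condition * lag + (1 | subject_id), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(optimizer = "Nelder_Mead",
                                                calc.derivs = FALSE))
  ftab <- fixed_f_table(fit, ddf)
  emm <- emmeans::emmeans(fit, ~condition | lag, lmer.df = "asymptotic")
  contrasts <- as.data.frame(summary(emmeans::contrast(emm, "pairwise"),
                                     adjust = "fdr"))
  structure(list(fit = fit, f_table = ftab,
                 emm = as.data.frame(emm), contrasts = contrasts, ddf = ddf),
            class = "ccc_model")
}

#' @export
print.ccc_model <- function(x, ...) {
  cat("CCC mixed model (REML, Nelder-Mead; ddf =", x$ddf, ")\n\n")
  print(x$f_table, row.names = FALSE)
  invisible(x)
}

#' Winsorize a numeric vector at quantile limits
#'
#' @param x Numeric vector.
#' @param probs Lower/upper quantile limits (default 5th/95th percentile).
#' @return `x` with values outside the limits replaced by the limits.
#' @export
winsorize <- function(x, probs = c(0.05, 0.95)) {
  q <- stats::quantile(x, probs, na.rm = TRUE, names = FALSE)
  pmin(pmax(x, q[1]), q[2])
}

#' Correlate a per-subject summary with individual differences
#'
#' Pearson correlation of a per-subject biological summary (e.g., mean FAA,
#' or the lag-2 CCC, in a chosen condition) with each covariate column, with
#' Benjamini-Hochberg adjustment across the covariate family and optional
#' winsorization of both variables before correlating.
#'
#' @param scores Data frame with `subject_id` and `value`.
#' @param covariates Data frame with `subject_id` and numeric covariate
#'   columns (other non-numeric columns are ignored).
#' @param winsorize_data Winsorize both members of each pair first?
#' @param probs Winsorization limits.
#' @return Data frame: `variable`, `r`, `n`, `df`, `p`, `p_adj`,
#'   `winsorized`, `note` (reason a variable was skipped, else `NA`).
#' @export
correlate_individual_differences <- function(scores, covariates,
                                             winsorize_data = FALSE,
                                             probs = c(0.05, 0.95)) {
  stopifnot(all(c("subject_id", "value") %in% names(scores)))
  m <- merge(scores, covariates, by = "subject_id")
  vars <- setdiff(names(covariates), c("subject_id", "dyad_id"))
  vars <- vars[vapply(m[vars], is.numeric, logical(1))]
  rows <- lapply(vars, function(v) {
    ok <- stats::complete.cases(m$value, m[[v]])
    x <- m$value[ok]; y <- m[[v]][ok]
    if (winsorize_data) { x <- winsorize(x, probs); y <- winsorize(y, probs) }
    if (length(x) < 3 || stats::sd(y) == 0 || stats::sd(x) == 0) {
      return(data.frame(variable = v, r = NA_real_, n = length(x),
                        df = NA_integer_, p = NA_real_,
                        note = "zero variance or fewer than 3 pairs",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(variable = v, r = unname(ct$estimate), n = length(x),
               df = unname(ct$parameter), p = ct$p.value, note = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p)
  out$p_adj[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out$winsorized <- winsorize_data
  out[, c("variable", "r", "n", "df", "p", "p_adj", "winsorized", "note")]
}
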