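#' Pipeline configuration
#'
#' All tunable parameters of the analysis chain, with the conventional
#' defaults: 0.1-40 Hz bandpass, 0.9 channel-rejection threshold, 20-40 Hz /
#' 10 dB segment rejection, 500 ms epochs, alpha band 8-12 Hz with relative
#' power over 1-40 Hz, 4-epoch (2 s) bins, lags 0-3 bins, population-moment
#' CCC, Benjamini-Hochberg FDR.
#'
#' @param band_hz Bandpass edges (Hz).
#' @param alpha_band_hz Alpha band (Hz).
#' @param total_band_hz Denominator band for relative alpha (Hz).
#' @param grid_hz Periodogram frequency-grid spacing (Hz).
#' @param epoch_s Epoch length (s); `epoch_s * sampling rate` must be whole.
#' @param bin_epochs Epochs per bin.
#' @param lags Integer lags in bins.
#' @param channel_reject_threshold Correlation threshold of
#'   [reject_channels()].
#' @param neighbor_k Neighbors for channel prediction and interpolation.
#' @param artifact_band_hz,artifact_threshold_db Segment-rejection band and
#'   threshold.
#' @param segment_scope `"condition"` or `"recording"` (where the rejection
#'   median is computed).
#' @param alpha_mode `"relative"` or `"absolute"`.
#' @param clusters A [cluster_spec()].
#' @param moment `"population"` or `"sample"` CCC moments.
#' @param ddf Denominator-df method for model F tables.
#' @param winsorize_data Winsorize in individual-difference correlations?
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(band_hz = c(0.1, 40),
                            alpha_band_hz = c(8, 12),
                            total_band_hz = c(1, 40),
                            grid_hz = 0.5,
                            epoch_s = 0.5,
                            bin_epochs = 4,
                            lags = 0:3,
                            channel_reject_threshold = 0.9,
                            neighbor_k = 6,
                            artifact_band_hz = c(20, 40),
                            artifact_threshold_db = 10,
                            segment_scope = "condition",
                            alpha_mode = "relative",
                            clusters = cluster_spec(),
                            moment = "population",
                            ddf = "naive",
                            winsorize_data = FALSE) {
  stopifnot(bin_epochs >= 1, all(lags >= 0),
            channel_reject_threshold > 0, channel_reject_threshold <= 1)
  structure(list(band_hz = band_hz, alpha_band_hz = alpha_band_hz,
                 total_band_hz = total_band_hz, grid_hz = grid_hz,
                 epoch_s = epoch_s, bin_epochs = bin_epochs, lags = lags,
                 channel_reject_threshold = channel_reject_threshold,
                 neighbor_k = neighbor_k, artifact_band_hz = artifact_band_hz,
                 artifact_threshold_db = artifact_threshold_db,
                 segment_scope = segment_scope, alpha_mode = alpha_mode,
                 clusters = clusters, moment = moment, ddf = ddf,
                 winsorize_data = winsorize_data),
            class = "pipeline_config")
}

#' Run the full dyadic analysis pipeline
#'
#' preprocess -> epoch/alpha power -> FAA -> 2 s bins -> within-dyad
#' concurrent and lagged CCC -> group/subject tables. Conditions present for
#' only one partner of a dyad are skipped for that dyad with a warning.
#' Deterministic: the pipeline itself draws no random numbers.
#'
#' @param dyads A list whose elements are either [generate_dyad()] results
#'   or lists with components `p1` and `p2` ([raw_recording()]s of the two
#'   partners).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, tidy CSVs (`faa_epochs`,
#'   `faa_bins`, `ccc_subject`, `ccc_group`, `ccc_descriptives`, `qc`) and a
#'   plain-text run log are written there.
#' @return List of class `dyadsync_result` with data frames `faa_epochs`,
#'   `faa_bins`, `pairs`, `ccc_subject`, `ccc_group`, `ccc_descriptives`,
#'   `qc`.
#' @export
run_pipeline <- function(dyads, config = pipeline_config(), out_dir = NULL) {
  if (inherits(dyads, "synth_dyad")) dyads <- list(dyads)
  faa_all <- list(); bins_all <- list(); pairs_all <- list()
  ccc_all <- list(); qc_all <- list()

  for (dy in dyads) {
    recs <- list(p1 = dy$p1, p2 = dy$p2)
    common <- intersect(recs$p1$schedule$condition, recs$p2$schedule$condition)
    for (nm in names(recs)) {
      extra <- setdiff(recs[[nm]]$schedule$condition, common)
      if (length(extra) > 0) {
        warning("dyad ", recs[[nm]]$dyad_id, ": partner ", nm,
                " condition(s) ", paste(extra, collapse = ", "),
                " missing for the other partner; skipped")
        recs[[nm]]$schedule <-
          recs[[nm]]$schedule[recs[[nm]]$schedule$condition %in% common, ]
      }
    }
    bins <- list()
    for (nm in names(recs)) {
      pp <- preprocess(recs[[nm]], config)
      faa <- faa_series(pp$recording, config)
      b <- bin_faa(faa, config$bin_epochs)
      faa_all[[length(faa_all) + 1L]] <- faa
      bins_all[[length(bins_all) + 1L]] <- b
      qc_all[[length(qc_all) + 1L]] <- pp$qc
      bins[[nm]] <- b
    }
    pairs_all[[length(pairs_all) + 1L]] <-
      lagged_pairs(bins$p1, bins$p2, config$lags)
    ccc_all[[length(ccc_all) + 1L]] <-
      dyad_ccc(bins$p1, bins$p2, config$lags, config$moment)
  }

  pairs <- do.call(rbind, pairs_all)
  ccc_subject <- do.call(rbind, ccc_all)
  agg <- aggregate_ccc(pairs, ccc_subject, config$moment)
  res <- structure(list(faa_epochs = do.call(rbind, faa_all),
                        faa_bins = do.call(rbind, bins_all),
                        pairs = pairs, ccc_subject = ccc_subject,
                        ccc_group = agg$group,
                        ccc_descriptives = agg$descriptives,
                        qc = do.call(rbind, qc_all),
                        config = config),
                   class = "dyadsync_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.dyadsync_result <- function(x, ...) {
  cat(sprintf("<dyadsync_result> %d subjects, %d conditions, lags %s\n",
              length(unique(x$faa_epochs$subject_id)),
              length(unique(x$faa_epochs$condition)),
              paste(range(x$ccc_subject$lag_bins), collapse = "-")))
  cat("\nGroup-level CCC (pooled):\n")
  print(utils::head(x$ccc_group, 12), row.names = FALSE)
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("faa_epochs", "faa_bins", "ccc_subject", "ccc_group",
            "ccc_descriptives", "qc")
  for (nm in tabs) {
    utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  cfg <- res$config
  cfg$clusters <- unclass(cfg$clusters)
  log_lines <- c("dyadsync run log",
                 paste0("records: ", paste(vapply(tabs, function(nm)
                   sprintf("%s=%d", nm, nrow(res[[nm]])), ""), collapse = " ")),
                 "config:",
                 vapply(names(cfg), function(k)
                   sprintf("  %s: %s", k, paste(format(unlist(cfg[[k]])),
                                                collapse = " ")), ""))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
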