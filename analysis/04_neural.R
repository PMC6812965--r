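#!/usr/bin/env Rscript

# Step 4 -- feedback-locked signal analyses on synthetic epochs.
#
# Simulates an EEG-style cohort (three opponent rates, 25/50/75%), embeds
# context information that is attenuated 400 ms after losses, and runs the
# two-step analysis: per-time-point multilevel context regressions, the
# 300-700 ms window PPI predicting upcoming choices, and the
# individual-difference correlations.

suppressPackageStartupMessages(library(foxrabbit))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 1)
dir.create("results", showWarnings = FALSE)

cfg <- session_config(opponent_rates = rep(c(0.25, 0.5, 0.75), 4))
cohort <- simulate_cohort(12, cfg, seed = seed + 10L)
epochs <- simulate_cohort_epochs(cohort, signal_spec(noise_sd = 3),
                                 seed = seed + 11L)

tc <- timepoint_context_regression(epochs)
utils::write.csv(tc, "results/coefficient_timecourses.csv", row.names = FALSE)
lossA <- tc[tc$predictor == "A" & tc$wl == -1, ]
late <- mean(abs(lossA$beta[lossA$time_ms >= 700]))
early <- mean(abs(lossA$beta[lossA$time_ms >= 250 & lossA$time_ms < 400]))
cat(sprintf("post-loss opponent-rate information: |beta| %.3f early vs %.3f late (%.0f%% attenuated)\n",
            early, late, 100 * (1 - late / early)))

ppi <- ppi_analysis(epochs)
utils::write.csv(ppi, "results/ppi_table.csv", row.names = FALSE)
cat("PPI coefficients (post-win):\n")
print(ppi[ppi$wl == 1, ], digits = 3)

sc <- subject_window_coefficients(epochs)
rs <- reversed_label_slopes(cohort$trials)
wr <- data.frame(subject_id = cohort$subjects$subject_id,
                 win_rate = tapply(cohort$trials$outcome == "win",
                                   cohort$trials$subject_id, mean))
idc <- suppressWarnings(
  individual_difference_correlations(sc, rs$subject_slopes, wr))
utils::write.csv(idc$correlations, "results/individual_correlations.csv",
                 row.names = FALSE)
utils::write.csv(idc$contrasts, "results/individual_contrasts.csv",
                 row.names = FALSE)
cat("individual-difference correlations written (",
    nrow(idc$correlations), "cells )\n")
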