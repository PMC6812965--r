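#!/usr/bin/env Rscript

# Step 2 -- fit the four-parameter choice model.
#
# Fits (a) the group-average condition grid (least squares, with
# residual-bootstrap intervals), (b) each player's own condition grid, and
# (c) each dyad player's trial-by-trial choices using the running estimate
# of the partner's switch rate. Requires step 1's outputs.

suppressPackageStartupMessages(library(foxrabbit))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 1)

trials <- read_trial_log("results/cohort_trials.csv")
grid <- condition_switch_rates(trials)
utils::write.csv(grid, "results/condition_grid.csv", row.names = FALSE)

gf <- fit_condition_averages(grid, seed = seed)
write_fit_result(gf, "results/group_fit.csv")
cat("group-average fit:\n"); print(gf)

fits <- suppressWarnings(fit_cohort(trials))
utils::write.csv(fits, "results/subject_fits.csv", row.names = FALSE)
cat(sprintf("per-player fits: mean ms %.3f, mean sm %.3f (n = %d)\n",
            mean(fits$ms), mean(fits$sm), nrow(fits)))

dyad_trials <- read_trial_log("results/dyad_trials.csv")
dfits <- suppressWarnings(fit_cohort(dyad_trials, method = "trialwise",
                                     p_os = "running"))
utils::write.csv(dfits, "results/dyad_fits.csv", row.names = FALSE)
cat(sprintf("dyad trial-by-trial fits: mean ms %.3f, mean sm %.3f (n = %d)\n",
            mean(dfits$ms), mean(dfits$sm), nrow(dfits)))
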