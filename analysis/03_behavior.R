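#!/usr/bin/env Rscript

# Step 3 -- behavioural analyses.
#
# Reversed-label slope contrast (the core feedback-contingent suppression
# test), the 15-predictor multilevel choice-history regression, the
# stochasticity-vs-noise control, and the parameter -> success regression.
# Requires steps 1-2.

suppressPackageStartupMessages(library(foxrabbit))

trials <- read_trial_log("results/cohort_trials.csv")

rs <- reversed_label_slopes(trials)
utils::write.csv(rs$subject_slopes, "results/subject_slopes.csv",
                 row.names = FALSE)
utils::write.csv(rs$group, "results/group_slopes.csv", row.names = FALSE)
cat(sprintf("post-win slope %.3f, post-loss (reversed) %.3f; interaction t = %.2f (df ~ %d)\n",
            rs$group$slope[rs$group$wl == 1],
            rs$group$slope[rs$group$wl == -1],
            rs$interaction$t, rs$interaction$df))

hr <- history_regression(trials[trials$subject_id <= 16, ])
utils::write.csv(hr$coefficients, "results/history_coefficients.csv",
                 row.names = FALSE)
cat(sprintf("history regression on %d trials (%d excluded; random effects: %s)\n",
            hr$n_rows, hr$n_excluded, hr$ranef_structure))
inter <- hr$coefficients[hr$coefficients$term %in% c("wl:rate", "rate:wl"), ]
cat(sprintf("win/loss x opponent-rate interaction: z = %.2f\n", inter$z))

sv <- stochasticity_vs_noise(trials)
utils::write.csv(sv$coefficients, "results/stochasticity_controls.csv",
                 row.names = FALSE)
cat(sprintf("win/loss slope contrast after RT and error controls: t = %.2f\n",
            sv$coefficients$t[sv$coefficients$term == "wl"]))

fits <- utils::read.csv("results/subject_fits.csv")
dfits <- utils::read.csv("results/dyad_fits.csv")
pool <- rbind(cbind(fits[c("ms", "sm", "pe", "ss", "win_rate")], group = 1),
              cbind(dfits[c("ms", "sm", "pe", "ss", "win_rate")], group = 2))
sr <- success_regression(pool)
utils::write.csv(sr$coefficients, "results/success_regression.csv",
                 row.names = FALSE)
cat("success regression (win rate on ms, sm, |pe|, |ss|):\n")
print(sr$coefficients, digits = 3)
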