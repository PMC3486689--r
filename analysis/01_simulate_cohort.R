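#!/usr/bin/env Rscript
# Simulate the study cohort: 7 synthetic subjects following the
# Bayes-factor strategy through both 500-trial parts (100 standard-only
# training trials, then probe trials interleaved at 0.45 after standards).
# Writes the combined trial log for the downstream stages.

suppressPackageStartupMessages(library(shiftselect))
seed <- 17
dir.create("results", showWarnings = FALSE)

cond1 <- part1_condition()
cond2 <- part2_condition()
cohort <- simulate_cohort(cond1, cond2, n_subjects = 7,
                          strategy = "bayes_factor", seed = seed)
write_trial_log(cohort, "results/trials.csv")

n_probe <- sum(cohort$trial_type == "probe")
cat(sprintf("Simulated %d subjects, %d trials (%d probe trials, %.1f%%).\n",
            length(unique(cohort$subject_id)), nrow(cohort), n_probe,
            100 * n_probe / nrow(cohort)))
cat(sprintf("Standard-trial accuracy: %.1f%% (choices against the true model).\n",
            100 * mean(cohort$correct[cohort$trial_type == "standard"])))
cat("Trial log written to results/trials.csv\n")
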