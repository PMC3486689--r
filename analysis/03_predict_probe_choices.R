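#!/usr/bin/env Rscript
# Build each explanation's probe-choice predictions next to the cohort's
# empirical choice probabilities: the Bayes-factor observer (alpha = 1,
# subject-independent), Bayesian policy inference over the fitted curves,
# and the average / biggest / halfway shift heuristics.

suppressPackageStartupMessages(library(shiftselect))
trials <- read_trial_log("results/trials.csv")
cond <- list(part1_condition(), part2_condition())

emp <- empirical_probe_probs(trials)
rows <- list()
for (i in seq_len(nrow(emp))) {
  s <- emp$subject_id[i]; part <- emp$part[i]; w <- emp$width[i]
  tr <- trials[trials$subject_id == s & trials$part == part, ]
  curve <- fit_response_curve(bin_standard_trials(tr, standard_bin_edges(part)),
                              if (part == 1) "sigmoid" else "two_part_sigmoid")
  rows[[i]] <- data.frame(
    subject_id = s, part = part, width = w,
    empirical = emp$p_hat[i], n = emp$n[i],
    bayes_factor = predict_probe_choice_bayes(cond[[part]], w),
    policy_inference = predict_probe_choice_policy(cond[[part]], curve, w),
    average = predict_probe_choice_heuristic(curve, "average", w),
    biggest = predict_probe_choice_heuristic(curve, "biggest", w),
    halfway = predict_probe_choice_heuristic(curve, "halfway", w))
}
pred <- do.call(rbind, rows)
write.csv(pred, "results/predictions.csv", row.names = FALSE)

pooled <- aggregate(cbind(empirical, bayes_factor, policy_inference, average,
                          biggest, halfway) ~ part + width, pred, mean)
cat("Mean choice probabilities for M1 across subjects:\n")
print(pooled, digits = 3)
cat("Per-cell table -> results/predictions.csv\n")
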