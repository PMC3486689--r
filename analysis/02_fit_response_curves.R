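#!/usr/bin/env Rscript
# Fit each subject's standard-trial response curves: a sigmoid over shift
# magnitude for part 1 (bins [0,1]..[4,5] cm) and a two-partite sigmoid for
# part 2 (bins [0,2]..[8,10] cm), by least squares on the binned relative
# frequencies of choosing M1.

suppressPackageStartupMessages(library(shiftselect))
trials <- read_trial_log("results/trials.csv")

curves <- list()
for (s in unique(trials$subject_id)) {
  fits <- list()
  for (part in 1:2) {
    tr <- trials[trials$subject_id == s & trials$part == part, ]
    b <- bin_standard_trials(tr, standard_bin_edges(part))
    fit <- fit_response_curve(b, if (part == 1) "sigmoid" else "two_part_sigmoid")
    fits[[paste0("part", part)]] <-
      list(family = fit$family, params = as.list(fit$params), sse = fit$sse,
           degenerate = fit$degenerate,
           bins = data.frame(lo = b$edges[-length(b$edges)], hi = b$edges[-1],
                             n_m1 = b$n_m1, n = b$n_total, freq = b$freq))
    cat(sprintf("%s part %d: %s, sse = %.4f\n", s, part, fit$family, fit$sse))
  }
  curves[[s]] <- fits
}
jsonlite::write_json(curves, "results/curves.json", auto_unbox = TRUE,
                     digits = NA, dataframe = "columns")
cat("Fitted curves for", length(curves), "subjects -> results/curves.json\n")
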