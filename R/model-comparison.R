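# Confront the five explanations' probe predictions with trial data:
# empirical choice probabilities, negative log-likelihoods, ranking, and the
# exact significance tests used on the probe-trial tables.

explanation_names <- c("bayes_factor", "policy_inference",
                       "average", "biggest", "halfway")

#' Empirical probe-trial choice probabilities
#'
#' Counts of M1 choices and trials per (subject, part, width), with the
#' relative frequency `p_hat`. Cells with no trials are simply absent.
#'
#' @param trials A trial-log data frame containing probe trials.
#' @return A data frame with columns `subject_id`, `part`, `width`, `n_m1`,
#'   `n`, `p_hat`.
#' @export
empirical_probe_probs <- function(trials) {
  pr <- trials[trials$trial_type == "probe", , drop = FALSE]
  if (nrow(pr) == 0) stop("no probe trials in the log")
  agg <- stats::aggregate(cbind(n_m1 = pr$choice == "M1", n = rep(1, nrow(pr))),
                          by = list(subject_id = pr$subject_id, part = pr$part,
                                    width = pr$array_width_cm),
                          FUN = sum)
  agg$p_hat <- agg$n_m1 / agg$n
  agg[order(agg$subject_id, agg$part, agg$width), , drop = FALSE]
}

#' Negative log-likelihood of probe choices under a prediction table
#'
#' \eqn{-\sum \log p} over probe trials, where `p` is the predicted
#' probability of the realized choice. Predictions are clipped to
#' `[1e-6, 1 - 1e-6]` (with a warning when clipping bites) so the NLL stays
#' finite under degenerate predictions.
#'
#' @param predictions Data frame with columns `subject_id`, `part`, `width`,
#'   `p` (predicted probability of choosing M1); one row per realized cell.
#' @param trials A trial-log data frame.
#' @return Total negative log-likelihood (nats).
#' @export
probe_nll <- function(predictions, trials) {
  pr <- trials[trials$trial_type == "probe", , drop = FALSE]
  if (nrow(pr) == 0) stop("no probe trials in the log")
  key <- function(s, pt, w) paste(s, pt, w, sep = "|")
  p <- predictions$p[match(key(pr$subject_id, pr$part, pr$array_width_cm),
                           key(predictions$subject_id, predictions$part,
                               predictions$width))]
  if (any(is.na(p)))
    stop("missing prediction for cell ",
         key(pr$subject_id, pr$part, pr$array_width_cm)[which(is.na(p))[1]])
  eps <- 1e-6
  if (any(p < eps | p > 1 - eps))
    warning("predictions clipped to [1e-6, 1 - 1e-6] for the NLL")
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(ifelse(pr$choice == "M1", log(p), log1p(-p)))
}

# prediction table for one explanation across subjects/parts/widths
prediction_table <- function(explanation, cells, curves, cond1, cond2,
                             alpha = 1, grid = shift_grid()) {
  p <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cond <- if (cells$part[i] == 1) cond1 else cond2
    curve <- curves[[cells$subject_id[i]]][[paste0("part", cells$part[i])]]
    p[i] <- strategy_probe_prob(explanation, cond, curve, cells$width[i],
                                alpha, grid)
  }
  cbind(cells, p = p)
}

#' Five-way model comparison on a trial log
#'
#' For each subject, fits the part-1 sigmoid and part-2 two-partite response
#' curves from the standard trials, builds each explanation's probe
#' prediction table (the Bayes-factor observer is subject-independent with
#' softmax `alpha`; policy inference and the three heuristics use the
#' subject's fitted curves), and scores every explanation by the total
#' negative log-likelihood of the observed probe choices. Lower is better.
#' No complexity penalty is applied: none of the explanations carries
#' per-subject free parameters beyond the shared fitted curves.
#'
#' @param trials A trial-log data frame with both parts' standard and probe
#'   trials.
#' @param cond1,cond2 [task_condition()]s for parts 1 and 2.
#' @param alpha Softmax inverse temperature of the Bayes-factor observer.
#' @param grid A [shift_grid()].
#' @return An object of class `comparison_result`: `total_nll` (named,
#'   sorted ascending), `per_subject_nll` (matrix explanation x subject),
#'   `ranking`, `n_probe_trials`, `curves`, `excluded`.
#' @export
compare_explanations <- function(trials, cond1 = part1_condition(),
                                 cond2 = part2_condition(), alpha = 1,
                                 grid = shift_grid()) {
  subjects <- unique(trials$subject_id)
  curves <- list()
  excluded <- character()
  for (s in subjects) {
    fit <- tryCatch({
      t1 <- trials[trials$subject_id == s & trials$part == 1, ]
      t2 <- trials[trials$subject_id == s & trials$part == 2, ]
      list(part1 = fit_response_curve(bin_standard_trials(t1, standard_bin_edges(1)),
                                      "sigmoid"),
           part2 = fit_response_curve(bin_standard_trials(t2, standard_bin_edges(2)),
                                      "two_part_sigmoid"))
    }, error = function(e) {
      warning("subject ", s, " excluded: ", conditionMessage(e))
      NULL
    })
    if (is.null(fit)) excluded <- c(excluded, s) else curves[[s]] <- fit
  }
  keep <- trials$subject_id %in% names(curves)
  trials <- trials[keep, , drop = FALSE]
  if (length(curves) == 0) stop("curve fitting failed for every subject")

  emp <- empirical_probe_probs(trials)
  cells <- emp[, c("subject_id", "part", "width")]

  per_subj <- matrix(NA_real_, nrow = length(explanation_names),
                     ncol = length(curves),
                     dimnames = list(explanation_names, names(curves)))
  for (expl in explanation_names) {
    tab <- prediction_table(expl, cells, curves, cond1, cond2, alpha, grid)
    for (s in names(curves))
      per_subj[expl, s] <- probe_nll(tab[tab$subject_id == s, , drop = FALSE],
                                     trials[trials$subject_id == s, ,
                                            drop = FALSE])
  }
  total <- rowSums(per_subj)
  structure(list(total_nll = sort(total),
                 per_subject_nll = per_subj,
                 ranking = names(sort(total)),
                 n_probe_trials = sum(trials$trial_type == "probe"),
                 curves = curves, excluded = excluded, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Model comparison over %d probe trials, %d subject(s)%s\n",
              x$n_probe_trials, ncol(x$per_subject_nll),
              if (length(x$excluded))
                paste0(" (", length(x$excluded), " excluded)") else ""))
  cat("Negative log-likelihood by explanation (lower is better):\n")
  for (i in seq_along(x$total_nll))
    cat(sprintf("  %d. %-17s %10.1f\n", i, names(x$total_nll)[i],
                x$total_nll[i]))
  invisible(x)
}

#' Exact test of width-choice association for one subject and part
#'
#' Fisher's exact test (Freeman-Halton extension for the 2 x k table) of
#' independence between probe choice and array width. Degenerate tables with
#' a zero margin return p = 1 with a `degenerate` attribute.
#'
#' @param trials A trial-log data frame.
#' @param subject Subject id.
#' @param part Experiment part (1 or 2).
#' @return p-value in (0, 1], with attribute `degenerate`.
#' @export
width_choice_association <- function(trials, subject, part) {
  pr <- trials[trials$trial_type == "probe" & trials$subject_id == subject &
                 trials$part == part, , drop = FALSE]
  if (nrow(pr) == 0 || length(unique(pr$array_width_cm)) < 2)
    stop("need probe trials across at least two widths")
  tab <- table(factor(pr$choice, levels = c("M1", "M2")), pr$array_width_cm)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(structure(1, degenerate = TRUE))
  # generous workspace: the network algorithm can exhaust its default on
  # 2 x 3 tables with a few hundred trials
  structure(stats::fisher.test(tab, workspace = 2e7)$p.value,
            degenerate = FALSE)
}

#' Rank-sum comparison of the two parts' choice probabilities
#'
#' Two-sided Wilcoxon rank-sum test comparing the per-subject empirical
#' probabilities of choosing M1 between parts 1 and 2 at a given width.
#'
#' @param table An [empirical_probe_probs()] result covering both parts.
#' @param width Array width (cm) to compare at.
#' @return p-value.
#' @export
part_comparison_test <- function(table, width) {
  x <- table$p_hat[table$part == 1 & table$width == width]
  y <- table$p_hat[table$part == 2 & table$width == width]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 subjects per part at width ", width)
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))$p.value
}
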