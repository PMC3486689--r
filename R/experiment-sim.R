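# Synthetic-subject simulator: trial schedule, standard-trial choices from a
# softmax over the exact-shift model posterior, and probe-trial choices
# generated by any of the five candidate strategies.

subject_strategies <- c("bayes_factor", "policy_inference",
                        "average", "biggest", "halfway")

#' Trial-schedule configuration
#'
#' Each experiment part comprises `n_per_part` trials; the first `n_training`
#' are standard trials only, after which probe trials are interleaved by a
#' Markov rule: a probe follows a standard trial with probability
#' `p_probe_after_standard` and follows a probe trial with probability
#' `p_probe_after_probe` (0 by default, so probes never repeat).
#'
#' @param n_per_part Trials per part. Default 500.
#' @param n_training Leading standard-only trials. Default 100.
#' @param p_probe_after_standard Probe probability after a standard trial.
#'   Default 0.45.
#' @param p_probe_after_probe Probe probability after a probe trial.
#'   Default 0.
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(n_per_part = 500, n_training = 100,
                            p_probe_after_standard = 0.45,
                            p_probe_after_probe = 0) {
  if (n_per_part < 1 || n_training < 0 || n_training > n_per_part)
    stop("need 0 <= n_training <= n_per_part and n_per_part >= 1")
  for (p in c(p_probe_after_standard, p_probe_after_probe))
    if (length(p) != 1 || !is.finite(p) || p < 0 || p > 1)
      stop("schedule probabilities must lie in [0, 1]")
  structure(list(n_per_part = as.integer(n_per_part),
                 n_training = as.integer(n_training),
                 p_probe_after_standard = p_probe_after_standard,
                 p_probe_after_probe = p_probe_after_probe),
            class = "schedule_config")
}

#' Synthetic-subject specification
#'
#' Describes how one synthetic subject behaves. Standard-trial choices come
#' from a softmax over the exact-shift model posterior \eqn{P(M|s)} with
#' inverse temperature `standard_beta` (1 = probability matching). Probe
#' choices follow the named `strategy` — one of the five candidate
#' explanations used as a generator. Strategies other than `bayes_factor`
#' require `generating_curves`, a list with elements `part1` and `part2`
#' holding [response_curve()] objects (see [canonical_response_curves()]).
#' Every choice is replaced by a fair coin with probability `lapse`.
#'
#' @param id Subject identifier.
#' @param strategy One of `"bayes_factor"`, `"policy_inference"`,
#'   `"average"`, `"biggest"`, `"halfway"`.
#' @param alpha Softmax inverse temperature for the Bayes-factor strategy.
#'   Default 1.
#' @param standard_beta Standard-trial decision noise (inverse temperature).
#'   Default 1.
#' @param lapse Lapse rate in `[0, 0.5)`. Default 0.02.
#' @param generating_curves Optional `list(part1 =, part2 =)` of
#'   [response_curve()]s.
#' @param seed Integer seed governing all of the subject's randomness.
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(id, strategy = subject_strategies, alpha = 1,
                         standard_beta = 1, lapse = 0.02,
                         generating_curves = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  if (length(lapse) != 1 || !is.finite(lapse) || lapse < 0 || lapse >= 0.5)
    stop("lapse must lie in [0, 0.5)")
  if (alpha < 0 || standard_beta < 0)
    stop("alpha and standard_beta must be nonnegative")
  if (strategy != "bayes_factor" && is.null(generating_curves))
    stop("strategy '", strategy, "' requires generating_curves")
  if (!is.null(generating_curves)) {
    if (!all(c("part1", "part2") %in% names(generating_curves)) ||
        !inherits(generating_curves$part1, "response_curve") ||
        !inherits(generating_curves$part2, "response_curve"))
      stop("generating_curves must be list(part1 =, part2 =) of response_curve")
  }
  structure(list(id = as.character(id), strategy = strategy, alpha = alpha,
                 standard_beta = standard_beta, lapse = lapse,
                 generating_curves = generating_curves,
                 seed = as.integer(seed)),
            class = "subject_spec")
}

#' Generate a trial-type schedule
#'
#' @param cfg A [schedule_config()].
#' @param seed Integer seed.
#' @return Character vector of `"standard"`/`"probe"` of length
#'   `cfg$n_per_part`.
#' @export
generate_schedule <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "schedule_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- cfg$n_per_part
  types <- rep("standard", n)
  if (n > cfg$n_training) {
    u <- stats::runif(n - cfg$n_training)
    for (i in seq(cfg$n_training + 1L, n)) {
      # with no training block the first trial has no predecessor; it is
      # treated as following a standard trial
      after_probe <- i > 1L && types[i - 1L] == "probe"
      p <- if (after_probe) cfg$p_probe_after_probe
           else cfg$p_probe_after_standard
      if (u[i - cfg$n_training] < p) types[i] <- "probe"
    }
  }
  types
}

#' Standard-trial choice probability of the generator
#'
#' The probability that a synthetic subject chooses M1 on a standard trial
#' with known shift `s`: a softmax with inverse temperature `beta` over the
#' exact-shift posterior log-odds
#' \eqn{\log[P(M1) P(s|M1)] - \log[P(M2) P(s|M2)]}, mixed with a lapse.
#' `beta = 1` reproduces the posterior probability itself (probability
#' matching).
#'
#' @param cond A [task_condition()].
#' @param s Signed shifts (cm); vectorised.
#' @param beta Inverse temperature, `>= 0`.
#' @param lapse Lapse rate. Default 0.
#' @return Probabilities of choosing M1.
#' @export
standard_choice_prob <- function(cond, s, beta = 1, lapse = 0) {
  l1 <- log(cond$p_m1) + log(prior_pdf(cond$prior_m1, s))
  l2 <- log(1 - cond$p_m1) + log(prior_pdf(cond$prior_m2, s))
  p <- stats::plogis(beta * (l1 - l2))
  (1 - lapse) * p + lapse * 0.5
}

#' Analytic probe-choice probability of a strategy
#'
#' The choice probability a given generating strategy assigns to M1 for an
#' array width, before lapse mixing. Used both by the simulator and to check
#' that simulated choice rates converge to the predictor modules' output.
#'
#' @param strategy One of the five strategies.
#' @param cond A [task_condition()].
#' @param curve The generating [response_curve()] for this part (ignored by
#'   `bayes_factor`).
#' @param width Array width (cm).
#' @param alpha Softmax inverse temperature for `bayes_factor`.
#' @param grid A [shift_grid()].
#' @return Probability of choosing M1.
#' @export
strategy_probe_prob <- function(strategy, cond, curve, width, alpha = 1,
                                grid = shift_grid()) {
  strategy <- match.arg(strategy, subject_strategies)
  switch(strategy,
    bayes_factor = predict_probe_choice_bayes(cond, width, alpha, grid),
    policy_inference = predict_probe_choice_policy(cond, curve, width, grid),
    predict_probe_choice_heuristic(curve, strategy, width))
}

empty_trial_log <- function() {
  data.frame(subject_id = character(), part = integer(), index = integer(),
             trial_type = character(), true_model = character(),
             shift_cm = numeric(), array_width_cm = numeric(),
             choice = character(), correct = logical(),
             stringsAsFactors = FALSE)
}

# vectorised simulation of one part; RNG state is already positioned
simulate_part <- function(cond, subj, cfg, part) {
  types <- generate_schedule(cfg)
  n <- length(types)
  is_std <- types == "standard"
  n_std <- sum(is_std)
  n_prb <- n - n_std

  true_model <- rep(NA_character_, n)
  shift <- rep(NA_real_, n)
  width <- rep(NA_real_, n)
  choice <- rep(NA_character_, n)

  # standard trials: model, shift, softmax-over-posterior choice
  m1 <- stats::runif(n_std) < cond$p_m1
  sh <- numeric(n_std)
  if (any(m1)) sh[m1] <- prior_sample(cond$prior_m1, sum(m1))
  if (any(!m1)) sh[!m1] <- prior_sample(cond$prior_m2, sum(!m1))
  p_std <- standard_choice_prob(cond, sh, subj$standard_beta, subj$lapse)
  ch_std <- ifelse(stats::runif(n_std) < p_std, "M1", "M2")
  true_model[is_std] <- ifelse(m1, "M1", "M2")
  shift[is_std] <- sh
  choice[is_std] <- ch_std

  # probe trials: equiprobable widths, strategy-driven choice
  if (n_prb > 0) {
    w <- sample(cond$probe_widths, n_prb, replace = TRUE)
    curve <- subj$generating_curves[[paste0("part", part)]]
    p_by_w <- vapply(cond$probe_widths, function(wi)
      strategy_probe_prob(subj$strategy, cond, curve, wi, subj$alpha),
      numeric(1))
    p_prb <- (1 - subj$lapse) * p_by_w[match(w, cond$probe_widths)] +
      subj$lapse * 0.5
    ch_prb <- ifelse(stats::runif(n_prb) < p_prb, "M1", "M2")
    width[!is_std] <- w
    choice[!is_std] <- ch_prb
  }

  data.frame(subject_id = subj$id, part = as.integer(part),
             index = seq_len(n), trial_type = types,
             true_model = true_model, shift_cm = shift,
             array_width_cm = width, choice = choice,
             correct = ifelse(is_std, choice == true_model, NA),
             stringsAsFactors = FALSE)
}

#' Simulate a single standard trial
#'
#' Draws the generating model (Bernoulli `p_m1`), a shift from that model's
#' prior, and a choice from the subject's standard-trial policy. Uses the
#' current RNG stream.
#'
#' @param cond A [task_condition()].
#' @param subj A [subject_spec()].
#' @param part Experiment part (1 or 2) recorded in the log.
#' @return A one-row trial-log data frame.
#' @export
simulate_standard_trial <- function(cond, subj, part = 1) {
  m <- if (stats::runif(1) < cond$p_m1) "M1" else "M2"
  s <- prior_sample(if (m == "M1") cond$prior_m1 else cond$prior_m2, 1)
  p <- standard_choice_prob(cond, s, subj$standard_beta, subj$lapse)
  ch <- if (stats::runif(1) < p) "M1" else "M2"
  data.frame(subject_id = subj$id, part = as.integer(part), index = 1L,
             trial_type = "standard", true_model = m, shift_cm = s,
             array_width_cm = NA_real_, choice = ch, correct = ch == m,
             stringsAsFactors = FALSE)
}

#' Simulate a single probe trial
#'
#' The choice is drawn from the subject's strategy prediction for the given
#' width, mixed with the lapse. No ground-truth model or correctness is
#' recorded (probe trials carry no feedback).
#'
#' @inheritParams simulate_standard_trial
#' @param width Array width (cm); must be one of `cond$probe_widths`.
#' @return A one-row trial-log data frame.
#' @export
simulate_probe_trial <- function(cond, subj, width, part = 1) {
  if (!width %in% cond$probe_widths)
    stop("width must be one of the condition's probe widths")
  curve <- subj$generating_curves[[paste0("part", part)]]
  p <- strategy_probe_prob(subj$strategy, cond, curve, width, subj$alpha)
  p <- (1 - subj$lapse) * p + subj$lapse * 0.5
  ch <- if (stats::runif(1) < p) "M1" else "M2"
  data.frame(subject_id = subj$id, part = as.integer(part), index = 1L,
             trial_type = "probe", true_model = NA_character_,
             shift_cm = NA_real_, array_width_cm = width, choice = ch,
             correct = NA, stringsAsFactors = FALSE)
}

#' Simulate a full two-part session for one subject
#'
#' Runs the schedule, standard trials and probe trials for both parts and
#' concatenates the logs. Fully reproducible from `subj$seed`.
#'
#' @param cond_part1,cond_part2 [task_condition()]s for the two parts.
#' @param subj A [subject_spec()].
#' @param cfg A [schedule_config()].
#' @return A trial-log data frame with `2 * cfg$n_per_part` rows and columns
#'   `subject_id, part, index, trial_type, true_model, shift_cm,
#'   array_width_cm, choice, correct`.
#' @export
simulate_subject <- function(cond_part1, cond_part2, subj,
                             cfg = schedule_config()) {
  stopifnot(inherits(subj, "subject_spec"), inherits(cfg, "schedule_config"))
  out <- vector("list", 2)
  for (part in 1:2) {
    set.seed(subj$seed + (part - 1L) * 1000003L)
    cond <- if (part == 1) cond_part1 else cond_part2
    out[[part]] <- simulate_part(cond, subj, cfg, part)
  }
  rbind(out[[1]], out[[2]])
}

#' Simulate a cohort of subjects sharing a strategy
#'
#' @inheritParams simulate_subject
#' @param n_subjects Number of subjects. Default 7.
#' @param strategy Generating strategy for every subject.
#' @param seed Base seed; subject `i` uses `seed + i`.
#' @param ... Further arguments to [subject_spec()] (e.g. `lapse`,
#'   `standard_beta`, `generating_curves`).
#' @return A combined trial-log data frame.
#' @export
simulate_cohort <- function(cond_part1, cond_part2, n_subjects = 7,
                            strategy = "bayes_factor", seed = 1,
                            cfg = schedule_config(), ...) {
  logs <- lapply(seq_len(n_subjects), function(i) {
    subj <- subject_spec(id = sprintf("S%02d", i), strategy = strategy,
                         seed = as.integer(seed) + i, ...)
    simulate_subject(cond_part1, cond_part2, subj, cfg)
  })
  do.call(rbind, logs)
}

#' Canonical response curves of the standard-trial generator
#'
#' Least-squares fits of the sigmoid (part 1) and two-partite sigmoid
#' (part 2) families to the analytic standard-trial choice probability
#' [standard_choice_prob()] over a fine magnitude grid. These serve as
#' generating curves for synthetic subjects whose probe strategy needs a
#' standard-trial policy (policy inference and the heuristics).
#'
#' @param cond_part1,cond_part2 [task_condition()]s.
#' @param beta Standard-trial inverse temperature of the generator.
#' @return `list(part1 =, part2 =)` of [response_curve()]s.
#' @export
canonical_response_curves <- function(cond_part1 = part1_condition(),
                                      cond_part2 = part2_condition(),
                                      beta = 1) {
  x1 <- seq(0, 5, by = 0.1)
  x2 <- seq(0, 10, by = 0.2)
  list(part1 = ls_fit_curve(x1, standard_choice_prob(cond_part1, x1, beta),
                            "sigmoid"),
       part2 = ls_fit_curve(x2, standard_choice_prob(cond_part2, x2, beta),
                            "two_part_sigmoid"))
}

trial_log_columns <- c("subject_id", "part", "index", "trial_type",
                       "true_model", "shift_cm", "array_width_cm",
                       "choice", "correct")

#' Write / read a trial log as CSV
#'
#' The log schema has header `subject_id, part, index, trial_type,
#' true_model, shift_cm, array_width_cm, choice, correct`; inapplicable
#' fields are `NA` ('.' decimal separator, UTF-8). `read_trial_log()`
#' validates the schema and the per-type NA pattern (standard trials carry a
#' shift and true model but no width; probe trials the reverse) and reports
#' the first offending row.
#'
#' @param trials A trial-log data frame.
#' @param file Path to a CSV file.
#' @return `read_trial_log()` returns the validated data frame;
#'   `write_trial_log()` returns `file` invisibly.
#' @export
write_trial_log <- function(trials, file) {
  validate_trial_log(trials)
  utils::write.csv(trials[, trial_log_columns], file, row.names = FALSE,
                   quote = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"),
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0) {
    warning("empty trial log: ", file)
    return(empty_trial_log())
  }
  validate_trial_log(df)
  df
}

validate_trial_log <- function(df) {
  if (!identical(sort(names(df)), sort(trial_log_columns)))
    stop("trial log must have exactly the columns: ",
         paste(trial_log_columns, collapse = ", "))
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("trial log row %d: %s", i[1], what))
  }
  bad(!df$trial_type %in% c("standard", "probe"), "unknown trial_type")
  bad(!df$choice %in% c("M1", "M2"), "choice must be M1 or M2")
  bad(!df$part %in% c(1L, 2L), "part must be 1 or 2")
  std <- df$trial_type == "standard"
  bad(std & (is.na(df$shift_cm) | is.na(df$true_model)),
      "standard trial missing shift or true_model")
  bad(std & !is.na(df$array_width_cm),
      "standard trial must not carry an array width")
  bad(!std & !is.na(df$shift_cm), "probe trial must not carry a shift")
  bad(!std & (is.na(df$array_width_cm)),
      "probe trial missing array width")
  bad(!std & !is.na(df$correct), "probe trial must not carry correctness")
  invisible(df)
}
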