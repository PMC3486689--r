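# Explanation 1: marginal likelihoods, Bayes factors, softmax choice rule,
# and the joint/shift posteriors shared with Bayesian policy inference.

# memoised per-(condition, d, grid) posteriors; keys are parameter digests
.cache <- new.env(parent = emptyenv())

cond_key <- function(cond, grid) {
  paste(c(unlist(cond$prior_m1), unlist(cond$prior_m2), cond$p_m1,
          cond$d_max, grid$step, length(grid$points)), collapse = ",")
}

#' Model evidence (marginal likelihood) of an array width
#'
#' \eqn{P(d|M) = \int ds\, P(d|s) P(s|M)}: the prior-weighted average of the
#' observation likelihood over the shifts compatible with the model, computed
#' by trapezoidal quadrature on the shift grid.
#'
#' @param cond A [task_condition()].
#' @param model `"M1"` or `"M2"`.
#' @param d Observed array width (cm), in `(0, d_max]`.
#' @param grid A [shift_grid()]; defaults to the package grid.
#' @return Nonnegative evidence value.
#' @export
model_evidence <- function(cond, model = c("M1", "M2"), d, grid = shift_grid()) {
  stopifnot(inherits(cond, "task_condition"))
  model <- match.arg(model)
  if (length(d) != 1 || !is.finite(d) || d <= 0 || d > cond$d_max)
    stop("d must lie in (0, d_max]")
  prior <- if (model == "M1") cond$prior_m1 else cond$prior_m2
  lik <- obs_likelihood(grid$points, d, cond$d_max)
  support_integral(grid, lik * prior_pdf(prior, grid$points), d)
}

#' Bayes factor between the two candidate models
#'
#' `model_evidence(cond, "M1", d) / model_evidence(cond, "M2", d)`. Values
#' above 1 favour M1.
#'
#' @inheritParams model_evidence
#' @return Evidence ratio.
#' @export
bayes_factor <- function(cond, d, grid = shift_grid()) {
  e1 <- model_evidence(cond, "M1", d, grid)
  e2 <- model_evidence(cond, "M2", d, grid)
  if (e2 <= 0)
    stop("evidence for M2 is zero at d = ", d, ": Bayes factor undefined")
  e1 / e2
}

#' Softmax choice probability from a log Bayes factor
#'
#' \eqn{P(a = M1) = 1 / (1 + e^{-\alpha \log BF})}, the logistic map from the
#' log evidence ratio to a choice probability with inverse temperature
#' `alpha`. `alpha = 0` yields indifference (0.5) regardless of the evidence.
#'
#' @param log_bf Log Bayes factor (finite).
#' @param alpha Inverse temperature, `>= 0`. Default 1.
#' @return Probability in (0, 1).
#' @export
softmax_choice_prob <- function(log_bf, alpha = 1) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha < 0)
    stop("alpha must be a single nonnegative number")
  if (any(!is.finite(log_bf)))
    stop("log_bf must be finite")
  stats::plogis(alpha * log_bf)
}

#' Joint posterior over shift and model after a probe observation
#'
#' \eqn{P(s, M | d) \propto P(d|s) P(s|M) P(M)}, normalised so that the sum
#' over models of the integral over shifts is 1. Zero outside
#' \eqn{|s| \le d/2}.
#'
#' @inheritParams model_evidence
#' @return An object of class `posterior_grid` with fields `grid`, `d` (the
#'   conditioning width) and the densities `density_m1`, `density_m2`
#'   (1/cm).
#' @export
joint_posterior <- function(cond, d, grid = shift_grid()) {
  stopifnot(inherits(cond, "task_condition"))
  if (length(d) != 1 || !is.finite(d) || d <= 0 || d > cond$d_max)
    stop("d must lie in (0, d_max]")
  key <- paste("jp", cond_key(cond, grid), d)
  hit <- .cache[[key]]
  if (!is.null(hit)) return(hit)
  lik <- obs_likelihood(grid$points, d, cond$d_max)
  num1 <- lik * prior_pdf(cond$prior_m1, grid$points) * cond$p_m1
  num2 <- lik * prior_pdf(cond$prior_m2, grid$points) * (1 - cond$p_m1)
  z <- support_integral(grid, num1, d) + support_integral(grid, num2, d)
  if (z <= 0) stop("posterior undefined: zero total evidence at d = ", d)
  out <- structure(list(grid = grid, d = d, density_m1 = num1 / z,
                        density_m2 = num2 / z),
                   class = "posterior_grid")
  .cache[[key]] <- out
  out
}

#' Posterior over the shift after a probe observation
#'
#' \eqn{P(s|d) = \sum_M P(s, M|d)}: the model-marginalised shift posterior
#' used by Bayesian policy inference. Integrates to 1; zero for
#' \eqn{|s| > d/2}.
#'
#' @inheritParams model_evidence
#' @return Numeric vector of densities over `grid$points` (1/cm).
#' @export
shift_posterior <- function(cond, d, grid = shift_grid()) {
  jp <- joint_posterior(cond, d, grid)
  jp$density_m1 + jp$density_m2
}

#' Probe-choice probability under the Bayes-factor observer
#'
#' Composes the log Bayes factor (computed as a difference of log evidences,
#' avoiding underflow) with the softmax rule.
#'
#' @inheritParams model_evidence
#' @param alpha Softmax inverse temperature. Default 1.
#' @return Probability of choosing M1.
#' @export
predict_probe_choice_bayes <- function(cond, d, alpha = 1, grid = shift_grid()) {
  key <- paste("bf", cond_key(cond, grid), d)
  log_bf <- .cache[[key]]
  if (is.null(log_bf)) {
    e1 <- model_evidence(cond, "M1", d, grid)
    e2 <- model_evidence(cond, "M2", d, grid)
    if (e1 <= 0 || e2 <= 0)
      stop("zero evidence at d = ", d, ": log Bayes factor undefined")
    log_bf <- log(e1) - log(e2)
    .cache[[key]] <- log_bf
  }
  softmax_choice_prob(log_bf, alpha)
}
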