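#' Gaussian-mixture prior over the lateral shift
#'
#' A shift prior is a finite mixture of Gaussians over the signed lateral
#' visuomotor shift \eqn{s} (cm, positive to the subject's right). A single
#' Gaussian is the one-component case. The experiment uses three priors:
#' N(0, 1 cm^2) and N(0, 16 cm^2) for model M1 in parts 1 and 2, and the
#' bimodal mixture 0.5 N(-2.5, 0.25) + 0.5 N(2.5, 0.25) for model M2.
#'
#' @param weights Positive mixture weights; must sum to 1 (within 1e-12).
#' @param means Component means (cm).
#' @param vars Component variances (cm^2), strictly positive.
#' @return An object of class `shift_prior`.
#' @examples
#' shift_prior(1, 0, 1)                        # N(0, 1)
#' shift_prior(c(.5, .5), c(-2.5, 2.5), .25)   # the bimodal M2 prior
#' @export
shift_prior <- function(weights, means, vars) {
  n <- max(length(weights), length(means), length(vars))
  weights <- rep_len(as.numeric(weights), n)
  means <- rep_len(as.numeric(means), n)
  vars <- rep_len(as.numeric(vars), n)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("mixture weights must be finite and strictly positive")
  if (abs(sum(weights) - 1) > 1e-12)
    stop("mixture weights must sum to 1 (within 1e-12)")
  if (any(!is.finite(vars)) || any(vars <= 0))
    stop("component variances must be finite and strictly positive")
  if (any(!is.finite(means)))
    stop("component means must be finite")
  structure(list(weights = weights, means = means, vars = vars),
            class = "shift_prior")
}

#' @export
print.shift_prior <- function(x, ...) {
  cat("Shift prior (Gaussian mixture):\n")
  for (k in seq_along(x$weights))
    cat(sprintf("  %0.3f * N(%.2f cm, %.3f cm^2)\n",
                x$weights[k], x$means[k], x$vars[k]))
  invisible(x)
}

#' Mixture density of a shift prior
#'
#' @param prior A [shift_prior()].
#' @param s Shift values (cm); vectorised.
#' @return Density values (1/cm).
#' @export
prior_pdf <- function(prior, s) {
  stopifnot(inherits(prior, "shift_prior"))
  out <- numeric(length(s))
  for (k in seq_along(prior$weights))
    out <- out + prior$weights[k] *
      stats::dnorm(s, prior$means[k], sqrt(prior$vars[k]))
  out
}

#' Mixture CDF of a shift prior
#'
#' @inheritParams prior_pdf
#' @return P(S <= s).
#' @export
prior_cdf <- function(prior, s) {
  stopifnot(inherits(prior, "shift_prior"))
  out <- numeric(length(s))
  for (k in seq_along(prior$weights))
    out <- out + prior$weights[k] *
      stats::pnorm(s, prior$means[k], sqrt(prior$vars[k]))
  out
}

#' Sample shifts from a prior
#'
#' Components are chosen by weight, then a Gaussian draw is made from the
#' chosen component. Reproducible given `seed`; when `seed` is `NULL` the
#' current RNG stream is used.
#'
#' @param prior A [shift_prior()].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` shifts (cm).
#' @export
prior_sample <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "shift_prior"))
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop("n must be a single integer >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  k <- sample.int(length(prior$weights), n, replace = TRUE,
                  prob = prior$weights)
  stats::rnorm(n, prior$means[k], sqrt(prior$vars[k]))
}

#' Task condition for one experiment part
#'
#' Bundles the two candidate shift priors, the model prior probability, the
#' maximum realizable array width and the admissible probe array widths.
#'
#' @param prior_m1,prior_m2 [shift_prior()] objects for models M1 and M2.
#' @param p_m1 Prior probability of model M1, in (0, 1). Default 0.5.
#' @param d_max Maximum possible array width (cm). Default 8.
#' @param probe_widths Admissible probe array widths (cm), each in
#'   `(0, d_max]`. Default `c(3, 5, 8)`.
#' @return An object of class `task_condition`.
#' @seealso [part1_condition()], [part2_condition()]
#' @export
task_condition <- function(prior_m1, prior_m2, p_m1 = 0.5, d_max = 8,
                           probe_widths = c(3, 5, 8)) {
  stopifnot(inherits(prior_m1, "shift_prior"), inherits(prior_m2, "shift_prior"))
  if (length(p_m1) != 1 || !is.finite(p_m1) || p_m1 <= 0 || p_m1 >= 1)
    stop("p_m1 must lie strictly between 0 and 1")
  if (length(d_max) != 1 || !is.finite(d_max) || d_max <= 0)
    stop("d_max must be a single positive number")
  probe_widths <- as.numeric(probe_widths)
  if (any(probe_widths <= 0) || any(probe_widths > d_max))
    stop("every probe width must lie in (0, d_max]")
  structure(list(prior_m1 = prior_m1, prior_m2 = prior_m2, p_m1 = p_m1,
                 d_max = d_max, probe_widths = probe_widths),
            class = "task_condition")
}

#' Experimental conditions of the two study parts
#'
#' Part 1 pairs the narrow Gaussian M1 prior N(0, 1 cm^2) with the bimodal
#' M2 mixture at +/-2.5 cm; part 2 widens M1 to N(0, 16 cm^2) while M2 is
#' unchanged. Model prior probabilities are 0.5 each, `d_max` is 8 cm and the
#' probe widths are 3, 5 and 8 cm.
#'
#' @return A `task_condition`.
#' @export
part1_condition <- function() {
  task_condition(prior_m1 = shift_prior(1, 0, 1),
                 prior_m2 = shift_prior(c(0.5, 0.5), c(-2.5, 2.5), 0.25))
}

#' @rdname part1_condition
#' @export
part2_condition <- function() {
  task_condition(prior_m1 = shift_prior(1, 0, 16),
                 prior_m2 = shift_prior(c(0.5, 0.5), c(-2.5, 2.5), 0.25))
}

#' Quadrature grid over shifts
#'
#' Uniform symmetric grid used for all trapezoidal integrals over \eqn{s}.
#' The default span of +/-20 cm covers the widest configured prior
#' (sigma = 4 cm) out to five standard deviations, so every configured prior
#' integrates to 1 on the grid within 1e-6; the 0.005 cm step keeps
#' quadrature error well below 1e-6 relative to a tenfold finer grid.
#'
#' @param half_width Half-width of the grid (cm). Default 20.
#' @param step Grid spacing (cm). Default 0.005.
#' @return An object of class `shift_grid` with fields `points` and `step`.
#' @export
shift_grid <- function(half_width = 20, step = 0.005) {
  if (half_width <= 0 || step <= 0 || step > half_width)
    stop("half_width and step must be positive with step <= half_width")
  n <- round(half_width / step)
  structure(list(points = seq(-n, n) * step, step = step),
            class = "shift_grid")
}

#' Marginal (model-averaged) shift density
#'
#' The superposition \eqn{P(s) = P(M1) P(s|M1) + P(M2) P(s|M2)} of the two
#' conditional priors of a condition.
#'
#' @param cond A [task_condition()].
#' @param s Shift values (cm); vectorised.
#' @return Density values (1/cm).
#' @export
marginal_shift_pdf <- function(cond, s) {
  stopifnot(inherits(cond, "task_condition"))
  cond$p_m1 * prior_pdf(cond$prior_m1, s) +
    (1 - cond$p_m1) * prior_pdf(cond$prior_m2, s)
}

#' Observation model of the probe array width
#'
#' Likelihood of observing an ambiguous cursor array of width `d` given a
#' true shift `s`:
#' \deqn{P(d|s) = 1 / (d_{max}/2 - |s|)} when \eqn{d \ge 2|s|} and
#' \eqn{d \le d_{max}}, and 0 otherwise: the array must contain the shift and
#' cannot exceed the maximum width. As a function of `s` for fixed `d` it is
#' even in `s` and increases with `|s|` on its support. The single point
#' `|s| = d_max/2` (reachable only when `d = d_max`) is assigned 0, since the
#' formula is singular there and the point carries no probability mass.
#'
#' @param s Shift values (cm); vectorised.
#' @param d Observed array width (cm), scalar, `>= 0`.
#' @param d_max Maximum possible array width (cm). Default 8.
#' @return Likelihood values.
#' @examples
#' obs_likelihood(0, d = 5) # 1/4
#' obs_likelihood(2, d = 5) # 1/2
#' obs_likelihood(3, d = 5) # 0: the array is too small to contain the shift
#' @export
obs_likelihood <- function(s, d, d_max = 8) {
  if (length(d) != 1 || !is.finite(d) || d < 0)
    stop("d must be a single nonnegative number")
  if (length(d_max) != 1 || !is.finite(d_max) || d_max <= 0)
    stop("d_max must be a single positive number")
  denom <- d_max / 2 - abs(s)
  ok <- (d >= 2 * abs(s)) & (d <= d_max) & (denom > 0)
  out <- numeric(length(s))
  out[ok] <- 1 / denom[ok]
  out
}

# trapezoidal integral of y over a shift_grid
grid_integral <- function(grid, y) {
  pracma::trapz(grid$points, y)
}

# trapezoidal integral restricted to the observation-model support
# |s| <= d/2: the integrand jumps to zero there, and integrating across the
# jump would add spurious boundary triangles of O(step) mass
support_integral <- function(grid, y, d) {
  idx <- abs(grid$points) <= d / 2 + 1e-12
  pracma::trapz(grid$points[idx], y[idx])
}
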