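# Explanation 2: standard-trial response curves (psychometric fits) and
# probe predictions by probabilistic superposition under the shift posterior.

#' Standard-trial response curve
#'
#' A psychometric function giving the probability of choosing M1 as a
#' function of the shift magnitude `|s|`. Two families are used: a sigmoid
#' \deqn{P(a = M1 | s) = 1 - 1/(1 + e^{-(s+\zeta)/\theta})}
#' for part 1, and a two-partite sigmoid
#' \deqn{P(a = M1 | s) = 1 - 1/(1 + e^{-(s+\gamma)/\delta})
#'       + 1/(1 + e^{-(s+\kappa)/\tau})}
#' for part 2, whose second term lets the curve rise again for very large
#' shifts (the wide M1 prior reclaims them). Scale parameters must be
#' positive; evaluated probabilities are clipped to [0, 1].
#'
#' @param family `"sigmoid"` or `"two_part_sigmoid"`.
#' @param params Named numeric vector: `c(zeta, theta)` for the sigmoid,
#'   `c(gamma, delta, kappa, tau)` for the two-partite form.
#' @param sse Optional sum of squared errors of the fit that produced the
#'   curve.
#' @param degenerate Logical flag set by [fit_response_curve()] when the data
#'   carried no discriminative signal.
#' @return An object of class `response_curve`.
#' @export
response_curve <- function(family = c("sigmoid", "two_part_sigmoid"), params,
                           sse = NA_real_, degenerate = FALSE) {
  family <- match.arg(family)
  params <- as.numeric(params)
  if (family == "sigmoid") {
    if (length(params) != 2) stop("sigmoid curves take params (zeta, theta)")
    names(params) <- c("zeta", "theta")
    if (params["theta"] <= 0) stop("scale parameter theta must be positive")
  } else {
    if (length(params) != 4)
      stop("two-partite curves take params (gamma, delta, kappa, tau)")
    names(params) <- c("gamma", "delta", "kappa", "tau")
    if (params["delta"] <= 0 || params["tau"] <= 0)
      stop("scale parameters delta and tau must be positive")
  }
  structure(list(family = family, params = params, sse = sse,
                 degenerate = degenerate),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("Response curve (%s): %s%s%s\n", x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              if (is.finite(x$sse)) sprintf(" [sse %.4g]", x$sse) else "",
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Evaluate a response curve at a shift magnitude
#'
#' @param curve A [response_curve()].
#' @param s_mag Shift magnitudes (cm), `>= 0`; vectorised.
#' @return Probabilities of choosing M1, clipped to [0, 1].
#' @export
response_prob <- function(curve, s_mag) {
  stopifnot(inherits(curve, "response_curve"))
  if (any(s_mag < 0)) stop("s_mag must be nonnegative (curves take |s|)")
  p <- curve$params
  v <- if (curve$family == "sigmoid") {
    1 - stats::plogis((s_mag + p["zeta"]) / p["theta"])
  } else {
    1 - stats::plogis((s_mag + p["gamma"]) / p["delta"]) +
      stats::plogis((s_mag + p["kappa"]) / p["tau"])
  }
  pmin(pmax(unname(v), 0), 1)
}

#' Standard bin edges for each experiment part
#'
#' Five equidistant magnitude bins: 0--5 cm in 1 cm steps for part 1,
#' 0--10 cm in 2 cm steps for part 2.
#'
#' @param part 1 or 2.
#' @return Numeric vector of six edges.
#' @export
standard_bin_edges <- function(part) {
  if (!part %in% c(1, 2)) stop("part must be 1 or 2")
  if (part == 1) seq(0, 5, by = 1) else seq(0, 10, by = 2)
}

#' Bin standard trials by shift magnitude
#'
#' Signed shifts are mapped to their magnitude and sorted into half-open bins
#' `[lo, hi)`; magnitudes at or beyond the last edge fall into the last bin.
#' Returns counts of M1 choices and totals per bin.
#'
#' @param trials A trial-log data frame (see [simulate_subject()]) containing
#'   standard trials of one subject and part.
#' @param edges Ascending bin boundaries (cm), e.g. [standard_bin_edges()].
#' @return An object of class `binned_responses` with fields `edges`,
#'   `centers`, `n_m1`, `n_total` and `freq` (NA for empty bins).
#' @export
bin_standard_trials <- function(trials, edges) {
  trials <- trials[trials$trial_type == "standard", , drop = FALSE]
  if (nrow(trials) == 0) stop("no standard trials to bin")
  edges <- as.numeric(edges)
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("edges must be strictly increasing with at least two values")
  if (any(is.na(trials$shift_cm))) stop("standard trials must carry a shift")
  mag <- abs(trials$shift_cm)
  nb <- length(edges) - 1
  idx <- findInterval(mag, edges, rightmost.closed = FALSE)
  idx[idx < 1] <- 1      # cannot occur for edges starting at 0, kept for safety
  idx[idx > nb] <- nb    # magnitudes beyond the last edge join the last bin
  n_total <- tabulate(idx, nbins = nb)
  n_m1 <- tabulate(idx[trials$choice == "M1"], nbins = nb)
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 n_m1 = n_m1, n_total = n_total,
                 freq = ifelse(n_total > 0, n_m1 / n_total, NA_real_)),
            class = "binned_responses")
}

# deterministic multi-start grids; best sse wins, ties to first in order
start_grid_sigmoid <- function() {
  as.matrix(expand.grid(zeta = c(-10, -6, -2, 2), theta = c(0.2, 1, 5)))
}
start_grid_two_part <- function() {
  as.matrix(expand.grid(gamma = c(-6, -3, -1), delta = c(0.5, 2),
                        kappa = c(-10, -7, -4, -2), tau = c(0.5, 2)))
}

#' Fit a response curve to binned relative frequencies
#'
#' Nonlinear least squares of the curve family evaluated at the bin centers
#' against the bins' relative frequencies of choosing M1, all non-empty bins
#' weighted equally. A deterministic multi-start (12 starts for the sigmoid,
#' 48 for the two-partite form, spanning location -10..2 cm and scale
#' 0.2..5 cm) guards against the multimodal objective; the best
#' sum-of-squares wins, ties broken by grid order. Flat data (all
#' frequencies equal) yield a constant curve flagged `degenerate`.
#'
#' @param binned A [bin_standard_trials()] result.
#' @param family `"sigmoid"` or `"two_part_sigmoid"`.
#' @return A [response_curve()] with its `sse` filled in.
#' @export
fit_response_curve <- function(binned, family = c("sigmoid", "two_part_sigmoid")) {
  stopifnot(inherits(binned, "binned_responses"))
  family <- match.arg(family)
  keep <- binned$n_total > 0
  x <- binned$centers[keep]
  y <- binned$freq[keep]
  need <- if (family == "sigmoid") 2L else 4L
  if (sum(keep) < need)
    stop(sprintf("need >= %d non-empty bins to fit a %s curve (have %d)",
                 need, family, sum(keep)))

  if (stats::sd(y) < 1e-12) {
    # no discriminative signal: a flat curve at the common frequency
    c0 <- min(max(y[1], 1e-6), 1 - 1e-6)
    big <- 1e6
    params <- if (family == "sigmoid") {
      c(big * stats::qlogis(1 - c0), big)
    } else {
      c(big * stats::qlogis(1 - c0), big, -big, big)
    }
    return(response_curve(family, params, sse = 0, degenerate = TRUE))
  }

  ls_fit_curve(x, y, family)
}

# multi-start least squares of a curve family against (x, y) points
ls_fit_curve <- function(x, y, family) {
  # objectives written in raw arithmetic: they sit in a tight optim loop
  sse_of <- if (family == "sigmoid") {
    function(p) {
      if (p[2] <= 0) return(Inf)
      v <- 1 - 1 / (1 + exp(-(x + p[1]) / p[2]))  # already within [0, 1]
      sum((v - y)^2)
    }
  } else {
    function(p) {
      if (p[2] <= 0 || p[4] <= 0) return(Inf)
      v <- 1 - 1 / (1 + exp(-(x + p[1]) / p[2])) +
        1 / (1 + exp(-(x + p[3]) / p[4]))
      v[v > 1] <- 1
      v[v < 0] <- 0
      sum((v - y)^2)
    }
  }

  starts <- if (family == "sigmoid") start_grid_sigmoid() else start_grid_two_part()
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], sse_of, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) stop("response-curve fit failed from every start")
  # gradient polish sharpens the simplex optimum (matters for exact data)
  polish <- tryCatch(
    stats::optim(best$par, sse_of, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$value) && polish$value <= best$value)
    best <- polish
  response_curve(family, best$par, sse = best$value)
}

#' Probe-choice probability under Bayesian policy inference
#'
#' The probabilistic superposition
#' \eqn{P(a = M1 | d) = \int ds\, P(s|d)\, P(a = M1 | s)}: the fitted
#' standard-trial policy, evaluated at `|s|`, averaged under the shift
#' posterior for the observed width.
#'
#' @param cond A [task_condition()].
#' @param curve A fitted [response_curve()] for the matching part.
#' @param d Observed array width (cm).
#' @param grid A [shift_grid()].
#' @return Probability of choosing M1, in [0, 1].
#' @export
predict_probe_choice_policy <- function(cond, curve, d, grid = shift_grid()) {
  post <- shift_posterior(cond, d, grid)
  v <- support_integral(grid, post * response_prob(curve, abs(grid$points)), d)
  min(max(v, 0), 1)
}
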