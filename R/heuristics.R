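# Explanations 3-5: non-probabilistic heuristics that read a single assumed
# shift off the probe array and apply the standard-trial policy there.

heuristic_modes <- c("average", "biggest", "halfway")

#' Assumed shift magnitude of a probe heuristic
#'
#' The three heuristics map an array of width `d` to a single assumed shift
#' magnitude: `average` assumes the shift in the middle of the array (0),
#' `biggest` the largest shift the array can contain (`d/2`), and `halfway`
#' a shift halfway between the middle and the edge (`d/4`).
#'
#' @param mode `"average"`, `"biggest"` or `"halfway"`.
#' @param d Array width (cm), `> 0`.
#' @return Assumed shift magnitude (cm).
#' @export
heuristic_assumed_shift <- function(mode = heuristic_modes, d) {
  mode <- match.arg(mode)
  if (any(d <= 0)) stop("d must be positive")
  switch(mode, average = 0 * d, biggest = d / 2, halfway = d / 4)
}

#' Probe-choice probability under a shift heuristic
#'
#' Evaluates the standard-trial response curve at the heuristic's assumed
#' shift. The `average` heuristic therefore predicts the same choice
#' probability for every array width; for a monotone-decreasing curve the
#' three heuristics bracket each other
#' (average >= halfway >= biggest at every width).
#'
#' @param curve A fitted [response_curve()].
#' @param mode `"average"`, `"biggest"` or `"halfway"`.
#' @param d Array width (cm).
#' @return Probability of choosing M1.
#' @export
predict_probe_choice_heuristic <- function(curve, mode = heuristic_modes, d) {
  mode <- match.arg(mode)
  response_prob(curve, heuristic_assumed_shift(mode, d))
}
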