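---
title: "Methods: five accounts of model selection under ambiguous feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: five accounts of model selection under ambiguous feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftselect)
```

## The task

An observer reaches toward one of two targets while a lateral visuomotor
shift $s$ (cm) displaces the cursor relative to the hand. On each trial the
shift is drawn from one of two candidate generative models with equal prior
probability $P(M_1) = P(M_2) = 1/2$:

* part 1: $P(s \mid M_1) = \mathcal{N}(0, 1\,\mathrm{cm}^2)$,
* part 2: $P(s \mid M_1) = \mathcal{N}(0, 16\,\mathrm{cm}^2)$,
* both parts: $P(s \mid M_2) = \tfrac12 \mathcal{N}(-2.5, 0.25) +
  \tfrac12 \mathcal{N}(2.5, 0.25)$.

On *standard trials* the shifted cursor is shown briefly, and the observer
reports both the shift (by compensating) and the model (by target choice),
receiving correctness feedback. On *probe trials* the cursor is replaced by
an ambiguous array of width $d \in \{3, 5, 8\}$ cm centred on the midline:
only the model choice remains informative, and the shift must be integrated
out. The observation model ties the array width to the shift,

$$P(d \mid s) = \frac{1}{d_{\max}/2 - |s|} \quad
  \text{if } d \ge 2|s| \text{ and } d \le d_{\max}, \qquad 0
  \text{ otherwise},$$

with $d_{\max} = 8$ cm: an array must contain the shift and cannot exceed
the maximum width.

## The five candidate accounts of probe choices

**1. Bayes factors.** The ideal observer scores each model by its marginal
likelihood $P(d \mid M_i) = \int \mathrm{d}s\, P(d \mid s) P(s \mid M_i)$
and chooses through a softmax on the log Bayes factor,
$P(a = M_1 \mid d) = 1/(1 + e^{-\alpha \log [P(d \mid M_1)/P(d \mid M_2)]})$
with inverse temperature $\alpha = 1$ by default (`alpha` is exposed but
never fitted: the account carries no per-subject free parameters).

**2. Bayesian policy inference.** The observer is assumed to have learned a
standard-trial policy $P(a = M_1 \mid s)$ and a single marginal prior over
shifts. On probe trials the policy is averaged under the shift posterior
$P(s \mid d) \propto P(d \mid s) P(s)$:
$P(a = M_1 \mid d) = \int \mathrm{d}s\, P(s \mid d)\, P(a = M_1 \mid s)$.
The policy is estimated per subject and part from the standard trials:
choices are binned by shift magnitude into five equidistant bins
([0,1]..[4,5] cm in part 1, [0,2]..[8,10] cm in part 2), and the relative
frequencies of choosing $M_1$ at the bin centres are fitted by least
squares with a sigmoid
$P(a = M_1 \mid s) = 1 - 1/(1 + e^{-(s+\zeta)/\theta})$ in part 1 and a
two-partite sigmoid
$1 - 1/(1 + e^{-(s+\gamma)/\delta}) + 1/(1 + e^{-(s+\kappa)/\tau})$ in
part 2, whose second term lets the choice probability rise again for very
large shifts (which the broad part-2 prior reclaims).

**3–5. Shift heuristics.** Three non-probabilistic readings of the array
reuse the same fitted curves at a single assumed shift: the *average*
heuristic evaluates the curve at $s = 0$ (predicting width-independent
choice rates), the *biggest* at $s = d/2$, and the *halfway* at $s = d/4$.
For any monotone-decreasing curve the three bracket each other
(average $\ge$ halfway $\ge$ biggest at every width).

Explanations are compared by the total negative log-likelihood of the
observed probe choices under their predicted choice probabilities; raw
NLLs are compared without a complexity penalty because none of the accounts
has per-subject free parameters beyond the shared fitted curves.

## Numerical choices

* **Quadrature.** All integrals over $s$ use the trapezoidal rule on a
  uniform grid with 0.005 cm spacing. The grid spans ±20 cm — five standard
  deviations of the widest prior — so every configured prior integrates to
  1 on the grid within $10^{-6}$ (a ±3σ span would strand 0.27% of the
  σ = 4 cm prior's mass). Integrands involving $P(d\mid s)$ are integrated
  over the likelihood support $|s| \le d/2$ only; integrating across the
  jump to zero would add a spurious boundary triangle of order
  step × density, which is visible against an unbiased Monte-Carlo
  estimate.
* **The singular width.** At $d = d_{\max}$ the printed likelihood
  $1/(d_{\max}/2 - |s|)$ diverges at $|s| = d_{\max}/2$, and since the
  priors have positive density there, the continuum evidence integral at
  the widest array diverges logarithmically: every finite value is a
  discretisation choice. The package assigns the singular grid point
  likelihood zero and defines the $d = 8$ evidence by the grid convention
  above. Consequences: (i) refining the grid tenfold moves the part-2
  $M_1$ evidence at $d = 8$ by about +22% while all $d < 8$ evidences are
  stable to $10^{-4}$ relative or better; (ii) a Monte-Carlo average over
  prior draws — whose expectation is the divergent integral — sits
  systematically above the grid value at $d = 8$, so oracle agreement
  there is checked only for $d < d_{\max}$-style statements, and the
  $d = 8$ discrepancy is an expected property, not a defect of either
  estimator. The qualitative orderings at $d = 8$ (which model wins, and
  the near-tie in part 2) are stable across discretisations.
* **Log-space Bayes factors.** $\log BF$ is computed as a difference of
  log evidences to avoid underflow; $d = d_{\max}$ is admitted inclusively.
* **Curve fitting.** Nonlinear least squares uses a deterministic
  multi-start (12 starting points for the sigmoid, 48 for the two-partite
  form, spanning locations −10..2 cm and scales 0.2..5 cm), Nelder–Mead
  then a BFGS polish; the best sum of squares wins with ties broken by
  grid order. The two-partite objective is multimodal, hence the denser
  start grid. All non-empty bins are weighted equally and curves are
  evaluated at bin centres (the simplest reading of least-squares on
  binned frequencies; bin means of $|s|$ and count weighting are
  defensible alternatives that change fits negligibly at these trial
  counts). Two-partite probabilities are clipped to [0, 1] before use.
  Flat response data (zero variance across bins) return a constant curve
  flagged `degenerate` rather than an arbitrary steep fit.
* **Response curves take $|s|$.** Shifts are signed (positive to the
  subject's right, an arbitrary fixed convention); binning and curve
  evaluation map them to magnitudes. Because priors and likelihood are
  even in $s$, evaluating the superposition integral at $|s|$ on the
  symmetric grid is equivalent to any signed convention.
* **NLL clipping.** Predicted probabilities are clipped to
  $[10^{-6}, 1 - 10^{-6}]$ before taking logs (with a warning), so
  degenerate predictions (e.g. the biggest heuristic's near-zero
  prediction at $d = 8$ in part 1) yield finite, dominated NLLs.
* **Significance tests.** The width × choice association per subject and
  part uses Fisher's exact test on the full 2 × 3 table (the
  Freeman–Halton extension); pairwise 2 × 2 tests would also be
  defensible, but the full table uses all probe widths at once. The
  between-part comparison of per-subject choice probabilities at a width
  uses the two-sided Wilcoxon rank-sum test. Degenerate tables (a zero
  margin) report p = 1 with a flag.

## The synthetic-subject simulator

No human choice data are distributed with this task, so every downstream
stage is exercised on simulated subjects whose generative process is fully
specified:

* **Schedule.** Each part has 500 trials; the first 100 are standard-only
  training, after which a probe trial follows a standard trial with
  probability 0.45 and never follows another probe. The stationary probe
  fraction of this two-state Markov rule is $0.45/1.45 \approx 0.310$.
  Probe widths are equiprobable over {3, 5, 8} cm.
* **Standard trials.** The true model is drawn 50:50, the shift from that
  model's prior, and the choice from a softmax over the exact-shift
  posterior log-odds with inverse temperature `standard_beta`. The
  experiment itself does not constrain how standard-trial stochasticity
  arises; the default `standard_beta = 1` is probability matching, a
  standard description of choice variability in psychophysics, and it
  produces binned response curves with the right sigmoid/two-partite
  shapes at realistic noise levels. A lapse rate (default 0.02, a typical
  attentional-slip rate) replaces any choice by a fair coin.
* **Probe trials.** The choice is drawn from the generating strategy's own
  analytic prediction for the realized width — any of the five accounts
  can serve as generator — mixed with the lapse. Strategies that need a
  standard-trial policy use *canonical curves*: least-squares fits of the
  two parametric families to the analytic standard-trial policy, computed
  once per condition.
* **Reproducibility.** Each subject derives all randomness from a single
  integer seed (with a fixed offset per part), so identical seeds yield
  byte-identical trial logs.

What the simulator deliberately does not emulate: movement kinematics,
force fields and the probe display's micro-structure (no analysis consumes
them); the continuous compensatory shift report; learning dynamics within
the training block (synthetic subjects know the priors from trial one); and
human departures from the generating strategies. The last point matters
when reading test output: a cohort of ideal Bayes-factor observers is more
regular than people, so, for example, its part-2 width–choice association
remains significant where human data need not be. Passing tests therefore
certify the analysis machinery and its self-consistency, not any claim
about human behaviour.

## Problem sizes

The shipped studies use 7 subjects × 1000 trials (the experiment's own
scale), 10⁶-draw Monte-Carlo and rejection oracles for quadrature checks,
200 replicates for parameter recovery at 80 trials per bin, and 100 seeds
per generating strategy for model recovery (25 in the lighter
`analysis/05_model_recovery.R` driver). Recovery is scored as the fraction
of replicates in which the generating strategy attains the lowest NLL; the
two Bayesian accounts are scored as a pair, since their predictions differ
only through fitting noise in the curves and the data cannot reliably
separate them — their mutual confusability is itself a property of the
design, not a failure of the comparison.

## Known limitations

* Evidence values at $d = d_{\max}$ are grid-convention quantities (see
  above); only their orderings and the resulting choice probabilities are
  meaningful across implementations.
* The curve-fitting contract requires at least 2 (sigmoid) or 4
  (two-partite) non-empty bins; subjects failing it are excluded from the
  comparison with a warning rather than imputed.
* The comparison assumes the probe widths realized in the data are among
  the condition's admissible widths; predictions are built per realized
  cell only.
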