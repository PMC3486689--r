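# shiftselect

How do people decide *which statistical model* generated what they just
saw, rather than merely estimating a parameter within one model?
`shiftselect` studies this question in a sensorimotor setting: a reaching
task in which a lateral cursor shift $s$ (cm) is drawn on every trial from
one of two candidate distributions — a Gaussian
$P(s\mid M_1) = \mathcal{N}(0, \sigma^2)$ (narrow in part 1, broad in
part 2) or a bimodal mixture
$P(s\mid M_2) = \tfrac12\mathcal{N}(-2.5, 0.25) + \tfrac12\mathcal{N}(2.5, 0.25)$
— and the observer reports the generating model. On *probe trials* the
cursor is replaced by an ambiguous array of width $d \in \{3,5,8\}$ cm, so
the shift must be integrated out: a pure model-selection problem.

The package implements, simulates and compares five accounts of probe-trial
choices, for researchers in sensorimotor psychophysics and computational
cognitive modelling:

1. **Bayes factors** — marginal likelihoods
   $P(d\mid M_i) = \int \mathrm{d}s\, P(d\mid s)P(s\mid M_i)$ under the
   observation model $P(d\mid s) = 1/(d_{\max}/2 - |s|)$ on
   $\{d \ge 2|s|,\ d \le d_{\max}\}$, passed through a softmax with
   inverse temperature $\alpha = 1$;
2. **Bayesian policy inference** — the fitted standard-trial policy
   $P(a = M_1 \mid s)$ averaged under the shift posterior
   $P(s \mid d)$;
3. **average-shift heuristic** — the policy evaluated at $s = 0$;
4. **biggest-shift heuristic** — at $s = d/2$;
5. **halfway heuristic** — at $s = d/4$.

It also provides a synthetic-subject simulator of the full two-part,
500-trials-per-part experiment (any of the five accounts can act as the
generator), psychometric fitting of sigmoid and two-partite response
curves, negative log-likelihood model comparison, the associated exact
significance tests (Freeman–Halton Fisher test, Wilcoxon rank-sum), and
parameter- and model-recovery studies. See the methods vignette
(`vignettes/model-selection-methods.Rmd`) for the model details and
numerical choices.

## Worked example

```r
library(shiftselect)

cond1 <- part1_condition()   # N(0,1) vs the bimodal mixture
cond2 <- part2_condition()   # N(0,16) vs the same mixture

# Ideal-observer choice probabilities for M1 by array width
sapply(c(3, 5, 8), function(d) predict_probe_choice_bayes(cond1, d))
#> [1] 0.9683990 0.5411606 0.2879735
sapply(c(3, 5, 8), function(d) predict_probe_choice_bayes(cond2, d))
#> [1] 0.9148725 0.4013765 0.5466767
```

In part 1 the predicted preference for the narrow Gaussian falls from 97%
at the smallest array to 29% at the widest: wide arrays admit large shifts,
which only the bimodal model explains well. Widening $M_1$'s prior in
part 2 restores near-indifference (55%) at the widest array — the same
stimulus, judged differently because the competing model changed.

```r
# Simulate a 7-subject cohort driven by the Bayes-factor strategy,
# then let the five explanations compete on its probe choices
cohort <- simulate_cohort(cond1, cond2, n_subjects = 7,
                          strategy = "bayes_factor", seed = 17)
compare_explanations(cohort, cond1, cond2)
#> Model comparison over 1705 probe trials, 7 subject(s)
#> Negative log-likelihood by explanation (lower is better):
#>   1. bayes_factor          882.0
#>   2. policy_inference      957.0
#>   3. halfway              1047.5
#>   4. biggest              2032.0
#>   5. average              3132.1
```

The generating account wins; its Bayesian twin (policy inference) is
close, as the two differ only through curve-fitting noise, while the
average heuristic — which predicts width-independent choices — is ruled
out decisively.

The numbered scripts under `analysis/` run this pipeline end to end
(simulate → fit curves → predict → compare → model recovery), writing
tables under `results/`.

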