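---
title: "Signal-detection models of confidence and post-decision evidence integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-detection models of confidence and post-decision evidence integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdeconf)
```

## The generative model

`pdeconf` implements a signal-detection account of perceptual choice and
confidence in a two-interval dot-density discrimination. On each trial the
true side is $d \in \{-1, +1\}$ and the observer receives a pre-decision
internal sample

$$X_{pre} \sim \mathcal{N}(d\,\theta_{pre},\, 1),$$

with $\theta_{pre}$ the internal evidence strength (in internal-noise SD
units). The choice is $a = \mathrm{sign}(X_{pre} - m)$, where the criterion
$m$ absorbs stimulus-independent response biases; the fitting likelihood
treats this rule as a softmax with slope 1000, numerically a step, and
simulation uses the step with a fair-coin tie-break.

In the post-decision evidence task a second sample $X_{post} \sim
\mathcal{N}(d\,\theta_{post}, 1)$ follows the choice, with $\theta_{post}
\in \{\mu_{low}, \mu_{high}\}$ equally often. Because the observer does not
know which strength generated a sample, both samples are evaluated under a
single-Gaussian approximation of the equal mixture: mean $\mu =
(\mu_{low} + \mu_{high})/2$ and, by the law of total variance, $\sigma^2 =
((\mu_{high}-\mu_{low})/2)^2 + 1$ (`mixture_moments()`). In the confidence
task, where only one strength occurs, $\mu = \mu_{low}$ and $\sigma^2 = 1$.
Each sample contributes direction log-odds $LO_{dir} = 2\mu X / \sigma^2$;
conditioning on the action gives log-odds of being correct, and confidence
is the logistic transform of their sum.

Three variants modify the combination rule:

* **temporal weighting** — $w_{pre}\,LO^{corr}_{pre} + w_{post}\,LO^{corr}_{post}$;
* **choice weighting** — the post-decision term is scaled by
  $w_{confirmatory}$ when $\mathrm{sign}(X_{post}) = \mathrm{sign}(a)$ and
  by $w_{disconfirmatory}$ otherwise;
* **choice bias** — a fixed amount of subjective probability $w_{bias}$ is
  added to the chosen option on the *direction* log-odds before
  conditioning on the action, so the bias also shifts ratings in the task
  without post-decision evidence. With $w_{bias} = 0.5$ (and with unit
  temporal weights) the variants reduce exactly to the base model; these
  reductions are enforced by tests.

Confidence is clamped to $[10^{-6}, 1-10^{-6}]$ before the report stage so
log-odds round-trips stay finite. A report is the model confidence plus
Gaussian noise (`sigma_report`, probability units), clipped to $[0,1]$ and
snapped to the 9-point rating grid $\{0, 0.125, \dots, 1\}$; the 0–100%
labels of the on-screen scale are presentation only.

## What the simulator emulates

`run_calibration()` reproduces the calibration phase: a 2-down-1-up
staircase on the log dot difference (70 trials), the converged low strength
being the mean of the last 25 presented log strengths, with 50 additional
judgements at 1.3 times the current staircase log strength interleaved
after 20 burn-in trials. The stimulus grid holds 625 cells with 313 filled
in the reference square, so dot differences live in $[1, 312]$. The
staircase's accuracy asymptote is $\sqrt{0.5} \approx 70.7\%$; the
high-strength manipulation targets roughly 80% correct.

The staircase step (0.1 natural-log units) and start value (dot difference
70) are package defaults, stated as such, not inferences about the original
experiment. Physical-to-internal mapping is a power law $\theta = k (\log
\Delta)^{\gamma}$ with $\gamma = 1.6$ by default, chosen so the 1.3-fold
log-strength manipulation multiplies $\theta$ by $1.3^{1.6} \approx 1.52$
and carries a 71%-calibrated observer to about 80% correct; $\gamma = 1$ is
available for sensitivity checks. The default gain $k = 0.06$ places the
71% threshold near $\log\Delta \approx 4$, close to the staircase start, so
the 70-trial staircase converges with its last-25 average eliciting about
71% — the design target of the calibration procedure. Sessions comprise 120
calibration, 60 confidence-task and 120 post-decision-evidence-task trials;
task-2 conditions are interleaved with no more than four consecutive trials
of one level, and the physical post-decision evidence always favours the
true side (its internal sample may still land on either side).

Missed trials are independent Bernoulli lapses (default 1%) that blank the
choice and rating; confidence response times are lognormal with a 1500 ms
median so the 850 ms exclusion rule is exercisable. Neither mechanism is
described in the emulated study; both are stated defaults.

`generate_population()` adds the individual-differences structure: a
quadratic orientation-to-dogmatism relation (standardized 0.37), a linear
orientation-to-authoritarianism relation (0.38), a residual correlation of
0.21 between the two radicalism facets, and a standardized coupling of 0.18
between composite radicalism (the sum of the two z-scored facets) and the
logit of the generating choice-bias weight. The weight itself is lognormal
on the logit scale around 0.55 with SD 0.5; couplings of radicalism to
other observer parameters (e.g., report noise) are supported in the
configuration but off by default. Gender and education are integer-coded
nuisance covariates with no planted effect.

What passing tests on these data do *not* show: real raters drift, learn
and lapse in structured ways; real metacognitive variation is not reducible
to report noise plus a bias weight; and the questionnaire factor scores
here are draws from the planted structure, not refitted factor models.

## Metacognition metrics

`dprime_criterion()` is equal-variance SDT with 0.5 added to every cell of
the stimulus-response table, so extreme rates stay finite. `meta_d()` is a
maximum-likelihood estimator of meta-d′: the type-1 sensitivity an ideal
observer with the subject's type-1 criterion (held at the same relative
position) would need to produce the observed response-conditional
confidence distributions. Type-2 criteria are free parameters ordered away
from the meta criterion via log-increment parametrization; the multinomial
likelihood is maximized by `nlminb` from two starts, cells are padded by
$1/(2\,n_{bins})$, and the rating grid collapses automatically to the
levels the subject actually used (meta-d′ is invariant to monotone
relabelling, which the tests assert). A subject using a single rating level
is flagged `degenerate_confidence`. The emulated study estimated the same
quantity with a Bayesian scheme; the estimand, not the engine, is
reproduced here, and correctness is established against simulation oracles
(ideal observer: meta-d′ = d′; shuffled ratings: meta-d′ ≈ 0).

Confidence bias defaults to mean confidence minus proportion correct; raw
mean confidence is available behind a switch because the operational
definition in the source analyses is ambiguous. Earnings follow the
quadratic scoring rule, $1 - (\mathrm{accuracy} - \mathrm{confidence})^2$
per trial. d′ for the regression battery averages tasks 1 and 2.

Evidence-integration measures are ordinary least squares, as in the
emulated analyses: per-subject regressions of confidence on the evidence
code (confidence task 0, low 1, high 2) separately for correct
(confirmatory) and incorrect trials (disconfirmatory; sign-flipped so
higher means more integration), and a task-2-only model with accuracy
(±1), strength (1/2) and their interaction, whose interaction coefficient
summarizes sensitivity to post-decision evidence independently of task-1
based meta-d′. Missed trials are excluded listwise; an intercept is always
included; slopes are in confidence-probability units per evidence level.

## Model fitting

The original analysis used variational inference with per-trial latent
samples. Because the downstream analyses consume only parameter point
estimates, `fit_subject()` instead computes MAP estimates under the stated
priors, marginalizing the latent samples by deterministic midpoint
quadrature (61 nodes per dimension by default, 15 minimum; the pre-decision
sample over the half-line selected by the action, the post-decision sample
over ±8 SD). Priors: criterion $\mathcal{N}(0,1)$; report noise half-normal
with scale 0.1; weights $\mathcal{N}(1,1)$; bias weight $\mathcal{N}(0.5,1)$
on the probability scale, optimized on the logit scale; evidence strengths
are not fitted hierarchically but carry unit-SD priors centred on the
observed d′/2 at each strength, the high-strength d′ coming from the 50
high-strength calibration trials. Optimization is Nelder-Mead with one
informed start (observed type-1 statistics, prior-mean weights) plus
jittered restarts (five starts by default), followed by a fresh-simplex
polish whose failure to improve defines convergence. MAP on transformed
coordinates with priors on the natural scale is parametrization-dependent;
we accept this, since the target is a point estimate of the same estimand.

One deliberate departure from the source model: the rating likelihood is
interval-censored. The source treats the snapped rating as a continuous
value with Gaussian noise; under MAP that density is degenerate — the
confidence clamp concentrates an atom just below 1, so the likelihood
diverges as `sigma_report` → 0, and with a floor the noise pins at the
floor while `mu_low` inflates by ~25% even at 1200 trials. Scoring the
Gaussian mass inside the snapped grid cell (outer cells absorbing the
clipped tails) matches the generative report stage exactly, is well-posed
as the noise vanishes, and restores parameter recovery (report-noise
estimates land on the generating value). The quadrature likelihood is
compiled (Rcpp) with an R reference implementation (`trial_loglik()`)
tested equal to it; `outcome_probs()` independently recomputes the same
outcome probabilities in R and is checked against Monte-Carlo frequencies.

`fit_population()` fits subjects independently by default; its hierarchical
mode is a simple empirical-Bayes fixed point (group means/SDs of criterion
and weights re-estimated from subject fits, SDs floored at 0.05, up to
three passes), which the tests verify shrinks estimate variance for
homogeneous subjects. Report noise is fitted per subject under the group
half-normal prior rather than tied across subjects; the source's group
tying is implicit and the prior scale (0.1) dominates either way.
`posterior_predictive()` draws parameters from a Gaussian approximation
around the MAP (inverse transformed-scale Hessian) — 100 draws and 4000
trials per condition by default — and reports group means with 95%
intervals for the top radicalism decile versus the rest.

## Group-level battery

`robust_regress()` z-scores outcome and predictors, then delegates the
iteratively reweighted least-squares fit with Tukey bisquare weights
(tuning constant 4.685) to `MASS::rlm`, mirroring the "robust" option of
the original analysis software; standard errors come from the IRLS
solution at convergence and p-values use a t reference with $n - k - 1$
degrees of freedom. One-tailed testing halves the two-tailed p when the
sign matches the declared direction (the replication-sample convention).
Z-scoring happens before robust weighting; the alternative order is
unstated in the source. VIFs are $1/(1-R^2_j)$ with a warning above the
standard cut-off of 10; per-predictor $R^2$ is the full-versus-reduced
difference in explained variance. Regression BIC is $n \log(RSS/n) + k
\log n$ with $k$ counting slopes, intercept and error variance — the
constant cancels in the differences that are reported, and the best model's
difference is zero by construction.

`compare_models_radicalism()` regresses composite radicalism on
$\hat\mu_{low}$, $\hat\mu_{high}$ plus each variant's weight estimates, and
additionally on the single-weight reductions of the two-weight variants so
the bias model cannot win on parameter count alone. `quad_vs_linear()`
labels factor interrelations by BIC among linear, quadratic and two-term
fits; when the two-term model wins, the label follows the larger
standardized beta. Exclusions use strict inequalities — accuracy above 85%
or below 60%, one rating more than 90% of the time (missed trials removed
before the histogram), median confidence RT under 850 ms, more than 5%
missed — and are applied before any group analysis.

## Numerical choices

* Quadrature: midpoint rule; truncation at ±8 SD; node count configurable
  with a documented minimum of 15 per dimension. Population-scale runs in
  the tests use 41 nodes and 1–2 starts after verifying on pilot subjects
  that estimates move by < 0.02 relative to the 61-node five-start
  configuration.
* Report-noise floor $10^{-3}$; confidence clamp $10^{-6}$; rating-kernel
  support cut at 8 noise SDs beyond the cell edge.
* Degenerate regressions: constant outcomes give zero betas; RSS is floored
  at $10^{-12}$ so BIC stays finite for perfect fits.
* Ties at the decision criterion are a fair coin from the session RNG;
  everything is reproducible given a seed.

## Problem sizes used by the checks

The packaged checks run at sizes chosen to exercise the claims while
staying desk-scale: 100 observers for the calibration targets; 20,000
trials for the meta-d′ oracles; a 20-point parameter sweep with $10^5$
Monte-Carlo trials per point for the likelihood oracle; 50 subjects at 180
trials (plus one 10,000-trial subject) for parameter recovery; 20
replicates of a 60-subject population for the model-comparison recovery
check; and a 400-subject population — the scale of the emulated samples —
for the qualitative radicalism signature.

## Known limitations and an honest negative result

Two end-to-end expectations about the synthetic population are not met, and
the analysis of why is itself informative. First, with radicalism coupled
only to the choice-bias weight (the default, matching the reported
standardized association of 0.18), the bias mechanism mainly produces
*overconfidence*: it inflates confidence-task ratings on error trials so
strongly that the pooled tasks-1+2 disconfirmatory slope *increases* with
the bias weight over its plausible range. Within task 2 alone the
confidence drop under stronger disconfirmatory evidence does shrink with
the bias weight (asserted by the integration tests for a strongly biased
observer), but at the planted coupling of 0.18 the top-decile contrast of
that drop is smaller than its sampling noise at realistic n. A regression of
dogmatism on the metric battery therefore shows a robustly elevated-error-
confidence decile pattern but only a weak negative meta-d′ beta and no
reliably negative disconfirmatory beta: that empirical signature is not a
consequence of the bias mechanism alone in this regime. Second, the
model-comparison recovery is near chance at realistic sample sizes: weight
estimates from the rival variants proxy the planted bias weight at
correlations of 0.75–0.85, leaving a BIC margin of roughly $0.008\,n$ for
the bias regression — about a coin flip at $n = 400$ and ~55% at $n = 600$.
A single observed BIC ranking of these models at a few hundred subjects
should accordingly be read as weak evidence about the generating mechanism.
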