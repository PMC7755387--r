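---
title: "Models and methods in moodrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in moodrl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`moodrl` implements the analysis pipeline for a two-car "race" bandit in
which momentary happiness is probed alongside choices. This vignette is the
package's own account of the models, the estimators, and the design choices
made where several reasonable options existed. Everything stated here about
behaviour of the estimators is computed by the package's test suite or by
`scripts/acceptance.R`; this document explains *why* things are set up the
way they are.

## The task

Two cars race on every trial and exactly one wins — a one-armed bandit,
because the two outcomes are perfectly anticorrelated. The better car wins
with probability 0.8, enforced *exactly*: within every 10-trial sub-block
the better car wins on exactly 8 trials, in uniformly random order. In the
stable environment the better car is fixed for all 80 trials; in the
volatile environment it reverses every 20 trials (so reversals fall at
trials 21, 41 and 61, 1-based). Offered rewards are drawn uniformly with
replacement from ten fixed (left, right) point pairs:
10–10, 10–40, 10–60, 10–80, 20–40, 40–10, 40–20, 40–40, 60–10, 80–10.
Reward magnitude is therefore independent of outcome probability, which is
what lets the pipeline dissociate learning-relevant from learning-irrelevant
influences on mood. A happiness probe ("How happy are you right now?",
0–100) occurs every 3–4 trials.

Two presentation details are generated but deliberately inert: the screen
side of each car (swapped every 6–10 trials) is cosmetic metadata, because
beliefs attach to car identity, not side; and the initial better car is a
coin flip under the seed. Trial indexing is 1-based throughout.

```{r}
library(moodrl)
sched <- generate_schedule(task_config("volatile"), seed = 1)
mean(sched$winner == sched$best_car)  # exactly 0.8, by construction
plot_schedule(sched)
```

## Learning and choice

All choice models share one Rescorla–Wagner learner over the win
probability. Because the race outcome is fully observed, a single latent
belief suffices: the belief about car B is always `1 - p_A`. The belief
starts at 0.5 at the start of each environment and is never reset —
reversals are unsignalled, so the learner must track them through
prediction errors:

\[
P_{t+1} = P_t + \alpha\,(o_t - P_t), \qquad \text{PPE}_t = o_t - P_t ,
\]

with learning rate \(\alpha \in [0,1]\) and outcome \(o_t \in \{0, 1\}\).

Four selectors map beliefs and offered rewards to a choice probability via
a logistic with inverse temperature \(\beta \in [0, 50]\):

* **additive**: \(\text{logit}^{-1}\!\big(\beta[\phi\,\Delta P +
  (1-\phi)\,\Delta R]\big)\) with \(\Delta P = 2P-1\), \(\Delta R\) the
  offered-reward difference divided by 80 (the maximum reward), and
  probability–magnitude weight \(\phi \in [0,1]\);
* **multiplicative**: expected-utility style,
  \(EU = \mathrm{clip}(\eta(P-0.5)+0.5,\,0,\,1)\times R/80\) with
  distortion \(\eta \in [0,10]\) (the clip is applied *after* the linear
  distortion); at \(\eta = 1\) this reduces to \(P \times R\);
* **probability-only** (\(\phi\) fixed at 1) and **magnitude-only**
  (\(\phi\) fixed at 0, no learner).

Rewards are rescaled by the maximum reward in *both* the additive and
multiplicative selectors. The shared \(\beta\) bound of 50 presumes value
differences of order one; with raw point rewards (differences up to 80)
most of the \(\beta\) range saturates the logistic, the log-likelihood
surface develops flat plateaus, and gradient-based fitting from random
starts fails. Rescaling keeps \(\eta\) and \(\alpha\) untouched and makes
\(\beta\) comparable across selectors.

Per-subject fitting is bounded maximum likelihood (L-BFGS-B) with 10
uniform-random restarts inside the bounds and a tight function tolerance;
the restarts are reproducible under a seed. Fits report
\(\mathrm{BIC} = k\ln n - 2\,\mathrm{LL}\) and McFadden's pseudo-r²,
\(1 - \mathrm{LL}/(n \ln 0.5)\), against the fair-coin chance likelihood.
McFadden's variant is a choice the package makes explicitly: several
pseudo-r² conventions exist and nothing in the analysis depends on which
one is used, as it never enters model selection.

```{r}
ses <- simulate_agent(sched, choice_params(0.47, 10, 0.44), seed = 2)
fit <- fit_choice_model(ses, "additive", seed = 3)
glance(fit)
```

## Momentary happiness

Eleven regression models explain each rating as a baseline plus weighted,
exponentially decaying sums of trial histories with a shared forgetting
factor \(\gamma \in [0,1]\):

\[
\text{Happiness}(t) = w_0 + \sum_{\text{terms}} w
  \sum_{j=1}^{t} \gamma^{\,t-j}\, x_j .
\]

The decayed sums run over *all* trials 1..t, not only rated ones, and a
rating is attributed to the most recent completed trial — the probe appears
after the outcome, so that trial's prediction error is part of the history.
The terms (see `happiness_models()`) combine subjective quantities, rebuilt
by replaying the learner at a fitted or supplied learning rate (chosen
probability \(\hat P\), \(\widehat{\text{PPE}}\),
\(\widehat{\text{RPE}} = r/80 - \hat{EV}\) with
\(\hat{EV} = \hat P \times R/80\)), their objective counterparts computed
from the scheduled 0.8/0.2 contingencies, obtained reward relative to its
session mean or to a fitted reference point \(RP \in [0, 80]\) points, and
plain win/loss indicators (entering as \(+w_{win}\) and \(-w_{loss}\)).
Reward-history terms stay in points so \(RP\) has point units;
prediction-error terms use rewards rescaled to [0, 1]. Parameter counts
match the model family's convention: \(w_0\) and \(\gamma\) are counted,
the Gaussian noise scale is profiled out and not counted (so the
\(\widehat{\text{PPE}}\)-only model has k = 3).

**Fitting.** For a fixed \(\gamma\) the model is linear, so the weights are
profiled out by ordinary least squares; \(\gamma\) is then the only
nonlinear parameter and is optimised on a dense grid (step 0.01) followed
by local refinement with `optimize()`. The grid makes the search global —
the decayed-regressor likelihood can be multimodal in \(\gamma\), which is
what the joint-then-separate fitting protocol guards
against; that two-stage protocol is still available
(`fit_happiness_two_stage()`), where the joint fit's \(\gamma\) seeds an
extra local refinement per environment. The reference-point model stays
linear through the reparameterisation
\(w\,D(R) - (w\,RP)\,D(1)\), where \(D\) is the decayed sum; \(RP\) is
read off as the coefficient ratio and, if it falls outside [0, 80], fixed
at the bound and the model refit. Fits report both the squared correlation
of predicted and observed ratings (`r2`) and variance explained (`r2_ve`),
and BIC from the concentrated Gaussian likelihood with n = number of
ratings.

Ratings are z-scored within subject and environment before fitting
(`zscore = TRUE`), as when comparing subjects who use the rating scale
differently; fitting raw 0–100 ratings (for baseline-mood analyses)
constrains \(w_0\) to [0, 100] via `w0_bounds`. Whether z-scoring is done
within environment or across the whole session is configurable only in the
sense that the user controls what they pass in; the package default is
within-environment, which keeps per-environment fits self-contained.

Degenerate inputs are flagged rather than fitted: constant ratings return a
`"degenerate"` fit, and an essentially flat \(\gamma\) profile (as with
pure-noise ratings) is flagged `"flat_gamma"` while still returning the
least-squares weights.

**A useful identity.** If the probability and PPE weights of the
\(\hat P + \widehat{\text{PPE}}\) model are equal, the two terms collapse:
\(w(\hat P - 0.5) + w(o - \hat P) = w(o - 0.5)\), an exponentially weighted
average of past wins. The package tests this identity to machine precision;
it is the algebraic reason the win–loss model is a serious competitor, and
why *unequal* fitted weights are informative about an influence of
probability estimates beyond win history.

## Model comparison

Fixed-effects comparison sums BIC across subjects (`compare_fixed()`),
reporting differences to a reference model. Random-effects comparison
(`rfx_bms()`) treats the model identity as a random effect with an unknown
population distribution: per-subject log evidences (approximated by
−BIC/2, a deliberate, reproducible stand-in for toolbox-specific
free-energy approximations) drive a variational Dirichlet scheme with a
uniform prior (\(\alpha_0 = 1\)), iterating subject-wise posterior model
assignments and the concentration update to convergence. The exceedance
probability — the posterior probability that a model is the most frequent
in the population — is estimated by sampling the fitted Dirichlet (10⁶
draws keeps the Monte-Carlo error below 0.001); ties in the argmax are
broken at random, which matters only in exactly symmetric cases. Only
within-subject evidence differences matter; the implementation normalises
per subject, which also guards the exponentials against overflow.

## Group statistics

Win-stay/lose-shift conditions staying (by car identity) on the previous
outcome and on whether the previously chosen car was the high- or
low-probability car under the contingency in force on that trial; empty
cells yield `NA` and drop out of group tests. Choice accuracy is the
proportion of trials choosing the higher objective-expected-value option,
with tied-EV trials (10–10, 40–40, and the 40–10-type ties at 0.2/0.8)
excluded from the denominator — both objective probabilities are written
out directly so ties are exact in floating point. Group-level inference
uses a two-sided Wilcoxon signed-rank test implemented to expose the
tie-corrected, continuity-corrected normal z statistic (with the exact
distribution for small untied samples; `stats::wilcox.test` does not
report z, but the implementation is cross-checked against it), and
Spearman correlations via `stats::cor.test` with the asymptotic
t-approximation. The standardised-difference analysis z-scores a
per-subject quantity within each environment, takes volatile − stable, and
rank-correlates it with the standardised symptom score.

Two model-free checks mirror the model-based ones: a per-subject OLS of
ratings on the 10 most recent PPEs (only ratings with at least 10
preceding trials enter; earlier ratings have no full lag window and are
excluded), and the rank correlation between
win–loss-model residuals and the trial-by-trial probability estimate.

## The synthetic cohort

`generate_cohort()` stands in for an archived human dataset: 75 subjects,
both environments, 80 trials each, ratings every 3–4 trials, and a
PHQ-like 0–27 symptom score. It generates what the analyses *assume*:

* **Choice parameters** are drawn per environment from truncated normals
  at the group means (stable \(\alpha\) 0.16, \(\phi\) 0.57; volatile
  \(\alpha\) 0.47, \(\phi\) 0.44; \(\beta\) 10 with SD 2.5 — \(\beta\) is
  not among the reported group statistics, so a moderate spread around the value
  used in the recovery experiments is assumed). Population SDs are
  reconstructed from the reported group SEMs as \(\mathrm{SEM}\times\sqrt{75}\).
  The truncated draws are *mean-matched*: the location parameter is solved
  so the post-truncation mean equals the target, since the target means
  are means of bounded empirical distributions.
* **Happiness parameters** for the generating \(\hat P +
  \widehat{\text{PPE}}\) model likewise (stable \(w_P\) 0.74,
  \(w_{PPE}\) 1.32, \(\gamma\) 0.59; volatile 0.94, 1.14, 0.63). By
  default one \(\gamma\) per subject is shared across environments — the
  forgetting factor behaves like a trait — drawn from the average of the
  two environments' distributions; `gamma_trait = FALSE` gives independent
  draws for sensitivity analyses.
* **Ratings** are produced from the generative model on the z scale plus
  i.i.d. Gaussian noise with SD 0.6, at which the model explains about 60%
  of rating variance, then mapped to the slider as
  \(w_0 + 15\,(\text{prediction} + \text{noise})\) and clipped to
  [0, 100]. The 15-point scale factor and the clipping are configurable;
  the generator reports the clipped fraction (about 7% at defaults — a
  bounded scale cannot carry the default between- and within-subject
  spreads under a Gaussian model without mass at the ends; real raters
  compress near the ends instead of clipping, which is one of the ways the
  generator is *not* a model of real data).
* **Symptoms and mood** are tied by a Gaussian copula. The symptom latent
  couples to both environments' baseline moods — weakly positive with
  stable mood (+0.07), negative with volatile mood (−0.28) — with a
  cross-environment baseline-mood correlation of 0.22. This triple is what
  makes the standardised volatile − stable mood difference correlate with
  symptoms at about the volatile coupling itself; coupling the symptom to
  volatile mood alone would cap that correlation at \(\rho/\sqrt 2\). The
  latent correlation carries a single calibrated inflation factor that
  offsets the attenuation from discretising the symptom score to 0–27
  integers and from the dilution of baseline mood in observed mean
  happiness by weight heterogeneity and rating noise, so the *observed*
  analyses on generated cohorts exhibit the target correlations. Symptom
  scores follow a negative-binomial marginal (mean 6, SD ≈ 4.2) truncated
  at 27. Parameters are drawn independently across subjects and across
  parameter types; the true cross-subject covariance is unknown and
  independence is the documented assumption.

What passing recovery tests on such cohorts shows is that the *pipeline*
is consistent: data generated under the assumed model, at the default
group parameters and realistic noise, give back those parameters and the
correct model ranking. It does not show that human data satisfy those
assumptions — no synthetic cohort can.

## Recovery experiments and their problem sizes

The acceptance script and the recovery tests use 75 subjects and 80-trial
sessions — the task's native dimensions — with 10 optimiser restarts per
choice fit; smaller replicate cohorts (n = 20) are used only to check the
sign of the volatile-minus-stable learning-rate difference across
replicates, where the effect is an order of magnitude larger than its
standard error.

Two deliberate choices in the recovery harness:

* **Term histories at the generating learning rate.** When the happiness
  stage is given term histories built from each subject's *fitted*
  \(\alpha\), the estimation noise in \(\alpha\) propagates into the
  \(\hat P\)/\(\widehat{\text{PPE}}\) series and attenuates the recovered
  forgetting factor noticeably, while leaving the PPE weight essentially
  unbiased. The recovery experiments therefore replay the learner at the
  generating \(\alpha\), isolating the identifiability of the happiness
  model itself from learner-estimation noise. The full-pipeline route
  (fitted \(\alpha\)) remains the default for real or raw cohorts — as in
  the swapped-learning-rate analysis, which shows \(\gamma\) estimates are
  robust to which \(\alpha\) builds the histories.
* **No re-standardisation of z-scale ratings.** Recovery fits on ratings
  generated on the z scale use `zscore = FALSE`: z-scoring data whose
  total SD is not exactly 1 rescales every weight by the realised SD and
  would bias the comparison of recovered to generating weights. Raw 0–100
  cohorts are fitted with `zscore = TRUE`, as the rating-scale-use
  argument requires.

## Known limitations

* The generator assumes Gaussian rating noise, independent parameters
  across subjects, and hard clipping at the scale ends; none of these are
  claims about human raters.
* Log model evidence is approximated by −BIC/2; Laplace or free-energy
  evidences would weight parameter uncertainty differently.
* The outcome pseudo-randomisation enforces only the 8-of-10 rule; any
  additional run-length constraints a particular experiment imposed would
  make its schedules a subset of the ones generated here.
* Forgetting factors near 1 make the win and loss decayed histories nearly
  collinear with the intercept; the win–loss baseline is then poorly
  determined (which is why raw-rating fits bound it to the rating scale).
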