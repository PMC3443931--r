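---
title: "Audio-visual bisection and the MLE integration model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audio-visual bisection and the MLE integration model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avbisect)
```

# The task and the generative model

In a bisection task the observer sees (and/or hears) three brief stimuli
and reports whether the middle one was closer — in time or in space — to
the first or to the third. The probe offset $x$ is the displacement of the
second stimulus from the physical midpoint of the outer two, positive
towards the third stimulus; the response is coded 1 for "closer to third".
Two task domains are implemented:

* **temporal bisection** (units ms): three stimuli over 1000 ms, five
  interleaved conditions — vision only, audition only, and three bimodal
  conditions with audio-visual conflict $\Delta \in \{-50, 0, +50\}$ ms.
  The conflict is stored as the *half-conflict* applied to the second
  stimulus (its auditory component leads or lags its visual component by
  $\Delta$), while the outer stimuli carry the opposite offset $-\Delta$;
  the effective audio-visual separation of the probe from the outer pair
  is therefore $2\Delta$, i.e. up to 100 ms. 150 trials per session
  (30 per condition).
* **spatial bisection** (units deg): three stimuli along a speaker array,
  the second always 500 ms after the first, seven interleaved conditions —
  two unimodal and five bimodal with
  $\Delta \in \{0, \pm4.5^\circ, \pm9^\circ\}$, the second stimulus'
  visual component displaced by $+\Delta$ and its auditory component by
  $-\Delta$, outer stimuli audio-visually aligned. 210 trials per session.

A simulated observer has unimodal noise levels $\sigma_V, \sigma_A$ (the
SDs of its internal estimates, in task units) and a combination rule for
bimodal trials. Writing $e_V, e_A$ for the displacement of the second
stimulus relative to each cue's *own* midpoint (`cue_offsets()`), the
internal decision variable is $e = w_V e_V + w_A e_A$ and

$$P(\text{response}=1 \mid x) \;=\;
  \tfrac{\lambda}{2} + (1-\lambda)\,\Phi\!\left(e/\sigma_\mathrm{eff}\right),$$

with lapse rate $\lambda$ (default 0, matching a lapse-free fitted model).
The rules are: `optimal` (variance-ratio weights, harmonic
$\sigma_\mathrm{eff}$, below), `visual_capture` ($w_V=1$,
$\sigma_\mathrm{eff}=\sigma_V$), `auditory_capture` ($w_A=1$,
$\sigma_\mathrm{eff}=\sigma_A$), and `fixed_weights`
($\sigma_\mathrm{eff}^2 = w_V^2\sigma_V^2 + w_A^2\sigma_A^2$).

# The MLE integration model

For an observer weighting cues by their reliability, the bimodal
estimate is $\hat S_{VA} = w_V \hat S_V + w_A \hat S_A$ with

$$w_V = \frac{\sigma_A^2}{\sigma_A^2 + \sigma_V^2},\qquad
  w_A = 1 - w_V,\qquad
  \sigma_{VA}^2 = \frac{\sigma_V^2 \sigma_A^2}{\sigma_V^2 + \sigma_A^2}
  \le \min(\sigma_V^2, \sigma_A^2),$$

the improvement reaching $\sqrt 2$ when $\sigma_V = \sigma_A$. With the
cue standards displaced symmetrically at $\pm\Delta$ about the neutral
midpoint, the predicted point of subjective equality (PSE) is

$$\hat S(\Delta) = w_V\Delta - w_A\Delta = (1-2w_A)\,\Delta,$$

so the slope of PSE against conflict identifies the weights:
$w_A = (1-\hat S'(\Delta))/2$. Total visual dominance gives slope $+1$,
total auditory dominance $-1$. The package estimates the weights both
ways — from unimodal thresholds (`weights_from_thresholds()`) and from
the per-observer ordinary-least-squares PSE-conflict slope
(`slope_from_pses()` + `weights_from_slope()`) — and never clips
slope-derived weights that fall outside $[0,1]$ (clipping would bias
group comparisons of the two estimates; they are flagged instead).

## Sign bookkeeping: raw fits versus the symmetric frame

Psychometric fits report the PSE on the *probe-offset axis*: the $x$ at
which the two responses are equally likely. Under the generative model
this raw PSE is $-2 w_A \Delta$ in the temporal task (where only the
auditory geometry is shifted, asymmetrically, by $2\Delta$) and
$(2 w_A - 1)\Delta$ in the spatial task (where a probe must be moved to
$-\Delta$ to null a $+\Delta$ visual displacement). Both are mapped to
the common symmetric frame of $\hat S(\Delta)$ by `conflict_pse()`,
*after* bias correction: time $S(\Delta) = (\mu_\Delta - \mu_0) + \Delta$,
space $S(\Delta) = -(\mu_\Delta - \mu_0)$. In this frame visual dominance
lies on the $+\Delta$ line and auditory dominance on the $-\Delta$ line
in both domains, which is what the slope-weight relation above assumes.
The factor-2 temporal bookkeeping lives entirely in `cue_offsets()`.

Constant response biases (e.g. the first interval tending to appear
longer) are removed by subtracting the zero-conflict PSE from every
conflict condition's PSE (`bias_correct()`); the $\Delta=0$ entry is 0 by
construction, and — because the $\Delta=0$ point anchors the regression —
the correction affects only the intercept of the slope fit, never the
slope.

# Adaptive placement

Probe offsets are chosen by a QUEST-style Bayesian track per condition
(three or five run simultaneously across the bimodal conflicts, one per
unimodal condition). The track keeps a discrete posterior over candidate
bisection points (201 grid points spanning the prior mean $\pm$ 4 prior
SDs, and at least $\pm3$ assumed slopes), updates it with the
cumulative-Gaussian likelihood of each response (likelihood floored at
$10^{-10}$ to avoid $\log 0$), and recommends the posterior *mean*
(smoother than the mode on a coarse grid; the mode is available as an
option). Each placement adds zero-centred Gaussian jitter so that the
flanks of the psychometric function are sampled as well as the steep
region, and the two responses stay equally likely on average. Defaults —
assumed slope 120 ms / 15°, jitter SD 100 ms / 10°, prior SD equal to the
assumed slope — are of the order of child unimodal thresholds; they are
explicit knobs of `bisection_design()` and `quest_track()`, not claims
about any particular experiment.

# Fitting

Each condition's raw binary trials are fitted by maximum likelihood with
$P(1\,|\,x) = \Phi((x-\mu)/\sigma)$, maximizing the Bernoulli likelihood
directly (adaptive placements are uneven and unbinned, so no binned least
squares), parameterized as $(\mu, \log\sigma)$ with an L-BFGS-B search
started from the probit-regression closed form — refits of identical data
are identical. No lapse parameter is fitted by default. A fit whose
$\log\sigma$ reaches the box bounds (three decades around the placement
spread — in practice, perfectly separated responses) is flagged, never
silently clipped; its PSE remains usable. Standard errors are
nonparametric case-resampling bootstraps (default 100 replicates, seeded;
failed replicates are dropped and counted, with a warning above 20%).

The pooled bimodal threshold uses all conflict conditions: each
condition's trials are recentred on that condition's fitted PSE, the
recentred trials pooled, and a single cumulative Gaussian with $\mu$
fixed at 0 fitted (bootstrap resampling within condition). Recentring
removes the conflict-dependent PSE shifts that would otherwise inflate
the pooled $\sigma$; pooling without recentring is available
(`recenter = FALSE`). Recentring on *estimated* PSEs absorbs a little
genuine noise, so the pooled estimate carries a small downward bias at 30
trials per condition — visible in the parameter-recovery experiment and
covered by its bootstrap-SE-scaled tolerance.

# Group-level evaluation

The explained-variance statistic for a group compares measured
bias-corrected PSEs $S_i$ with model predictions $\hat S_i$ over all
observers and conflicts ($N$ points):

$$R^2 = 1 - \frac{1}{\hat\sigma^2 + \sigma^2}\cdot\frac1N
        \sum_{i=1}^N (S_i - \hat S_i)^2,$$

where $\hat\sigma^2$ and $\sigma^2$ are the variances of the predicted
and measured sets. Both are read as *population* variances (denominator
$N$): then a constant prediction at the data mean gives exactly $R^2=0$,
perfect prediction gives 1, and anti-correlated predictions can go
negative. An alternative reading of $\hat\sigma^2$ (bootstrap variance of
the predictions) would change the normalization only; it is not the
default. The statistic is invariant under a common change of units.

Bimodal thresholds are tested against the MLE prediction with a
one-sample, one-tailed t-test on the per-observer differences, direction
fixed as measured $>$ predicted — the direction of failure to reach the
optimal (lower) bound. Stars at $p<0.05$ and $p<0.01$; no multiple-testing
correction across age groups by default (a Bonferroni option exists),
matching the per-group convention of developmental threshold plots.
Across-subject (not across-bootstrap) testing is used. With fewer than
two observers in a group the SEM is reported as undefined rather than 0.

# What the synthetic cohorts emulate — and what they cannot

`default_cohort()` encodes a stylized developmental pattern per domain:
three child groups governed by unisensory capture (auditory capture in
time, visual capture in space) and an adult group integrating optimally.
Unimodal precision matures with age where the task rewards it — temporal
thresholds fall from 160/150 ms (visual/auditory, youngest) to
120/70 ms (adult), and visual spatial thresholds from 7° to 2.5° — while
auditory *spatial* thresholds stay poor (6–8°) at all ages, audition
being the weaker spatial sense. Child groups are given *comparable* unimodal
thresholds — as unimodal precision is still maturing — which is also what
makes single-modality capture measurably sub-optimal: when one cue is far
better than the other, capture by the better cue is nearly
indistinguishable from optimality at these trial counts.

These observers are stationary, lapse-free Bernoulli responders with
exactly Gaussian internal noise and a hard-wired combination rule. Real
children drift, lapse, and may mix strategies; inter-subject parameter
spread here is generated only by sampling noise, not by true individual
differences. Passing the pipeline's tests therefore shows that the
*analysis recovers what the generative model put in* at the study's
design size — it does not certify behaviour on real data, and no claim is
made about reproducing any particular empirical dataset (none is bundled).

# Problem sizes and numerical choices

The package's validation suite runs at the sizes its questions need and
no more, chosen as follows:

* **Parameter recovery** (`parameter_recovery()`): 100 optimal observers
  on the spatial design, $\sigma_V \sim \log U(2.5, 10)$°,
  $\sigma_A \sim \log U(5, 20)$° (four-fold ranges spanning child-to-adult
  spatial precision). The spatial design is used for weight recovery on
  power grounds: the slope-derived $w_A$ has standard error roughly
  $\sigma_\mathrm{eff}\sqrt{c/n}\,/\,(2\sqrt{\sum\Delta^2})$ with
  $c \approx 2$ for adaptive placement, so a $\pm 0.12$ recovery band at
  $n=30$ trials/condition requires $\sigma_\mathrm{eff}$ comparable to
  the conflict span — true for spatial thresholds against
  $\sqrt{\sum\Delta^2} \approx 14^\circ$, not true for ~100 ms temporal
  thresholds against $\pm 50$ ms conflicts. Pooled-threshold agreement is
  assessed in bootstrap-SE units (4 SEs), which correctly widens for
  observers whose per-condition data carry little slope information.
* **Developmental cohorts**: 10 observers per age group, 30
  trials/condition, 100 bootstrap replicates — a realistic single-study
  size. Pilot runs of the cohort at several seeds were used, before
  freezing the validation thresholds, to locate robust bands for the
  qualitative signature (capture-group slopes beyond $\pm0.75$, adult
  slopes within 0.2 of their weight prediction, high explained variance
  only in the optimally integrating spatial adult group, threshold stars
  only in capture groups). Group-level $R^2$ with threshold-based
  predictions from 30-trial unimodal fits is intrinsically noisy; in the
  temporal domain even a perfect integrator's $R^2$ is capped well below
  1 at this design size because PSE measurement noise is large relative
  to the $\pm50$ ms conflict span. The near-1 check is therefore
  evaluated where it is attainable, in the spatial adult group.
* **Oracle checks**: the ML fit is compared against an exhaustive 2-D
  likelihood grid search on ≤200-trial fixtures; t-test p-values against
  the exact $2^n$ sign-flip permutation distribution at $n \le 10$;
  Monte-Carlo response frequencies against the analytic model at $10^5$
  draws (3 binomial SDs).

Degenerate inputs are handled explicitly: single-class response sets
refuse to fit (naming the condition); a missing zero-conflict condition
stops bias correction; zero-variance difference sets flag the t-test as
degenerate ($t=0$, $p=0.5$ when the mean is 0); a single bootstrap
replicate yields SE 0 with a degenerate flag.

# Reproducibility

Every stochastic step descends from one root seed: observer seeds are
derived deterministically from the root seed and the observer label, and
simulation restores the caller's RNG state. A cohort configuration plus
seed determines every output byte (up to floating-point platform
variation). Session tables serialize to flat CSV with explicit units
columns; configurations and seeds are recorded in a JSON manifest.

# Known limitations

* The forced-fusion MLE model is the only combination model evaluated —
  no causal-inference or partial-integration variants.
* Bootstrap SEs only (as is conventional for this fitting pipeline); no
  full Bayesian posterior over $(\mu, \sigma)$.
* The pooled bimodal threshold's recentring bias (above) is small but
  not corrected.
* The adaptive-track parameters are fixed per domain, not tuned per
  observer; very precise observers relative to the jitter SD yield
  per-condition slope estimates that can saturate (flagged), with the
  pooled estimate and PSEs remaining informative.
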