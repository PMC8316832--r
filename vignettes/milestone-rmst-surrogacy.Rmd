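---
title: "Milestone survival and RMST as trial-level surrogates for overall survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Milestone survival and RMST as trial-level surrogates for overall survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milesurv)
```

## The problem

First-line chemo-immunotherapy trials in extensive-stage small cell lung
cancer (ES-SCLC) violate the proportional-hazards assumption in a
characteristic way: the overall-survival (OS) curves of the experimental and
control arms overlap or cross for roughly the first six months, separate
afterwards, and a minority of patients form a long-term-survivor plateau in
the tail. Under these kinetics a single hazard ratio compresses the curve
into a number whose meaning drifts with follow-up, and the median — control
median OS in this disease is only 8–10 months — sits in the region where the
curves have barely separated. Two model-free alternatives summarize the
curve where immunotherapy acts: the **milestone survival rate**, the
Kaplan–Meier estimate S(τ) at a prespecified clinically meaningful time, and
the **restricted mean survival time** (RMST), the area under the survival
curve from 0 to a horizon τ — the mean survival time truncated at τ.

`milesurv` asks the *trial-level surrogacy* question: across randomized
comparisons, how well does the treatment effect on a candidate endpoint
(milestone-rate ratio at 12 months, RMST ratios at 12 and 24 months, the PFS
hazard ratio, relative risks for response and disease control) predict the
treatment effect on OS?

## The surrogacy model

Each experimental arm is compared with its trial's (possibly shared)
control arm, so a three-arm trial contributes two comparisons. For
comparison *i* with surrogate effect $s_i$ (uniformly
experimental/control) and OS hazard ratio $\mathrm{HR}_{OS,i}$, the model
is a weighted least-squares line on double-log axes:

$$\min_{a,b}\ \sum_i w_i\,\big(\log_{10}\mathrm{HR}_{OS,i} - a -
  b\,\log_{10} s_i\big)^2, \qquad w_i = n_i,$$

with $n_i$ the combined randomized size of the two arms. Surrogacy strength
is reported as the weighted coefficient of determination

$$R^2 = 1 - \frac{\sum_i w_i e_i^2}{\sum_i w_i\,(y_i - \bar y_w)^2},$$

which in this single-regressor model equals the squared weighted Pearson
correlation of the two log effects, together with the Spearman rank
correlation of the untransformed pairs and two-sided tests (slope *t* test,
identical here to the overall *F* test; Spearman *p* by the *t*
approximation with $n-2$ degrees of freedom, with an exact enumeration
available for $n \le 10$).

Design choices where the convention was genuinely open:

* **Log base.** Base 10 on both axes. Slope, $R^2$ and all p-values are
  invariant to the shared base; only the intercept changes. Configurable
  via `log_base`.
* **Weights.** "Sample size" is read as the combined randomized n of the
  two arms in the comparison; any other positive column can be supplied
  via `weight_col`.
* **Ratio direction.** Experimental/control uniformly, for every
  surrogate. With this convention a beneficial drug has milestone/RMST
  ratios above 1 and HRs below 1, so the fitted slope for those ratios is
  negative. Published analyses are not always explicit about the
  orientation of extracted ratios, and a flipped orientation flips the
  sign of the Spearman r and slope (but not $R^2$); results should be
  compared sign-aware.
* **Complete cases per surrogate.** A comparison missing one surrogate is
  excluded from that surrogate's fit only, so each candidate can have its
  own n; at least 3 usable comparisons are required for a fit.

## Estimation from subject-level records

`kmFit()` is the product-limit estimator over distinct event times with the
Greenwood variance; censoring shrinks the risk set without a step.
`milestoneRate()` evaluates the right-continuous step at τ; its confidence
interval applies the Greenwood SE on the complementary log-log scale
(`conf_scale = "plain"` gives the clipped Wald interval), the standard way
to keep survival-probability intervals inside [0, 1]. `rmst()` integrates
the step function exactly and uses the standard integrated-Kaplan–Meier
variance
$\widehat{\mathrm{Var}} = \sum_j A_j^2\, d_j / \{n_j (n_j - d_j)\}$, where
$A_j$ is the remaining area from event time $t_j$ to τ. `coxHR()` maximizes
the two-group partial likelihood with **Efron** tie handling (less biased
than Breslow under the heavy ties that month-resolution data produce) by
Newton–Raphson to relative tolerance 1e-8, capped at 100 iterations with a
diagnostic error on failure.

Estimation never extrapolates: a τ beyond the last observed (event or
censoring) time is an error unless `extrapolate = TRUE`, which
carries the last survival value forward and warns.

## Estimation from digitized curves

Published trials rarely share subject-level data, so the second pathway
consumes (time, survival) coordinates read off published Kaplan–Meier
figures. Raw digitizer output is noisy: `cleanCurve()` sorts by time,
collapses duplicate times to their minimum survival (a step at that time),
clamps to [0, 1], enforces monotonicity by a running minimum and anchors
the curve at (0, 1) — a time-0 coordinate below 1 is treated as
digitization noise and reset. Cleaning is idempotent and its output always
satisfies the step-curve invariants.

`rmst()` on a clean curve integrates the **right-continuous step function**
through the coordinates — a Kaplan–Meier curve *is* a step function, so
this is the default; a trapezoid mode is kept as a sensitivity option for
digitizers that sample slanted segments. On a non-increasing curve the step
value is always ≥ the trapezoid value, since each segment contributes its
left (larger) survival. Curve-derived milestone rates and RMSTs carry no
standard error: the figure does not contain the variance information.

## What the simulator emulates — and what it does not

`trialScenario()`/`simulateArm()` generate subject-level data with the
structure the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `control_hazard` | rate `log(2)/10` /month | exponential control OS, median 10 months — the upper end of the 8–10-month range typical of ES-SCLC |
| `delay_months` | 6 | months before the experimental hazard ratio switches on; reproduces the early curve overlap of immunotherapy trials |
| `hr_post_delay` | 0.7 | hazard ratio after onset (< 1 is benefit), one per experimental arm |
| `cure_fraction` | 0 | mixture proportion of never-event long-term survivors in experimental arms (the tail plateau) |
| `accrual_months`, `admin_cutoff_months` | 14, 40 | uniform accrual and administrative censoring, sized so 24-month horizons stay within every arm's follow-up |
| `dropout_rate` | 0.005 /month | exponential loss to follow-up |
| `orr_*`, `dcr_*` | 0.58/0.62, 0.80/0.85 | per-arm response probabilities, DCR ≥ ORR by construction; values typical of platinum–etoposide ± checkpoint inhibition |
| `pfs_hazard_mult` | 2 | PFS hazard = OS hazard × multiplier, then clipped to PFS ≤ OS (median PFS ≈ 5 months) |

OS times come from inverse-transform sampling of the piecewise-exponential
cumulative hazard; the delayed effect is a hazard-ratio step at
`delay_months` (the simplest mechanism producing the described curve
kinetics), and the cure fraction is a mixture, not a hazard plateau, so the
analytic survival is $S(t) = c + (1-c)e^{-H(t)}$ with closed-form RMST
(`scenarioSurvival()`, `scenarioRmst()` expose these as ground truth for
recovery checks). `simulateTrialSuite()` sweeps `hr_post_delay` across
trials, runs the full estimation chain per trial and attaches the true
generative effects. One suite seed drives everything: per-trial sub-seeds
are drawn once up front, so the suite is reproducible as a whole.

The emulated digitizer (`digitizeEmulator()`) samples a uniform time grid
(or the exact step corners, which makes the round trip lossless), adds
truncated Gaussian noise on the survival axis and shuffles a few adjacent
points.

What is *not* modeled: calibration to any specific published trial's
curves; a joint frailty model for the PFS–OS dependence (only the ordering
PFS ≤ OS is enforced, so simulated PFS hazard ratios track OS ones more
tightly than real trials, where PFS and OS effects can genuinely diverge);
informative censoring; and number-at-risk tables, which real curve
reconstruction can exploit. Passing simulation tests therefore demonstrate
that the *pipeline* recovers known generative relations, not that any
particular real-world endpoint is a valid surrogate.

## Numerical and testing choices

Problem sizes were chosen to make Monte-Carlo noise small relative to the
asserted tolerances: closed-form exponential checks use 50,000 subjects
(relative error < 2%), distribution-level sampler checks 100,000
(Kolmogorov distance < 0.01), digitization round trips 100 coordinates
with survival jitter SD 0.005 (RMST relative error < 2%), and end-to-end
surrogacy recovery 10 trials of 1,000 subjects per arm with post-delay
hazard ratios spanning 0.5–1.1 and no onset delay, where the induced
log-linear relation yields $R^2 \ge 0.9$ with a negative slope. The WLS
fit is checked against a brute-force normal-equation solution to 1e-10,
and the two-group Cox fit against an established proportional-hazards
implementation to 4 decimals.

Degenerate inputs are policy, not accidents: an all-censored arm yields
S ≡ 1 with an empty event grid; a zero-responder experimental arm gives
relative risk 0 with a warning while a zero-responder control arm is an
error; constant ranks are an error in the Spearman statistic; and at S = 0
or 1 the milestone interval collapses to the point estimate (the
complementary log-log transform is undefined there).

## Limitations

Trial-level surrogacy only: nothing here estimates patient-level
association. With a handful of comparisons (the motivating setting has 9)
the regression is fragile — single comparisons can dominate the weighted
fit, and $R^2$ from n ≤ 10 points has wide sampling variability. RMSTs
extracted from figures inherit digitization error that the 2% round-trip
bound quantifies only under the noise model above. And milestone/RMST
ratios share estimation noise with the OS hazard ratio when both come from
the same curves, which can inflate apparent association relative to
independently reported effects.
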