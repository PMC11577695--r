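---
title: "Adaptive enrichment designs from joint models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive enrichment designs from joint models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette explains the statistical machinery implemented in `enrichjm`,
the assumptions it rests on, and the design decisions taken where a choice
had to be made. It is the package's account of its own methods; every
empirical claim made here is recomputed by the test suite or by
`scripts/acceptance.R`, not asserted from memory.

## The problem

A two-arm trial recruits from a population split into two pre-defined
subgroups — in the motivating metastatic breast cancer setting, HER2-negative
(S1, prevalence $\lambda$) and HER2-positive (S2) patients — with overall
survival as the primary endpoint and a longitudinal biomarker (circulating
tumour DNA) measured repeatedly on every patient. The working belief is that
the experimental treatment helps S1 and possibly everyone. An adaptive
enrichment design runs an interim analysis once a planned number of S1 events
has occurred, selects the population that shows benefit (S1, S2, the full
population F, or none), optionally stops early for efficacy or futility, and
otherwise continues to a final analysis in the selected population only.

Two error rates drive the design: the familywise error rate
$\alpha$ — the probability of rejecting any true null hypothesis
$H_{0,j}\colon \theta_j \ge 0$ (effects are log hazard ratios; negative means
benefit) — and conditional power, the probability of rejecting $H_{0,1}$
given that S1 was selected, targeted at $1-\beta$.

## The joint model and the conditional score

The working model couples a linear latent biomarker trajectory with a
proportional-hazards survival model:

$$X_i(v) = b_{0i} + b_{1i} v, \qquad D_i(v) = X_i(v) + \varepsilon_i(v),
\qquad h_i(t) = h_0(t)\,\exp\{\gamma X_i(t) + \theta \psi_i\},$$

with subject-level random effects $(b_{0i}, b_{1i})$ bivariate normal,
independent Gaussian measurement errors with variance $\sigma^2$, and
$\psi_i$ the treatment indicator. Plugging the observed $D$ into a Cox model
attenuates $\gamma$ and distorts $\theta$; the conditional-score method
avoids this by conditioning on a sufficient statistic for the random
effects. For each subject the trajectory is re-estimated at every event time
$t$ by ordinary least squares on the measurements up to $t$, giving
$\hat X_i(t)$ with $\mathrm{Var}(\hat X_i(t)) = \sigma^2 \psi_i(t)$ where
$\psi_i(t)$ is the usual regression leverage
$1/s + (t-\bar v)^2/\sum(v-\bar v)^2$. The sufficient statistic
$S_i(t) = \hat X_i(t) + \gamma\sigma^2\psi_i(t)\,dN_i(t)$ replaces the latent
$X_i(t)$ in an estimating equation of partial-score form; risk sets admit
only subjects whose second measurement predates $t$, because two points are
needed to fit a line. The estimates $(\hat\gamma, \hat\theta)$ are the root
of this score with the pooled residual variance $\hat\sigma^2$ (residual sums
of squares over $m_i - 2$ degrees of freedom, subjects with more than two
measurements) plugged in.

The treatment-effect information is the sandwich
$I = n\,[(A^{-1} B A^{-\top})_{22}]^{-1}$ with $A$ the per-patient average
numeric Jacobian of the score and $B$ the per-patient average outer product
of the per-subject score contributions; $A$ is differenced numerically
(central differences, step $10^{-5}\max(1,|\cdot|)$). The standardized
statistic uses the benefit-positive convention $Z = -\hat\theta\sqrt{I}$, so
that benefit maps to large positive $Z$ and the worked design numbers
(threshold $\zeta = 0.674$ at drift $|\delta|\sqrt{I}$) come out as printed;
the hypotheses themselves are one-sided in $\theta$.

Two comparator analyses are provided with the same interface: a plain Cox
model ignoring the biomarker, and a Cox model with the observed biomarker as
an error-free time-varying covariate (last observation carried forward).
Both are fitted by Newton iteration on the partial-likelihood score; the
package's tests check them against `survival::coxph` on counting-process
data to $10^{-6}$.

## The simulator

`simulate_trial()` generates cohorts from the working model with the
defaults calibrated to the breast-cancer setting: $\lambda = 2/3$,
$\gamma = 0.8$, $\sigma^2 = 0.25$, random-effect moments
$\mu = (4.23, 1.81)$, $(\phi_1, \phi_{12}, \phi_2) = (2.5, 1.7, 5)$, and a
piecewise-constant baseline hazard of $0.0085$/year before one year and
$0.0142$/year after. Patients arrive deterministically at 2 per week,
alternate 1:1 between arms within subgroup, and are measured at entry, every
2 weeks to week 12, then every 4 weeks ("month" = 4 weeks; time is in years
with a week $= 7/365.25$ years). Latent event times invert the cumulative
hazard in closed form piece by piece; because the hazard grows like
$e^{\gamma b_1 t}$, subjects with $\gamma b_1 < 0$ can have bounded total
hazard and never fail (a cure fraction), which administrative censoring
handles naturally.

Choices worth flagging:

* **Baseline visit.** A measurement at entry ($v=0$) is included; the
  trajectory fit needs two early points before a subject can enter risk
  sets, and without a baseline visit almost no early events would be usable.
* **Dropout.** Loss to follow-up is exponential and independent. A nominal
  rate of $5\times10^{-5}$/year is irreconcilable with roughly 10% of
  patients being lost before their event, so the default rate (0.0917/year)
  was calibrated by `calibrate_censor_rate()` so that 10% of patients whose
  event would occur are lost first, under the null defaults. Subjects who
  would never fail are excluded from that definition — they are censored
  eventually at any rate.
* **What the generator does not emulate.** Nonlinear trajectories, treatment
  effects on the biomarker, informative dropout, staggered site activation,
  and uncertainty in $\lambda$ are all out of scope; passing tests say
  nothing about robustness to those features.

## Planning the design

`design_config()` holds the targets: $\alpha = 0.025$, power $0.9$, design
effect $|\delta| = 0.5$, $\lambda = 2/3$, and interim selection targets
$P(W{=}1) = 0.6$, $P(W{=}F) = 0.2$ under the alternative
$\Theta_A: \theta_1 = -0.5, \theta_2 = 0$.

**Threshold and interim information.** With independent standard-normal
interim statistics, the two selection-probability equations have the closed
form $\zeta = \Phi^{-1}(p_1/(p_1+p_F)) = 0.674$ and
$I_1^{(1)} = ((\zeta + \Phi^{-1}(p_1+p_F))/|\delta|)^2 = 9.19$;
`solve_threshold_and_info()` also offers a two-dimensional numeric solve as a
cross-check.

**Events per unit information.** Event-driven analyses need to convert
information targets into event counts, using $I = d/m$.
`calibrate_information_rate()` estimates $m$ by replicate simulation under
$\Theta_A$: replicate cohorts are censored at a grid of S1 event counts, the
analysis method is fitted to each, and the information at a grid point is
the inverse sampling variance of $\hat\theta$ across replicates — the
definition of information. The alternative of reading the sandwich estimate
off a single large dataset was examined and rejected: at interim scale the
sandwich systematically overstates information in this model (mildly at the
defaults, severely for large $\sigma^2$), so event counts planned from it
underpower the trial. Because information per event does not depend on the
subgroup label, the subgroup-2 curve is pooled into the power-law fit of
information against events, and the constants are evaluated at the design's
own information target. Event counts are expressed per unit of
subgroup-1-scale information, which makes the ratio identities
$m_2 \approx (1-\lambda)m_1/\lambda$ and $m_F \approx m_1/\lambda$ hold and
keeps $d_1^{(1)} = \lceil m_1 I_1^{(1)} \rceil$ a per-event relation in S1.

**Boundaries and maximum information.** Error is spent as
$f(t) = \min(\alpha t^2, \alpha)$ and $g(t) = \min(\beta t^2, \beta)$ of the
full-population information fraction. The stage-1 efficacy boundary solves
the global-null tail-mass equation summed over the selectable populations
(a futility stop selects nothing and can reject nothing, so it contributes
no rejection mass); the stage-2 boundary solves the conditional-tail
equation weighted by the stage-1 joint density of (statistic, selection) —
without that weight the expression is not a probability. Because power is
defined conditionally on selecting S1 while the joint density integrates to
$P(W{=}1) \approx 0.6$, the futility equations spend
$\beta^{(k)} P(W{=}1;\Theta_A)$; spending an unconditional $\beta$ would cap
conditional power at $1 - \beta/P(W{=}1) \approx 0.83$ no matter how many
events are collected.

`solve_imax()` searches for the maximum information at which the final
boundaries meet ($a_2 = b_2$), planning along the information path a trial
actually realizes when information accrues in proportion to events: at the
interim $I_2 \approx \tfrac{1-\lambda}{\lambda} I_1$ and (through the
prevalence-weighted combination) $I_F = I_1/\lambda$; at the final analysis
every selectable population has observed $d^{(2)}$ of its own events and so
reaches the same information $d^{(2)}/m_1 = I_{\max}$. The total event
target is $d^{(2)} = \lceil m_1 I_{\max}\rceil$. An alternative bookkeeping
found in the literature relabels the same solve with
$\tilde I_j^{(1)} = I_1^{(1)}$ for every population and an
$I_{\max}$ smaller by the factor $\lambda$; the event counts agree once the
scales are matched, but only the per-event path matches what a running trial
measures, which matters because trials here spend error at realized
information.

**The full-population statistic.** $Z_F$ combines the subgroup estimates as
$\hat\theta_F = \lambda\hat\theta_1 + (1-\lambda)\hat\theta_2$ with
$I_F = (\lambda^2/I_1 + (1-\lambda)^2/I_2)^{-1}$. Its joint density with the
selection event is a convolution of two scaled normals truncated to
$Z_1 > \zeta, Z_2 > \zeta$; the truncation limits are enforced in the
quadrature and validated against Monte-Carlo draws in the tests.

## Running a trial

`run_trial()` simulates a cohort, snapshots it when the planned number of S1
events has occurred, fits the chosen method per subgroup, applies the
threshold rule ($Z_j > \zeta$; both exceedances select F, neither stops the
trial), and tests only the selected hypothesis. Spent error is recomputed
from the *realized* interim information — the error-spending paradigm's
guarantee holds for any information path only if the spend tracks what was
observed — and the stage-1 boundaries are re-solved accordingly. If the
trial continues, the final snapshot is taken at the planned total event
count in the selected population; stage-2 information for unobserved
populations is predicted by linear event scaling
(`predict_information()`), and the entire remaining error budget is spent at
this terminal analysis (the trial ends there; capping the spend at a
predicted information fraction below one systematically discards rejection
probability that the design paid events for). The final hypothesis test
rejects when the selected population's statistic exceeds $b_2$, with
$a_2 = b_2$ binding.

`operating_characteristics()` replicates whole trials, running all requested
analysis methods on the same simulated datasets so that method differences
are not confounded with simulation noise, and reports selection
frequencies, familywise error, conditional power and binomial Monte-Carlo
standard errors. Replicates whose score equation has no root are counted and
reported, and the run aborts if they exceed 5%.

## Numerical choices

* Newton root finding with numerically differenced Jacobians; convergence at
  $\|U\|_\infty < 10^{-8} d$; restarts from $(0, 0)$, $(0, \pm 0.5)$.
* Gauss–Legendre quadrature (cached nodes; 80–160 points) for the selection
  densities; boundary equations solved to $10^{-10}$ by bracketed root
  finding with tails truncated at $\pm 8$.
* Event-time ties are impossible in simulated (continuous) data; file-based
  input is handled with Breslow tie handling in the comparators and stable
  subject-id ordering elsewhere.
* Single-stream seeding: one `set.seed()` call reproduces a whole study
  because every random draw is made in a fixed vectorised order.

## Problem sizes

Calibration uses cohorts of 1600 patients per replicate over a five-point
event grid, with 150 replicates by default (interactive planning) and
300–500 in the package's test suite and in `scripts/acceptance.R`, where the
planned event counts are checked to a ±10% band; trial cohorts are
1400–1500 patients and operating characteristics use 500 trial replicates.
All sizes are arguments, so larger reproductions (the reference analyses
used $10^4$ trial replicates) are one call away.

## Known limitations

* The canonical joint distribution holds only approximately for the
  conditional-score statistics; the observed interim-to-final correlation
  runs slightly below $\sqrt{I^{(1)}/I^{(2)}}$ at trial-sized event counts.
  Familywise error is protected by the spending construction regardless, but
  attained power can sit a percentage point or two below target.
* At large measurement-error variance ($\sigma^2 \gtrsim 2$) the sandwich
  information overstates precision at interim scale, making the interim
  statistics overdispersed and error control there anticonservative — the
  regime the sensitivity analyses flag as needing inflated event counts and
  at least 20 events per subgroup before the root is trustworthy.
  `solve_score()` warns below 20 events.
* With $\lambda$ fixed and known; unknown prevalence is out of scope.
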