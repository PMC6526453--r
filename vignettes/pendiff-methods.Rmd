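---
title: "Diffusion-model analysis of paper-based response times: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-model analysis of paper-based response times: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pendiff)
```

## The scientific problem

Paper-based speed tests are still standard instruments in cognitive aging
research, but classical paper administration cannot record item-level
response times, so process models of two-choice decisions could not be
applied to them. Digital pens change that: each checkmark leaves a
timestamped stroke, and the response time of item $i$ on a page can be
computed as the time difference between consecutive responses. `pendiff`
implements the full analysis chain for such an experiment — a lexical
decision task in which participants judge letter strings as words or
nonwords — from stroke logs to group-level statistics, together with a
synthetic-data generator that makes every stage testable by parameter
recovery.

## The diffusion model

The Ratcliff diffusion model describes a two-choice decision as a Wiener
process with drift $v$ that starts at $z = z_r\,a$ between two absorbing
boundaries $0$ and $a$ and accumulates evidence until a boundary is
reached. The observed response time is the first-passage time plus a
nondecision time $t_0$ (encoding and motor execution). The within-trial
diffusion coefficient is fixed at $s = 1$, which scales all other
parameters. Across trials, drift varies normally with SD $s_v$, the
relative starting point uniformly with full width $s_{zr}$, and the
nondecision time uniformly with full width $s_{t0}$; these variabilities
let the model produce both fast and slow errors.

For absorption at the lower boundary the first-passage density (with
$z = z_r a$) is

$$
g_-(t) = \frac{\pi}{a^2} \exp\!\Big(-v z - \frac{v^2 t}{2}\Big)
\sum_{k \ge 1} k \sin(k \pi z_r)
\exp\!\Big(-\frac{k^2 \pi^2 t}{2 a^2}\Big),
$$

with the upper-boundary density obtained by the reflection
$(v, z_r) \to (-v, 1 - z_r)$. The package evaluates two series
representations: the Fourier (large-time) form above, and for
$t/a^2 < 0.12$ the image (small-time) expansion, choosing the
representation by the scaled time so both tails are computed stably. The
defective CDF integrates the large-time series term by term with adaptive
truncation; per-node results are clamped to the admissible defective range
so that extreme parameter probes during optimisation cannot return values
outside $[0, P_\text{boundary}]$ even where the series cancels badly.

Choices and response times of one condition are represented jointly as a
*signed RT sample*: upper-boundary ("word") responses keep $+\mathrm{rt}$,
lower-boundary responses are negated. The model counterpart is the signed
CDF $G$, which rises from 0 through the lower-boundary choice probability
at $x = 0$ to 1. Across-trial variabilities are integrated out by
deterministic quadrature: Gauss–Hermite nodes for the normal drift
distribution and Gauss–Legendre nodes for the two uniform distributions.
The mixed defective CDFs are computed on a decision-time grid and
interpolated linearly at the sample points; at the default resolutions the
combined quadrature-plus-interpolation error of $G$ is a few $10^{-4}$,
two orders of magnitude below the Kolmogorov–Smirnov distances the
objective works with ($\approx 10^{-2}$).

## Simulation

`simulate_trials()` draws trials by Euler discretisation with step
`dt = 2e-4` s. Discretely monitored boundaries systematically miss
excursions between steps, an $O(\sqrt{dt})$ bias; the simulator therefore
applies the Broadie–Glasserman–Kou continuity correction (boundaries moved
inward by $0.5826\sqrt{dt}$), after which the simulated signed CDF agrees
with the analytic one to sup-distance below 0.01 at $n = 10^5$ — the
package's three-way consistency check between simulator, density series
and quadrature.

## Estimation

Each participant is fitted separately. Drift rate and relative starting
point are condition-specific (the word and nonword conditions differ in
stimulus quality and allow opposite response bias); boundary separation,
nondecision time and the three variabilities are shared across conditions.
A control model with a single shared starting point is available
(`share_zr = TRUE`).

The objective follows the Kolmogorov–Smirnov tradition: for each condition
the sup distance $D_c$ between the empirical signed CDF and $G_c$ is
converted to the Kolmogorov tail probability
$p_c = Q\big(D_c(\sqrt{n_c} + 0.12 + 0.11/\sqrt{n_c})\big)$, and the
search maximises $\log p_w + \log p_{nw}$ — p-values rather than raw
distances so that conditions with different trial counts are weighted
comparably. Two refinements proved necessary in recovery experiments:

* **Window conditioning.** RTs are trimmed to $[0.25, 3.5]$ s before
  fitting (see below), so the sample is truncated. Comparing it against
  the *unconditioned* model CDF biases the fit toward parameter sets that
  place no mass outside the window (drift up, drift variability down).
  The objective therefore conditions $G$ on the trimming window — exactly
  the distribution the kept data follow. With the window around 0.4% of
  the model mass, the correction is small but systematic.
* **A plateau tie-break.** For well-fitting parameter sets both p-values
  saturate at 1 and the objective becomes flat, leaving parameters free to
  drift. A small penalty $0.01\sum_c D_c \sqrt{n_c}$ keeps the search
  pointed toward smaller distances inside the plateau while being
  negligible wherever the p-values carry information.

Minimisation uses Nelder–Mead (SIMPLEX). Starting values are moment-based
(EZ-style closed forms from accuracy and correct-RT mean/variance, with
edge-corrected accuracies; $t_0$ starts at 90% of the fastest RT and the
starting points at a damped response-proportion asymmetry). Because the
objective is nearly flat in the variability parameters, restarts do not
merely jitter the start (±15% on the main parameters) but cycle the
variability parameters through a coarse low/high lattice — plain jitter
around one value never explores those directions. Each restart runs two
chained Nelder–Mead passes (restarting rebuilds the simplex, which
recovers progress lost to simplex collapse), and the best restart receives
two polishing passes at a tighter tolerance. Parameter bounds
($a \in (0.1, 10)$, $|v| < 10$, $z_r \in (0.02, 0.98)$ with the
starting-point range inside $(0,1)$, $t_0 > 0.05$ s,
$t_0 - s_{t0}/2 <$ fastest RT, variabilities non-negative) are enforced by
a penalty value rather than transforms, keeping the simplex geometry
simple. Note the lower-edge bound couples $t_0$ and $s_{t0}$: with
nondecision variability the fastest trials arrive near $t_0 - s_{t0}/2$,
so bounding $t_0$ itself by the fastest RT would exclude the generating
parameters of realistic data.

A fit is reported as converged when a Nelder–Mead pass meets its relative
tolerance or a polishing pass no longer improves the objective
meaningfully ($<10^{-4}$).

In recovery experiments at the default study conditions (1005 trials per
condition, parameters at the younger-adult group means), the
across-participant mean estimates of $v$, $a$, $t_0$ and $z_r$ fall within
about 6% of the generating values; the variability parameters are
noisier (held to a 30% standard in the tests), which matches their known
weak identifiability under KS fitting.

## Trimming

RTs below 250 ms or above 3500 ms are eliminated before fitting
(inclusive window). Trimming is listed with the analysis defaults because
pen-lift artifacts and page transitions produce physically impossible
RTs; fitting untrimmed data would let single outliers dominate the sup
distance.

The experiment's bookkeeping contains one subtlety: the first stimulus of
each page is a *reference* item that anchors the RT chain and never enters
the analysis, and a missing response breaks the chain — the following
item's RT cannot be computed across the gap. Practice sessions are flagged
(`is_practice`) but retained in the default analysis; the design's
stimulus arithmetic (2211 printed items, 201 references, 2010 analysed)
is only consistent with retention, and a configuration switch can exclude
them.

## Goodness of fit and its calibration

A participant's model-level fit statistic is the minimum of the two
condition p-values — conservative and monotone in both. Because the KS
test's power grows with trial count, large experiments flag even
excellent fits at the nominal $\alpha = 0.01$; the package therefore
calibrates the criterion by parametric bootstrap: parameter vectors are
drawn from a multivariate normal with the mean and covariance of the
fitted cohort (redrawn until the invariants hold; a singular covariance
falls back to its diagonal with a warning), datasets with empirically
resampled trial counts are simulated and refitted with the same
configuration, and the critical value is the empirical $\alpha$ quantile
(inverse-ECDF convention) of the resulting model p-values. Participants
below the calibrated value are flagged, and the statistical stage can be
rerun without them as a sensitivity analysis.

## Group statistics

Analyses operate on participant-level values, never pooled trials.
Condition-varying quantities (correct RT, accuracy, drift, starting
point) enter balanced 2 (age group) × 2 (condition) mixed ANOVAs computed
by classical sums of squares: group is tested against subjects within
groups, condition and the interaction against condition × subjects within
groups. Effect sizes are partial $\eta^2 =
SS_\text{effect}/(SS_\text{effect} + SS_\text{error,effect})$ for F tests
and $t^2/(t^2 + df)$ for t tests (the literature this mirrors reports
bare $\eta^2$ without stating a flavour; the partial convention is the
common one for mixed designs). Each ANOVA is followed by the family of
four simple effects — two independent-sample t-tests (pooled variance)
between groups within condition, two paired t-tests between conditions
within group — Bonferroni-corrected by the family size of four.
Parameters shared across conditions ($a$, $t_0$, variabilities) are
compared with pooled-variance t-tests. Nonword drifts are sign-flipped
before ANOVA so that "better performance" points the same way in both
conditions. The vocabulary analysis reports the Pearson correlation
between word drift and vocabulary score and the partial correlation
controlling the binary age-group indicator.

## The synthetic cohort generator

The generator emulates the study conditions end to end: 67 sessions × 3
pages × 11 stimuli with page-initial reference items; placeholder words
(random consonant-vowel strings, 5–7 letters, 46.7% labelled
low-frequency) with nonwords derived by replacing every vowel by a
different plain vowel (keeping `u` after `q`, mapping umlauts to plain
vowels); per-participant true parameters drawn independently per parameter
from the group means and SDs (the published tables give no covariances;
the only induced dependence is the vocabulary–word-drift coupling,
correlation 0.5, which the correlation stage must recover); 20
participants per age group; and a 2% contaminant fraction, uniform inside
the trimming window with coin-flip responses, so that trimming alone
cannot remove contaminants and the fit diagnostics are genuinely
stressed. Recovery experiments set the contamination to zero and the
between-person SDs to zero so that deviations measure estimator bias, not
population spread.

Stroke logs are synthesised so that `strokes_to_trials()` inverts them
exactly: timestamps are integer milliseconds (the emulated pen
resolution), and the generated trial table is itself derived from the
stroke log. One stimulus schedule is shared by all participants of a
cohort, as in a printed test booklet.

What the generator does *not* emulate: item-level word-frequency effects
on drift, sequential dependencies between trials, motor-time differences
between "yes" and "no" checkmarks, or real German lexical material.
Passing recovery tests therefore shows that the estimation and statistics
chain is correct under the model's own assumptions, not that the model is
adequate for any particular empirical dataset.

## Numerical choices

* Series truncation: adaptive with bounds $\sim 10^{-10}$ per term
  (density target $10^{-9}$); representation switch at $t/a^2 = 0.12$.
* Quadrature defaults: 20 Gauss–Hermite / 10 Gauss–Legendre nodes and a
  400-point grid for `predicted_signed_cdf()`; the fit objective uses a
  leaner 10/6/280 configuration whose CDF error (a few $10^{-4}$) is
  irrelevant at the objective's scale but roughly halves fit time. Both
  are configurable.
* Euler step `dt = 2e-4` s with the continuity correction above.
* The bootstrap quantile uses the inverse-ECDF (type 1) convention.
* Problem sizes in the test suite: recovery uses 10 participants per
  group at the full design size (1005 + 1005 trials); the distributional
  property checks use $10^5$-trial simulations; the bootstrap
  self-consistency check runs 30 simulations of a 6-participant cohort
  with variabilities fixed at zero. These sizes keep every Monte-Carlo
  band used by the tests well above its sampling noise.

## Known limitations

* KS-based fitting identifies the variability parameters weakly; their
  estimates should be interpreted as order-of-magnitude.
* The KS p-values assume a fully specified null; after fitting they are
  optimistic, which is exactly why the bootstrap calibration exists.
* The Euler simulator, although corrected, remains a discretisation; the
  analytic formulas define the fit, the simulator only generates data.
* Mixed ANOVAs assume the balanced 2 × 2 design of this study type;
  unbalanced group sizes are handled, unbalanced conditions are not.
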