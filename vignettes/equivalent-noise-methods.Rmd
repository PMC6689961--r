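---
title: "Equivalent-noise analysis of contour integration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-noise analysis of contour integration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqnoise)
library(dplyr)
```

## The scientific problem

Contour integration — binding local oriented elements into a single
extended contour by good continuation — can fail in two distinct ways: the
representation of each element can be noisy (elevated *internal noise*),
or the system can be poor at combining the elements it has (reduced
*integration efficiency*). The equivalent-noise technique separates the
two by measuring discrimination thresholds while known amounts of external
orientation noise are added to the stimulus. Thresholds that are flat at
low external noise and rise proportionally beyond a knee are summarized by
the two-parameter Linear Amplifier Model (LAM):

$$A_{\mathrm{threshold}}(\sigma_{\mathrm{ext}}) =
  \frac{\sqrt{\sigma_{\mathrm{ext}}^2 + \sigma_{\mathrm{int}}^2}}{\beta}.$$

$\sigma_{\mathrm{int}}$ (degrees of orientation) is the external-noise
level equivalent to the system's own variability — it moves the knee.
$\beta$ scales thresholds down at every noise level without moving the
knee. Elevated internal noise with preserved efficiency is therefore a
specific, identifiable signature, distinguishable from a global loss of
sensitivity.

This package implements the complete measurement and analysis chain as a
simulation pipeline: parametric contour stimuli, a stochastic observer
whose behaviour embodies the LAM, the adaptive staircase used to place
trials, Gumbel psychometric fitting, LAM estimation, and the rank-based
factorial inference — plus a cohort generator so every stage runs end to
end with no external data. The package's purpose is parameter recovery:
showing that when cohorts are generated with a group difference in
internal noise only, the pipeline recovers exactly that structure.

## The task and the stimulus model

Each simulated trial of the four-alternative forced-choice (4AFC) task
shows four contours, one per visual-field quadrant at 2.8 deg
eccentricity, each made of seven log-Gabor wavelets (6 cycles/deg peak
spatial frequency, 1.6 octave bandwidth, ±25 deg orientation bandwidth,
envelope FWHM 1.17/0.91 cycles along/across the stripes, 400 ms
presentations). One contour is *valid*: every element's orientation is
aligned with the tangent of an invisible curved path. The other three are
distractors whose element orientations are reflected about the contour's
chord — the orientation field of a contour curving the opposite way, with
positions unchanged. The observer picks the smoothest contour; chance is
25%. External noise adds independent Normal(0, $\sigma_{\mathrm{ext}}$)
orientation jitter per element, at 0, 8 or 16 deg SD in separate blocks.

The path geometry is deliberately simple. The description of the
stimulus pins the number of elements and the wavelet parameters but not
the exact path, so the package makes one concrete, documented choice: a
circular arc whose chord is fixed at 1.4 deg (placing seven elements
about 0.23 deg apart) and whose *sagitta* — the perpendicular distance
from chord midpoint to arc — is the scalar "curvature amplitude" that the
staircase controls. Chord orientation is drawn uniformly per quadrant per
trial and the curvature sign is randomized, so no fixed orientation cue
survives. Orientation arithmetic lives on the circle of period 180 deg,
with differences folded into (−90, 90].

Two consequences of this geometry are worth noting. The valid-distractor
orientation difference at each element is an odd function of amplitude
that vanishes at zero curvature, so at amplitude 0 target and distractors
are identical and performance is exactly at chance. And beyond roughly
0.3 deg of sagitta the doubled-angle separation between valid and
distractor orientations passes 90 deg and begins to *fold back*, making
very strongly curved contours harder to discriminate again — the same
qualitative failure at the top of the amplitude range that motivates the
high-amplitude screening rule in the psychometric fitting.

A pixel renderer (`render_stimulus()`) exists purely as a fixture for
inspection: cosine-phase wavelets under a Gaussian envelope derived from
the configured FWHMs. No analysis operates on pixels.

## The simulated observer

No observer model is dictated by the experimental description, so the
package uses the simplest rule whose thresholds provably follow the LAM.
The observer perceives each element's orientation corrupted by
independent internal noise ($\sigma_{\mathrm{int}}$, degrees), pools a
random subset of $\lceil \text{efficiency} \times 7 \rceil$ elements
(redrawn per quadrant per trial), and scores each quadrant by template
matching on the doubled-angle circle:

$$\mathrm{score} = \sum_{i \in \text{subset}}
  \cos 2(\theta_i^{\mathrm{perc}} - \theta_i^{\mathrm{valid}}) -
  \cos 2(\theta_i^{\mathrm{perc}} - \theta_i^{\mathrm{distractor}}),$$

choosing the arg-max (ties uniform; with probability `lapse` the response
is uniform). Writing $\delta_i$ for the tangent deviation from the chord
and $\varepsilon$ for the total orientation noise, the per-element score
is $2\sin(2\varepsilon + 2\delta_i)\sin 2\delta_i$ for the target, so
both its mean separation and its SD scale with $\sin 2\delta_i$ and the
decision signal-to-noise ratio is proportional to
$\delta / \sqrt{\sigma_{\mathrm{ext}}^2 + \sigma_{\mathrm{int}}^2}$ for
small angles — the LAM, by construction, with internal and external noise
entering through their quadrature sum. The test suite verifies this
empirically: simulated threshold-versus-noise curves are fit by the LAM
with $R^2 > 0.95$ and recover the generating $\sigma_{\mathrm{int}}$
within 25%.

Efficiency is modelled as element subsampling rather than multiplicative
decision noise; the two are not distinguishable from threshold data of
this design, and $\beta$ should be interpreted only through the LAM fit.
The fraction-pooled-to-$\beta$ mapping is monotone increasing and can be
tabulated with `calibrate_efficiency_beta()`.

## The staircase

Amplitude is tracked by a transformed 2-down-1-up rule: divided by the
current step factor after two consecutive correct responses, multiplied
after every error, converging where $P(\mathrm{correct}) = \sqrt{1/2}
\approx 70.7\%$. Runs terminate at 40 trials or 12 reversals, whichever
comes first. Step sizes and the summary rule are not pinned by the
experimental description, so the package adopts standard adaptive-methods
practice and documents it: multiplicative steps of $10^{0.1}$, shrinking
to $10^{0.05}$ after 3 reversals; the converged amplitude is the
geometric mean of post-shrink reversal amplitudes; the starting amplitude
defaults to half the upper amplitude bound (clearly suprathreshold, here
0.15 deg of sagitta with bounds [0.002, 0.3]). These choices only affect
where trials are placed — thresholds for analysis come from psychometric
fitting of all trials, not from the staircase summary. The
consecutive-correct counter resets after every triggered step, stated
explicitly because variants change convergence slightly.

## Psychometric fitting and the high-amplitude screen

Per subject, quadrant and noise level, binned trials are fit by maximum
likelihood with a Gumbel function of log10 amplitude,

$$p(x) = \gamma + (1 - \gamma - \lambda)
  \left(1 - e^{-10^{\,\mathrm{slope}\,(x - \alpha)}}\right),$$

with the guess rate fixed at $\gamma = 0.25$ and the lapse rate free in
[0, 0.05] per cell. The log10 parameterization matches the
multiplicative staircase; the threshold is $10^\alpha$, the point where
the function has risen $1 - e^{-1}$ of its range ($p \approx 0.72$ at
$\lambda = 0$, consistent with the staircase's 70.7% placement). The
optimizer is a small multi-start grid (threshold over the data range,
slopes 0.5–4) followed by bounded quasi-Newton refinement with an
analytic gradient; degenerate all-correct/all-wrong cells return flagged
boundary fits rather than failing.

Because very strongly curved contours can become hard to discriminate
again, the highest-amplitude point of a cell is dropped — at most twice,
never below 3 remaining points — when the fit is poor (goodness-of-fit
chi-square p < 0.05 against the saturated binomial model) *and* dropping
the point improves the deviance by more than the $\chi^2_1$ critical
value at 0.05. "Significant improvement" had to be operationalized; the
nested-deviance rule is the package's reading, chosen because it is the
standard likelihood analogue of a chi-square screen and cannot remove
points from well-fit monotone data (verified in the tests).

Cell-level uncertainty comes from a binomial bootstrap over trials
(`bootstrap_psychfit()`); at realistic trial counts (seven points of
~40 trials) the 95% interval covers the generating threshold in about
95% of simulated datasets.

## LAM estimation and outlier fences

`fit_lam()` minimizes squared error in log10 threshold over
$\sigma_{\mathrm{int}} \in [0, 90]$ and $\beta > 0$, searched in log
space from a closed-form initial guess; with three noise levels and two
parameters the fit is near-interpolating, so exact forward-generated
triples are recovered to six decimals and noisy fits inherit their
uncertainty from the threshold stage. Log-space loss matches the
multiplicative error of staircase-derived thresholds. Boundary solutions
(e.g. thresholds falling with noise, which drive
$\sigma_{\mathrm{int}} \to 0$) are flagged, not discarded.

Following the reported exclusion rule, subjects whose quadrant-averaged
$\sigma_{\mathrm{int}}$ or $\beta$ falls outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ — quartiles by
linear interpolation, fences computed within group and per parameter —
are flagged as outliers. The rule's scope ("for each group") was
ambiguous; computing fences within group on quadrant-averaged values is
this package's resolution.

## Rank-based inference

All group inference is nonparametric, matching the heterogeneous,
non-normal data the design anticipates. For the mixed 2×2×2 design
(group between subjects; upper/lower and left/right visual field within),
all observations are pooled and mid-ranked, per-cell *relative effects*
$(\bar R - 0.5)/N$ are computed, and effects are tested with the
Wald-type statistic

$$\mathrm{WTS} = (C\hat p)^{\top} (C \hat V C^{\top})^{+} (C\hat p),
  \qquad \mathrm{df} = \operatorname{rank}(C),$$

where $\hat V$ is block-diagonal over groups, built from the
between-subject empirical covariance of within-subject rank vectors, and
$C$ stacks Kronecker products of group contrasts with the within-cell
vectors for vertical, horizontal and their interaction. The exact
covariance construction is pinned here (the method family admits
variants) and validated two ways: the type-I error rate at n = 20/20
stays inside [0.03, 0.07] over 1,000 null simulations, and on small
instances the chi-square p-values rank-correlate above 0.9 with an
exhaustive permutation oracle of the same statistic. The chi-square
reference (not a small-sample F approximation) is used throughout;
results with any group below ~15 subjects deserve caution. No
multiplicity correction is applied anywhere — every p-value is raw and
labelled.

Quadrant biases are additionally tested on within-subject quadrant ranks
(mid-ranks for ties). Group locations are summarized by Hodges–Lehmann
pseudo-medians — the median of all Walsh averages, with confidence
intervals from exact signed-rank quantiles up to n = 25 and the normal
approximation beyond. Internal-noise/efficiency coupling is measured by
Spearman correlations (t approximation, tie-tolerant), per quadrant and
on quadrant-averaged values per group.

## The synthetic cohort generator

`cohort_spec()` defines the population the pipeline is demonstrated on.
Defaults are the study conditions, not knobs: group internal-noise
locations 4.51 / 6.1 / 6.69 deg (controls, single concussion, multiple
concussion — the reported group pseudo-medians) with post-exclusion
sample sizes 21 / 50 / 5, and *identical* efficiency distributions
across groups (location 0.7, i.e. five of seven elements pooled), so
that the generated truth is elevated internal noise with preserved
efficiency. Subject heterogeneity is log-normal with 0.25 log-unit scale
— positive and right-skewed, consistent with data that motivated
nonparametric analysis; the true subject-level variance is not
recoverable from printed intervals, so this scale is a labelled
convention. Efficiency draws are capped at 1; lapse rates are uniform in
[0, 0.02] per subject. Optional per-quadrant multiplicative offsets can
induce hemifield structure (e.g. a right-hemifield internal-noise
advantage in controls); the default is none, giving clean nulls for all
within-group tests.

`generate_cohort()` then simulates the full experiment — block order
randomized per subject, independent staircases per quadrant within each
noise block (the mapping of staircases to quadrants is assumed
independent; simultaneous presentation is not modelled as interaction) —
and emits every trial. Everything is reproducible from the spec's single
seed.

What the generator does *not* emulate: learning or fatigue across
blocks, lapse-rate heterogeneity beyond the uniform range, spatial
position noise, inter-quadrant interactions, or any coupling between
internal noise and efficiency within subject. Passing tests therefore
demonstrate that the *pipeline* recovers the structure it assumes, on
data of realistic size and noise — not that human data meet those
assumptions.

## Numerical choices and degenerate inputs

* Orientation arithmetic: period 180 deg; folded differences in
  (−90, 90]; the decision rule works on doubled angles so no explicit
  wrapping is needed there.
* Gumbel fitting: exponent clamped at $10^{30}$, probabilities at
  $[10^{-9}, 1 - 10^{-9}]$; analytic gradient treats clamped regions as
  flat. Fewer than 3 usable amplitudes is an error at the fit level and
  a logged skip at the pipeline level.
* LAM fitting: $\sigma_{\mathrm{int}}$ estimates below $10^{-5}$ snap to
  0 and flag the boundary; thresholds must be positive.
* Staircase: amplitudes clip at configured bounds (clips are counted);
  runs ending before any post-shrink reversal fall back to all reversal
  amplitudes, then to the final amplitude.
* Ties: uniform random tie-breaking in the 4AFC arg-max; mid-ranks
  everywhere in the rank statistics; singular contrasted covariances use
  the Moore–Penrose inverse and are flagged.

## Problem sizes used in the checks

The package's own validation uses desk-scale simulation sizes, chosen as
the smallest that make each property decisively testable: 2,000
staircase runs for the convergence point; 20,000 trials for the guessing
floor; 1,000 null replicates for the type-I rate; 20 datasets against a
252-assignment exhaustive permutation oracle; 200 replicates for
psychometric parameter recovery; 60 datasets × 200 resamples for
bootstrap coverage; 7 replicate cohorts at n = 21/50/5 for the
three-group ordering; and 100 replicate two-group pipelines at
n = 20/20 with 25-trial staircases for the power/specificity check.

## Known limitations

* The amplitude unit is this package's sagitta convention; $\beta$ is
  only defined up to that unit, so efficiency comparisons are
  meaningful within the pipeline but not against other tasks.
* The observer's LAM behaviour is slightly imperfect at the highest
  noise level (sinusoidal saturation of the decision variable), which is
  one reason recovered internal noise is checked to 25%, not exactly.
* Per-cell lapse rates are free within [0, 0.05]; sharing lapse across
  cells within subject is a defensible alternative not implemented.
* With three noise levels the LAM has one residual degree of freedom;
  model comparison against richer noise models is out of scope.
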