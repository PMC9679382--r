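---
title: "Micro-movement spikes and Gamma-process signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-movement spikes and Gamma-process signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmsgamma)
```

## The problem

Statistical learning experiments usually average event-locked epochs of a
continuous neural recording and discard the moment-to-moment fluctuations as
noise. `mmsgamma` takes the opposite view: the fluctuations *are* the signal.
The package characterizes a continuous multichannel biorhythmic recording
(EEG is the motivating case: 32 channels at 256 Hz over an 8-block,
64-trials-per-block session) as a *dynamic stochastic process*, tracking how
the probability distribution of amplitude fluctuations evolves while a
participant learns, and then asking cohort-level questions: do learners
split into subgroups with broad versus narrow fluctuation variance, and do
those subgroups differ in explicit memory of the task regularity?

The pipeline has five stages, each exposed as ordinary functions:

1. **Hub selection** (`bandpassRecording`, `adjacencyMatrix`,
   `clusteringCoefficients`, `selectHub`, `hubSeries`): within every sliding
   window (5 s, 50% overlap), all channel pairs are compared by Welch
   magnitude-squared coherence on the 13–100 Hz band; the maximal coherence
   per pair forms a weighted graph, and the channel with the largest
   weighted clustering coefficient is that window's *hub*. The hub
   channel's raw samples over each window's stride segment are concatenated
   into a single-channel series.
2. **Micro-movement spikes** (`buildMMS`): the peaks of the hub series are
   fitted by a two-parameter Gamma by maximum likelihood; the fitted mean
   $\hat\mu = \hat a \hat b$ is the *empirical mean amplitude*. The
   absolute deviations $|x(t) - \hat\mu|$ form the deviation series, whose
   peaks become unitless spikes
   $$\mathrm{MMS} = \frac{\max}{\max + \mathrm{avg}_{\min\text{-}\mathrm{to}\text{-}\min}},$$
   where the denominator's average runs over the samples strictly between
   the two local minima flanking the peak (the peak sample excluded). The
   ratio removes allometric amplitude effects — `MMS(c*x) = MMS(x)` for any
   `c > 0` — while the spike times keep the original peak timing.
3. **Windowed Gamma signatures** (`fitGamma`, `windowedGammaFits`,
   `quadrantSplit`): the spike values in every 5-s window (at least 100
   spikes required) are fitted by the Gamma family
   $$f(x) = \frac{1}{\Gamma(a)\,b^a}\,x^{a-1}e^{-x/b},$$
   giving a trajectory of (shape $a$, scale $b$) points on the Gamma
   parameter plane. Moments follow as mean $ab$, variance $ab^2$, skewness
   $2/\sqrt a$ and excess kurtosis $6/a$; the noise-to-signal ratio is
   $\mathrm{NSR} = ab^2/ab = b$, so the scale axis doubles as a noise axis
   and $\mathrm{SNR} = 1/b$. Quadrants of the log-log plane are spanned by
   the median log-shape and median log-scale: the right-lower quadrant
   (high shape, low scale) is the Gaussian-like low-noise regime, the
   left-upper quadrant the exponential-like high-noise regime. Shape
   $a = 1$ is the memoryless exponential anchor.
4. **EMD trajectories** (`windowHistogram`, `emd`, `emdSeries`,
   `emdPeaks`, `globalShapeProcess`): consecutive windows' spike histograms
   are compared by the Earth Mover's Distance. On a 1-D support the
   Wasserstein-1 distance has the cumulative-difference closed form
   $\sum_k |\,\mathrm{cum}(p-q)_k|\,\Delta c_k$; the linear-program
   transport formulation is retained as a test oracle only. A second-level
   analysis treats the sequence of window-level Gamma shapes itself as a
   signal and fits *its* fluctuation distribution — the Gamma process of
   Gamma-shape fluctuations.
5. **Cohort statistics** (`dipTest`, `ksTwoSample`, `splitSubgroups`,
   `etScore`, `rankSumTest`, `convergenceSummary`, `groupTests`): pooled
   windowed Gamma variances are tested for unimodality (Hartigan dip,
   uniform-bootstrap null), groups are compared by two-sample KS, and the
   mixed group is split — only when the dip test rejects at
   $\alpha = 0.01$ — by 1-D 2-means on the log maximum windowed variance
   per participant. Explicit-memory (ET) scores are hit rate over
   false-alarm rate; subgroups are compared by the two-sided Wilcoxon
   rank-sum test.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| window length | 5 s | smallest unit yielding at least 100 spikes per window, hence stable MLE fits with tight 95% CIs |
| window overlap | 50% | trajectory smoothness vs. redundancy |
| analysis band | 13–100 Hz | beta-through-gamma range used for hub selection |
| filter order | 20 | Butterworth bandpass, realized as ten biquads |
| Welch segment | 0.5 s (50% segment overlap) | 19 averages per 5-s window |
| histogram bins | 20 on [0, 1] | about 5 expected counts per occupied bin at the 100-spike minimum |
| minimum spikes | 100 | below this a window is skipped and logged |

Window intervals are half-open, 0-based sample intervals; a trailing
partial window is dropped rather than padded, because the fits need full
windows. Windows restart at each block boundary (block statistics are
reported per block); the empirical mean amplitude is estimated once per
participant session by default (`meanPerBlock = TRUE` switches to
per-block estimation).

Two defaults differ from the obvious sketch and deserve a note:

* **Welch segments of 0.5 s rather than 1 s.** The hub is the argmax of a
  clustering coefficient built from *maxima* of noisy coherence spectra.
  With $K$ Welch averages the null coherence level is about $1/K$ and its
  maximum over the band grows with the number of frequency bins; halving
  the segment doubles $K$ and halves the bin count, which lowers that null
  floor substantially and makes hub selection decisively more stable. The
  segment length is a parameter (`segS`) for users who prefer finer
  spectral resolution.
* **Filtering.** `signal::butter` offers no second-order-section output,
  and an order-20 bandpass as a single transfer function is numerically
  unusable at EEG rates. The package therefore designs the Butterworth
  bandpass analytically (prototype poles, bandpass transform, bilinear
  transform) as ten biquads, applied forward-backward with odd-reflection
  end padding. Without the padding, the filter's edge transients dominate
  the first and last windows of every recording and corrupt hub selection
  there.

## Numerical choices

* **Gamma MLE**: Newton iteration on the profile score
  $\log a - \psi(a) = \log \bar x - \overline{\log x}$ with Minka's
  closed-form initialization; 95% CIs from the observed information on
  $(\log a, \log b)$ mapped back, so intervals respect positivity. The
  observed information at the MLE is
  $n \begin{pmatrix} a^2\psi_1(a) & a \\ a & a\end{pmatrix}$ in those
  coordinates.
* **Family selection** (`fitCandidates`): Lognormal, Normal, Exponential,
  Gamma and Weibull are fitted by maximum likelihood and compared by raw
  maximized log-likelihood (no penalty). Because the exponential is the
  shape-1 special case nested inside the Gamma family, exponential-like
  data is reported through the Gamma fit with shape indistinguishable from
  1 — which is precisely how the analysis treats the memoryless regime.
* **Dip statistic**: implemented from the definition — the smallest
  sup-distance $d$ between the empirical cdf and any unimodal cdf — by
  bisection over $d$ with an exact feasibility check: a convex
  nondecreasing chain must pass through the lower/upper "gates"
  $[k/n - d,\,(k-1)/n + d]$ over a prefix and a concave chain over the
  complementary suffix (the greatest convex minorant of the upper gate
  points is the pointwise-maximal convex candidate), with an exact
  mode-junction condition linking the two sides: the convex side's minimal
  end value extended at its own final slope must not exceed the concave
  side's maximal start, or vice versa. The p-value is calibrated against
  the uniform null (the standard choice), 5,000 bootstrap replicates by
  default; each replicate needs only one feasibility check at the observed
  dip. The implementation agrees with an independent linear-programming
  reference to ~5e-13 (see the test suite) and with the hand-computable
  anchors dip({0,1}) = 1/4 and dip({0,1,2}) = 1/(2n) = 1/6.
* **Rank-sum**: exact enumeration when the pooled size is at most 12 and
  there are no ties; the tie-corrected normal approximation with continuity
  correction otherwise.
* **Degenerate inputs**: zero-variance peak sets fall back to the
  arithmetic mean (flagged); constant shape sequences are flagged
  degenerate rather than fitted; a zero false-alarm rate leaves the ET
  score undefined (NA) rather than infinite; coherence of a constant
  channel is an error, not a silent zero.
* **Ties**: hub-coefficient ties resolve to the first channel label;
  Gamma-plane points exactly on a median line fall left/lower.

## The synthetic cohort generator

The study's raw recordings are not deposited, so `generateParticipant` /
`generateCohort` synthesize recordings whose *peak statistics* are planted
and known. The defaults mirror the study conditions: 70 participants — 23
mixed (10 broad-variance + 13 narrow-variance), 23 correlated, 24 random —
8 blocks, 256 Hz, 32 channels, truncated-positive-normal ET scores with
subgroup means/SDs 0.94/0.4 (broad) and 1.52/0.75 (narrow), 1.37/0.9 for
the correlated group.

The hub channel of each block is a smooth positive carrier:

* a baseline at the scheduled mean amplitude carrying a small fast
  *pinning rhythm* (40 Hz, amplitude 0.1 of the mean), which anchors the
  empirically estimated mean amplitude just above the baseline and supplies
  a dense reference population of deviation peaks;
* sparse *events* at renewal times (shifted-exponential gaps, mean 100 ms)
  — smooth 40-ms bumps whose crest amplitudes are i.i.d. draws from the
  block's scheduled Gamma(shape, scale).

Per-block schedules (`regimeSchedule`): *exploratory* drifts log-linearly
from shape 1 (memoryless) to the Gaussian-range floor 10 with unit mean;
*error-correction* holds shape 10 at constant low scale 0.01; the stable
regimes hold shape 8. A per-participant log-normal jitter multiplies the
scheduled shapes (sd 0.08 in the mixed group, 0.25 in the stable groups):
mixed-group learners share the error-correction attractor, stable-group
baselines are idiosyncratic. Non-hub channels are attenuated copies of the
event component (gain U(0.3, 0.55)) plus independent band-limited noise, so
hub selection has a planted answer; the pinning rhythm is the hub's own,
which keeps spurious all-pair coherence at the pinning frequency out of the
network.

**Why this morphology?** The Eq.-style per-peak normalization is
deliberately scale-free, and it is more destructive than it first appears:
whenever a deviation peak's flanking minima hug the peak (as they do on any
noisy carrier), the min-to-min average is proportional to the peak itself
and every spike collapses toward a single value; and because deviations are
taken from the fitted mean, amplitude distributions fold around that mean,
which erases most of the planted dispersion (folded distributions have
nearly universal CV). Two consequences follow. First, the carrier must be
smooth, with sparse wide events over a pinned baseline, so that event
spikes grade with the crest-to-pedestal ratio: then the planted amplitude
CV ($1/\sqrt{a}$) maps *monotonically* onto the windowed MMS Gamma
variance, broad regimes come out broad, and narrow come out narrow — the
property all cohort analyses rest on. Second, spike values are confined to
$(1/2, 1]$ by construction (the min-to-min average can never exceed the
peak), so the *absolute* fitted shape/scale are not the planted ones, and
recovery through the full pipeline is validated ordinally: higher planted
CV gives higher windowed variance, exploratory trajectories start broad and
converge to the error-correction level by block 8, with zero overlap
between the subgroups' max-variance statistics at the default effect
sizes. Ground-truth event times and amplitudes are stored with every
synthetic recording, and the planted per-block amplitudes pass a KS test
against their scheduled Gamma.

What the generator does *not* emulate: eye/muscle artifacts, line noise,
volume conduction, task-evoked potentials, or any real spatial structure
across channels. Passing tests on this cohort show that the pipeline's
inference chain is sound under its own assumptions — not that real EEG
satisfies those assumptions.

Windows whose span crosses a hub-channel hand-off mix two channels'
streams; they are excluded from fitting and logged (a single hand-off
otherwise dominates a participant's max-variance statistic).

## Problem sizes used in the checks

The bundled acceptance script (`scripts/acceptance.R`) runs the full
pipeline on a desk-scale cohort: 23 mixed + 23 correlated participants,
8 blocks of 5 min at 256 Hz, 8 channels per recording; the dip test uses
5,000 uniform-bootstrap replicates on the ~20,000 pooled windows. The test
suite uses a further-scaled cohort (45-s blocks, 6 channels, same
participant counts and block structure). Both sizes are package choices
that keep every statistic comfortably estimable (over 100 spikes per
window, hundreds of windows per participant).

## Known limitations

* The subgroup-splitting rule (dip-gated 1-D 2-means on log max variance)
  is a reconstruction: the original subgroups "self-emerged" without a
  stated rule. The gate guarantees no split is reported for unimodal
  cohorts.
* The fitted MMS Gamma shape has a hard floor induced by the spike-value
  support $(1/2, 1]$; between-regime comparisons are meaningful, absolute
  shape values are not comparable to fits on unbounded data.
* Coherence-based hub selection assumes roughly stationary network
  structure within a window; rapidly switching hubs produce excluded
  windows rather than blended estimates.
* EDF/BDF support covers continuous equal-rate recordings (the formats'
  common case), not EDF+ annotations or variable-rate channels.
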