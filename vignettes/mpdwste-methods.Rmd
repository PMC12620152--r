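---
title: "Models and methods behind mpdwste"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpdwste}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpdwste)
```

This vignette documents the physical model, the simulator, the detector and
the numerical choices the package makes, in enough detail that a user can
judge what a passing test suite does and does not establish about real
acquisitions.

## The acquisition model

A stimulated echo stores magnetization along the longitudinal axis during
the mixing time $T_M$, which makes very long motion-sensitizing intervals
possible at the cost of $T_1$ (rather than $T_2$) decay. The multiple-point
variant replaces the single 90° readout pulse by $N_{RF}$ refocusing pulses
of increasing flip angle, one every $T_{RF}$ ms, each deflecting only a
fraction of the stored magnetization. Cycle $n$ therefore sees an effective
mixing time $T_{M,n} = T_M + (n-1)T_{RF}$ and a motion-sensitizing time
$\Delta_n = \Delta_1 + (n-1)T_{RF}$, with
$\Delta_1 = T_M + T_{RF,Exc.} + \delta$.

**Flip angles.** Requiring equal signal in consecutive cycles for a design
$T_1$ yields the backward recursion
$\alpha_n = \arctan\!\left(e^{-T_{RF}/T_1}\sin\alpha_{n+1}\right)$ with
$\alpha_{N_{RF}} = 90^\circ$ (`flip_angle_schedule()`). The compensation is
exact only at the design $T_1$: tissues with shorter $T_1$ drift downward
over the cycles, longer $T_1$ upward — `signal_constancy_residual()`
quantifies this, and the simulated phantom's $T_1$ tube ladder
(800/1000/1300/1600 ms) exercises both signs.

**Diffusion weighting.** For a pair of trapezoidal motion-sensitizing lobes
of amplitude $G$, flat-top-equivalent duration $\delta$, ramp time $\xi$
and separation $\Delta$, ignoring imaging gradients,
$$ b = \gamma^2 G^2\left[\delta^2(\Delta - \delta/3) + \xi^3/30 -
\delta\xi^2/6\right]. $$
Because the amplitude is fixed by the first cycle's $b_1$, later cycles
scale as the bracket ratio (`b_value_series()`). Note that the finite-pulse
correction $\xi^3/30 - \delta\xi^2/6 - \delta^3/3$ is *negative* at the
defaults, so $b_n/b_1$ slightly exceeds $\Delta_n/\Delta_1$ (e.g. the first
in vivo setting ends at 520 rather than 500 s/mm² from $b_1 = 50$).

**Gradient sub-pulse defaults.** $\delta = 5$ ms, $\xi = 1$ ms and
$T_{RF,Exc.} = 6$ ms are the package defaults. They were fixed once, by
consistency: together they reproduce every tabulated motion-sensitizing
time row ($\Delta_1 = T_M + 11$ ms across settings) and every tabulated
b-value endpoint after integer rounding, as well as the published gradient
amplitudes (27 / 13.5 / 11.9 / 19.0 mT/m) when the b-value expression is
inverted at $b_1$. The unit conventions are ms, mT/m, s/mm² and µm at every
interface, SI internally, with $\gamma/2\pi = 42.577$ MHz/T; conversions
live in one utility file so no other code multiplies by powers of ten.

**Displacement sensitivity.** A net displacement $\Delta x$ between the
lobes shifts the phase by $\varphi = \gamma G \delta\, \Delta x$; a π shift
corresponds to 87 µm for the strongest setting. The sensitivities computed
for the weaker settings differ by up to ~1 µm depending on whether the
published (rounded) or the internally derived amplitude is used; only the
87 µm value is exactly pinned, and tests treat the others with a ±1 µm
band.

## Motion and noise model

A twitch event is a displacement envelope $e(t)$: zero at onset, rising
piecewise-linearly to its peak over the contraction time, falling back to
exactly zero over the relaxation time (a smooth raised-cosine variant is
available via `shape = "cosine"`). The acquisition is sensitive only to the
*net* displacement between dephasing ($t = 0$) and rephasing
($t = \Delta_n$), so cycle $n$ sees the spread
$\sigma_n = A_{vox}\,|e(\Delta_n) - e(0)|$, where $A_{vox}$ is the voxel's
peak intra-voxel spread (largest at the footprint centroid, tapering
linearly to the rim of an ellipse elongated along the fiber direction).
Assuming the net displacement is Gaussian-distributed within the voxel, the
magnitude attenuates by $\exp(-\tfrac12(\gamma G\delta\sigma_n)^2)$ —
the simplest dispersion model consistent with signal-void phenomenology;
coherent bulk motion, which only shifts the global phase of a single-shot
image, is deliberately not modelled.

This two-time-point reduction operationalizes the five motion-pattern
classes: a twitch already active at dephasing and relaxed before $\Delta_1$
(M$_I$) attenuates every cycle identically; one starting and ending inside
$(0, \Delta_1)$ (M$_V$) is exactly invisible; one contained between
$\Delta_1$ and $\Delta_{N_{RF}}$ (M$_{III}$) shows its full rise and fall.
Class boundaries use half-open intervals — onset exactly 0 counts as after
the dephasing lobe — so the classification is total and tested by a grid
sweep.

Measurement noise is Rician (independent Gaussian on both quadratures,
$\sigma$ = reference/SNR, then magnitude), with a plain Gaussian model for
analytic checks. Background $\sigma$ is estimated with the Rayleigh
correction $\hat\sigma = \sqrt{\overline{v^2}/2}$.

## The synthetic scenes, and what they do not show

`build_phantom_scene()` is a digital twin of an incoherent-motion phantom:
a water bath, two intra-slice tubes housing a motion bead whose wake is
modelled as persistent per-column turbulence events, and four inter-slice
$T_1$ tubes. `build_leg_scene()` is a 64 × 64, 3 mm/pixel calf slice with
convex regions for soleus, both gastrocnemii and tibialis anterior
(muscle $T_1$ 1300 ms, $T_2$ 35 ms, ADC $1.5\times10^{-3}$ mm²/s).
`sample_events()` draws Poisson event counts per muscle and repetition,
uniform onsets over a window spanning the readout, contraction times of
40–160 ms and relaxation times of 80–300 ms (spanning reported contraction
times of slow- and fast-twitch calf muscle), and peak spreads of 20–200 µm
so both sub- and supra-threshold events occur.

The scenes emulate relaxation, diffusion weighting, event timing and
Rician noise. They do **not** emulate EPI artifacts, partial-Fourier
blurring, fat signal, coil profiles, registration error, physiological
background motion, or realistic muscle anatomy. Passing recovery tests
therefore demonstrate that the detector and the dynamic metrics are
internally consistent with the forward model at realistic SNR — not that
the thresholds are optimal for scanner data.

## Detection and linking

The published analysis used a convolutional network with recurrent
temporal processing for segmentation; that network is defined only by
citation and is out of scope here. The package instead uses a transparent
two-step detector: relative signal via a per-voxel, per-cycle **median
across repetitions** (immune to events present in fewer than half of the
repetitions; a model-predicted reference is available for single
repetitions or recurring fixed-location events), then thresholding at a
relative drop of 0.3 with 8-connected components of at least 2 voxels.
The default threshold sits well below the ~50% mean drop of true events
and about 9 noise standard deviations at SNR 30. Detection is restricted
to labelled tissue when a label map is available, because air voxels carry
no meaningful relative signal. Voids covering more than half of a muscle
or straddling more than two muscles are discarded as intended movement.

Linking joins components in consecutive cycles that share at least one
voxel; there is no gap bridging, so a one-frame disappearance splits an
event — matching the requirement of *spatially overlapping* visible voids.
Per event the package reports the CSA course (percent of peak), the
duration (inclusive frame count × $T_{RF}$), and the contraction time
SMAM$_{TC}$ from first visible void to peak CSA. Two conventions deserve
note:

- SMAM$_{TC}$ counts frames **inclusively** (peak − first + 1), so the
  smallest observable value is 1 frame = 40 ms and a peak in the frame
  after first appearance gives 80 ms, consistent with how median frame
  counts map to milliseconds in the literature on this sequence.
- Events already visible in the first frame are flagged
  `tc_evaluable = FALSE` and excluded from contraction-time summaries —
  their onset is unobserved — but still counted everywhere else.

The overall pECM counts a voxel once per repetition (union over cycles);
a per-cycle mode and a voxel-frame sum mode are also exported, since the
union-versus-sum choice is a genuine ambiguity. Frames are 1-based in all
reports; array storage is 0-based only internally.

## Statistics

Group comparisons use the tools a nonparametric pipeline needs:
Shapiro–Wilk (`normality_check()`), paired two-tailed Wilcoxon signed-rank
(`wilcoxon_paired()`; zero differences are discarded — the classic
convention, chosen because the original analysis software's policy is not
documented — and the exact distribution is used up to n = 25),
Friedman (`friedman_conditions()`, average ranks for ties, statistic 0 and
p = 1 for fully tied tables), and Bonferroni correction
(`bonferroni_adjust()`). The median CI is the distribution-free
order-statistic interval: the widest symmetric pair of order statistics
whose exact binomial coverage reaches the level, flagged when a small
sample cannot attain it. All of these are validated in the test suite
against brute-force oracles (exhaustive sign enumeration, hand-ranked
chi-square, binomial search).

## Numerical choices and degenerate inputs

- Flip angles are computed and stored in degrees at full double precision;
  rounding happens only at display and export. The recursion is verified
  to $10^{-12}$.
- The gradient-amplitude inversion round-trips with the forward b-value to
  $10^{-10}$ relative over a parameter grid.
- `validate_sequence_params()` never throws; it reports violations
  (e.g. $\xi > \delta$, non-positive bracket) and derived quantities so a
  CLI or config file can be vetted before use.
- Degenerate cases are defined, not errors: $N_{RF} = 1$ gives the single
  90° pulse; zero gradient gives $b = 0$; a stationary bead produces no
  turbulence events; empty muscles appear in summaries with `n = 0`.
- JSON schedule exports store the parameter set and recompute the schedule
  on import, so round-trips are exact rather than
  precision-limited.

## Problem sizes

The recovery experiments in the test suite use 100 repetitions of a
64 × 64 slice at SNR 30 with one M$_{III}$ twitch per repetition — enough
repetitions for stable median statistics while keeping the whole suite
fast on a single core — and the phantom checks use the 5-cycle protocol
with a 20 mm/s bead. Users studying detector behaviour at other operating
points can scale `repetitions`, `rates` and `noise_spec()` freely; all
randomness flows through explicit seeds.

## Known limitations

- The detector is a threshold rule, not a learned segmenter; its
  sensitivity near the drop threshold differs from the published network,
  so absolute event counts on real data are not comparable.
- The dephasing lobe is referenced to $t = 0$ of each shot; its true
  position inside the echo-time preparation is absorbed into
  $T_{RF,Exc.} + \delta$ through the $\Delta_1$ definition.
- Turbulence behind the phantom bead is a persistence heuristic, not fluid
  dynamics; only the monotone growth of the void is claimed.
- Single-slice, single-direction motion sensitization only; no
  registration, multi-slice handling or whole-body support.
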