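# mpdwste

Resting skeletal muscle twitches spontaneously: single motor units fire and
displace small bundles of fibers by tens to hundreds of micrometres over a
few hundred milliseconds. Diffusion-weighted MRI sees these twitches as
transient signal voids — *spontaneous mechanical activities of musculature*
(SMAMs) — because the incoherent intra-voxel displacement between the
dephasing and rephasing motion-sensitizing gradient lobes disperses the spin
phase. A conventional diffusion sequence samples one time point per twitch;
a **multiple-point diffusion-weighted stimulated-echo (MP-DW-STE)** sequence
stores the magnetization longitudinally and reads it out with a train of
N<sub>RF</sub> small-flip-angle refocusing pulses, one image every
T<sub>RF</sub> milliseconds, so a single twitch is followed through its
whole contraction–relaxation course.

`mpdwste` implements this acquisition and its analysis chain as software,
for MR physicists and neuromuscular-imaging researchers:

- **Sequence design.** The variable flip-angle series that keeps the
  stimulated-echo signal constant for a design T1 follows the backward
  recursion αₙ = arctan(e^(−T_RF/T1) · sin αₙ₊₁) with α_N_RF = 90°. Cycle
  timings grow arithmetically, T_M,n = T_M + (n−1)T_RF and
  Δₙ = Δ₁ + (n−1)T_RF with Δ₁ = T_M + T_RF,Exc. + δ, and the b-value of
  cycle n is b = γ²G²[δ²(Δₙ − δ/3) + ξ³/30 − δξ²/6] for trapezoidal lobes
  of duration δ, ramp time ξ and amplitude G. Amplitude inversion and the
  displacement-per-phase sensitivity Δx = φ/(γGδ) are included.
- **Signal simulation.** Per-voxel stimulated-echo series
  Sₙ = ½M₀ e^(−TE/T2) e^(−T_M,n/T1) sin αₙ ∏ₖ<ₙ cos αₖ e^(−bₙ·ADC), a
  Gaussian phase-dispersion model A = exp(−½(γGδσ)²) for incoherent
  displacement of intra-voxel spread σ, and Rician measurement noise.
- **Ground-truthed scenes.** A digital twin of an incoherent-motion phantom
  (bead-swept tube, T1 tube ladder at 800/1000/1300/1600 ms) and a
  synthetic calf slice with stochastic twitch events carrying latent
  motion-pattern classes M_I–M_V (timing of the twitch relative to the
  dephasing lobe and the readout cycles).
- **SMAM quantification.** Median-normalized threshold detection of signal
  voids, temporal linking by spatial overlap, cross-sectional-area (CSA)
  course, contraction time SMAM_TC, duration, start/end categories,
  percentage event count maps (pECMs) and per-muscle summaries with
  distribution-free median CIs.
- **Statistics.** Shapiro–Wilk, paired two-tailed Wilcoxon, Friedman and
  Bonferroni correction wrapped into a uniform report type.

## Worked example

```r
library(mpdwste)

params <- sequence_params(tm = 145, trf = 40, nrf = 10, b1 = 50)
sched  <- cycle_schedule(params)
sched
#> MP-DW-STE cycle schedule (G_D = 13.46 mT/m)
#>  cycle alpha_deg tm_ms delta_ms b_s_mm2
#>      1     15.85   145      156   50.00
#>      2     17.03   185      196   62.96
#>  ...
#>      9     44.12   465      476  153.69
#>     10     90.00   505      516  166.65
```

The ten flip angles rise from 15.9° to 90° so that each cycle deflects just
enough stored magnetization to hold the signal constant at T1 = 1300 ms
(skeletal muscle); the motion-sensitizing time grows from 156 to 516 ms and
the b-value from 50 to 167 s/mm².

```r
scene  <- build_leg_scene()
events <- sample_events(scene,
                        rates = c(soleus = 0.3, gastrocnemius_medialis = 0.1),
                        repetitions = 40, seed = 42, schedule = sched)
series <- render_dwi_series(scene, sched, events,
                            noise = noise_spec("rician", 30), seed = 43)
res <- analyze_series(series)
nrow(res$events)                      # detected SMAMs
#> [1] 11
res$activity_rate_pct                 # repetitions with >= 1 SMAM
#> [1] 20
per_muscle_summary(res$smams, scene$label_names)[1:2, c(1, 2, 4, 7, 8, 11)]
#>                   muscle n_events tc_median_frames tc_median_ms duration_median_frames duration_median_ms
#> 1                 soleus        8              1.5           60                      3                120
#> 2 gastrocnemius_medialis        3              1.0           40                      2                 80
```

Of the 13 sampled ground-truth twitches, 11 are recovered (the others are
class M_V — fully contained in the mixing interval and physically
invisible — or below the detection threshold). The soleus median duration
of 3 frames corresponds to 120 ms at the 40 ms frame interval; contraction
times count frames from first visible void to peak CSA inclusively, so the
smallest observable value is 1 frame (40 ms). The numbers above are the
output of this exact script.

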