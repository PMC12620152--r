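Package: mpdwste
Title: Multiple-Point Diffusion-Weighted Stimulated-Echo Design and Muscle
    Twitch Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Design and simulation of multiple-point diffusion-weighted
    stimulated-echo (MP-DW-STE) MRI acquisitions and quantification of
    spontaneous mechanical activities of musculature (SMAMs) in the
    resulting image time-series. Computes variable flip-angle schedules
    for constant stimulated-echo signal at a design T1, per-cycle mixing
    and motion-sensitizing times, b-value series for trapezoidal
    motion-sensitizing gradients, gradient amplitudes and displacement
    sensitivities. Simulates the stimulated-echo signal of digital
    phantoms (T1 tube ladder, incoherent-motion bead tube) and
    calf-muscle scenes with stochastic twitch events, including Rician
    measurement noise. Detects transient signal voids, links them over
    imaging cycles, and derives cross-sectional-area courses, contraction
    times, durations, motion-pattern classes, percentage event count maps
    and nonparametric group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
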