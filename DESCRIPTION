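Package: gammawave
Title: Directed Information Transfer and Travelling Gamma Waves in
    Multi-Electrode Cortical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify stimulus-modulated, direction-specific
    information transfer between cortical sites recorded with electrode
    arrays.  Implements transfer entropy from band-limited oscillation
    phase to firing rate with equipopulated binning, limited-sampling
    bias correction and a common-stimulus bootstrap null; lagged
    conditional information variants; circular phase-shift statistics
    (circular mean, phase locking value, Rayleigh test); pair causality
    classification and asymmetry indices; travelling-wave speed
    estimation from projected phase gradients with spline regression;
    phase-shift block segmentation and block-conditioned transfer
    entropy; multitaper spatial coherence; reverse-correlation receptive
    field mapping with stimulus-feature extraction; and a seeded
    synthetic session generator with planted travelling waves and
    directional phase-to-rate coupling for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
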