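---
title: "Directed information transfer and travelling gamma waves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed information transfer and travelling gamma waves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammawave)
```

## The scientific problem

Neighbouring populations in primary visual cortex oscillate in the gamma
band (50–80 Hz), and the *relative timing* of these oscillations — the
phase shift between sites a few millimetres apart — has been proposed as a
mechanism that routes information flow across the cortical sheet.
`gammawave` implements the full analysis chain needed to test this idea on
multi-trial, multi-electrode recordings:

1. band-limited phase and amplitude extraction (zero-phase Butterworth
   filtering plus the analytic signal),
2. transfer entropy (TE) from the gamma phase of a "sending" site to the
   firing-rate envelope of a "receiving" site, bias-corrected and Z-scored
   against a common-stimulus bootstrap null,
3. circular phase-shift statistics, pair-causality classification, and the
   correlation between phase shifts and directed TE,
4. travelling-wave speed estimation from the spatial phase gradient,
5. segmentation of time into positive/negative phase-shift blocks and
   block-conditioned TE,
6. sensory (scene) information carried by phases, phase shifts and rates,
7. receptive-field mapping by reverse correlation and stimulus-feature
   extraction (time contrast, orientation activation, directed motion).

Because the recordings this analysis was designed for are not required
here, the package ships a seeded synthetic-session generator with planted
ground truth; every stage has a recovery test against what was planted.

## Estimators

### Transfer entropy and its relatives

For a target series $X$ (receiver firing rate) and source series $Y$
(sender gamma phase), transfer entropy is the conditional mutual
information

$$T(Y \to X) = I(X_t;\, Y_{past} \mid X_{past}),$$

estimated by discretising each variable into equipopulated (quantile)
bins and plugging joint occupancy counts into the Shannon formulas.
Equipopulated binning is rank-based, so every estimate is invariant to
monotone transforms of the raw signals.  The lagged conditional
information (LCI) uses the sender's past rate as the conditioner instead
of the receiver's past rate; the localized LCI uses the receiver's past
phase.  All three share one estimator core
(`conditional_mutual_information()` and the fast counting path behind
`transfer_entropy()`).

Defaults that the source text left open, chosen once and exposed as
arguments:

* embedding dimension 1 per past, lag 10 ms, evaluated on a 2 ms grid —
  a single-sample past at roughly one gamma quarter-cycle;
* 3 equipopulated bins per variable for TE/LCI, so the 27-cell joint stays
  well-sampled at desk-scale session lengths (4 bins for sensory
  information, where the joint is only `bins x scenes`);
* Panzeri–Treves first-order residual-bias term as the default
  limited-sampling correction, computed from occupied-bin counts; a
  shuffle-subtraction correction is available as an alternative.  The
  corrected estimate can dip slightly below zero on independent data;
  tests treat values within sampling noise of zero as null.
* embeddings never span trial (or block) boundaries, and samples masked by
  the filter settling window are dropped listwise.

### The common-stimulus bootstrap null

Both sites see the same movie, so a naive TE is contaminated by shared
stimulus drive.  The null reconstructs that contamination while destroying
genuine within-trial interaction: the source series of trial $m$ is paired
with the target series of a different trial $m'$ (a random derangement of
trial labels) at identical movie time.  The observed TE is Z-scored
against `n_boot` such resamples (default 40; classification analyses use
more, see below).  On uncoupled-but-co-stimulated synthetic pairs the
resulting Z-scores are close to standard normal (the acceptance suite
checks |mean| < 0.5, SD in [0.7, 1.4], and a tail fraction above Z = 3 of
at most 5%).

The null TE distribution is right-skewed, so its standard deviation
converges slowly in `n_boot`.  For analyses that compare Z-scores between
the two directions of a pair (the symmetry classification), the package's
validation design uses `n_boot = 240`; for plain detection, 40 suffices.

### Sensory information

Scene information is Shannon information between the scene label and a
response reduced to one value per (trial, scene): the scene mean for slow
variables, the circular mean for wrapped angle series, and the
scene-centre sample for fast single-site phases, which are evaluated
against scenes of one oscillation period (`period_scenes()`).  Responses
are pooled and binned into 4 equipopulated bins.  Significance uses a
surrogate null that circularly rotates each trial's scene sequence by a
random offset.  A full within-trial permutation was rejected because it
destroys the autocorrelation of slowly varying responses and then
understates the null variance; rotation preserves the autocorrelation and
calibrates correctly (this matters for random-walk-like phase responses).

## Phase-shift and wave analyses

The phase shift of an ordered pair is the wrapped difference
$\Delta\varphi = \varphi_{send} - \varphi_{recv}$; positive shifts mean
the sender leads.  Windowed circular means and phase-locking values use a
300 ms sliding window.  Pair classification follows the published rules:
drop the 20% of pairs with the lowest (max-direction) TE, call a pair
strongly asymmetric when one direction carries at least ten times the TE
of the other, symmetric when the relative difference is below 20%.  The
asymmetry index is $|T_{ab} - T_{ba}| / \max(T_{ab}, T_{ba})$ on Z-scores
clipped at zero (Z can be negative; the clipping choice is ours).

### Wave speed

For each strongly asymmetric "reference" pair, electrodes whose
displacement to the reference receiver lies within 45° of the causal
direction contribute a (projected distance, mean shift) point; distances
are projections onto the sender-to-receiver axis, receiver at the origin,
upstream negative.  Profiles are unwrapped along each reference line
(ordered from the origin upstream) before pooling: at the planted speed of
0.36 m/s and 65 Hz the phase gradient is 1.13 rad/mm, so raw shifts wrap
beyond ~2.8 mm and would otherwise fold the profile.  If the minimum
unwrapped shift is achieved by the receiver of another reference pair,
that site becomes the origin, so the origin always marks the final target
of the propagation.  A cubic smoothing spline (penalty by generalized
cross-validation) is fitted to the pooled points; the speed is
$v = 2\pi f / |slope|$ from the tangent slope at the origin, with $f$ the
band centre (65 Hz) by default.  Slopes below tolerance are flagged as
"infinite speed" (global synchrony) rather than converted.  Uncertainty is
a bootstrap over reference pairs.

### Blocks and block-conditioned TE

Per sample, the sign of the shift is majority-voted across trials (exact
ties leave the sample unlabeled and break runs); runs of constant sign of
at least 300 ms become blocks.  TE is then computed separately within
positive and negative blocks after randomly down-sampling the blocks of
the longer condition — trimming the last kept block — so both conditions
use the same total duration within 10%.

## The synthetic-session generator

The generator plants a travelling plane wave on an electrode grid,

$$\varphi_e(t) = 2\pi f_0 t - k(t)\cdot x_e + \eta_e(t) + \xi(t) + \theta_{trial},
\qquad |k| = 2\pi f_0 / v,$$

with per-scene wave direction $k(t)$ (piecewise constant over 300 ms
scenes), per-electrode phase perturbations $\eta_e$, a shared random-walk
drift $\xi$, and an optional uniform per-trial offset $\theta_{trial}$.
The band signal is $A(t)\cos\varphi$ plus broadband noise.  Firing-rate
envelopes follow

$$r_j(t) = \mathrm{softplus}\!\big(b + \textstyle\sum_i g_{ij}(t)
\cos(\varphi_i(t-\delta) - \psi_{ij}) + c\, s_j(t) + a\, r_j(t-1)\big) + \epsilon,$$

clipped at zero: cosine phase tuning of the lagged sender phase is the
minimal mechanism consistent with significant phase-to-rate TE and LCI,
softplus keeps rates nonnegative and smooth, $s_j$ is a per-scene
stimulus drive shared by all trials (the confound the bootstrap must
remove), and $a$ is a one-sample self-history.  With direction gating the
edge gain is scaled by
$\texttt{gate\_floor} + (1-\texttt{gate\_floor})\max(0, \hat k \cdot \hat u)$,
the positive part of the alignment between the instantaneous wave
direction and the sender-to-receiver axis; the configurable floor lets a
design plant a finite with-wave : against-wave coupling ratio (0.25 gives
the ratio 4 used in validation).

Defaults: 4x4 grid, 2 mm spacing, 1000 Hz, 65 Hz carrier (the 50–80 Hz
band centre), 0.36 m/s planted speed, 300 ms scenes, 40 trials, 60 scenes.
One random stream per session is split per component so that adding noise
to one component does not perturb the draws of another.

Two generator choices deserve emphasis because they encode real
physiology that a naive implementation misses:

* **Finite linewidth** (`phase_drift_sd`, shared random-walk drift): a
  strictly periodic carrier is a clock, and a clock read at scene centres
  leaks spurious "stimulus information" into single-site phase through
  deterministic sampling offsets.  Real gamma decorrelates over tens of
  milliseconds; the drift reproduces that, leaves phase *differences*
  untouched (it cancels within a pair), and makes the dissociation test
  meaningful.
* **Correlated per-site perturbations** (`phase_noise_tau_ms`, default
  50 ms): with white per-site jitter all electrodes carry essentially the
  same phase signal, so TE cannot distinguish the true sender from any
  other site.  An AR(1)/Ornstein–Uhlenbeck perturbation with a correlation
  time of a few cycles gives each site a persistent private phase
  component that the planted coupling actually transmits — and that the
  estimator can attribute.

What the generator does **not** emulate: biophysical circuit dynamics,
spike bleed-through into the field signal, 1/f background spectra,
wideband (20 kHz) raw traces, wave attenuation or interference.  Passing
recovery tests therefore shows the estimators are correct and calibrated
under the planted statistical structure, not that any particular cortical
dataset satisfies that structure.

## Validation design (presets)

`preset_config()` freezes the eight study conditions used by the test
suite and by `scripts/acceptance.R`: null calibration (`uncoupled_pair`),
direction recovery (`coupled_pair`), classification (`classification`),
the phase-shift/TE correlation (`distributed`), block-conditioned TE
(`gated_pair`, with `mutual_pair` as the symmetric control), wave-speed
recovery (`wave_grid`), and the sensory-information dissociation
(`scene_gated_pair`).  Session sizes (10–20 trials, 10–20 scenes of
300 ms) are scaled so that the entire validation battery runs on one CPU
in well under half an hour while keeping every joint distribution
well-sampled; they are the package's chosen desk-scale study conditions.
The `distributed` preset couples all with-wave ordered pairs of a
collinear array through gated gains and uses a larger per-site phase
perturbation (0.6 rad): distributed propagation with locally
heterogeneous phase is what makes directed TE attributable to individual
senders.

In the `wave_grid` validation the reference causal pairs are taken from
the planted coupling geometry (the with-wave nearest-neighbour pairs)
rather than re-estimated, so that the speed test isolates the geometry
rules (cone, projection, re-anchoring, spline slope); pair recovery is
validated separately in the classification condition.

## Numerical choices and degenerate inputs

* "Zero-lag 8th-order Butterworth" filtering is implemented as a
  forward–backward (zero-phase) IIR Butterworth of polynomial order 8; a
  zero-lag FIR Butterworth does not exist, and forward–backward IIR is
  the standard realisation of "zero lag".
* Multitaper coherence uses 5 Slepian tapers at time-bandwidth 3 on
  non-overlapping 1 s blocks; only the block length was externally fixed.
* All-zero signals have undefined phase: flagged and excluded (`NA`) from
  circular statistics rather than silently set to 0.
* Constant series cannot be equipopulated-binned: estimators raise an
  error, except sensory information, which documents a guarded value of
  0 bits for constant responses.
* Rank ties in binning are broken by first occurrence (stable), keeping
  occupancies within one count of each other.
* Majority-vote ties in block segmentation (even trial counts) leave the
  sample unlabeled rather than inheriting a sign.
* The Rayleigh test at very large n rejects for trivially small resultant
  lengths; the pipeline subsamples shift series to at most 5000 angles
  before testing.

## Known limitations

* The Z-scored TE scale depends on the strength of stimulus-locked
  structure relative to coupling; comparing Z between conditions with very
  different null widths is less stable than comparing bias-corrected bit
  values (the block-conditioned comparison therefore reports bits).
* The Panzeri–Treves term implemented here is the first-order
  occupied-bin form; at extreme undersampling (joint cells with
  single-digit counts) a shuffle-based correction is preferable and
  available.
* Wave-speed estimation assumes a single dominant propagation axis per
  reference pair; interfering waves from multiple sources are out of
  scope.
* The time-contrast and orientation-activation pooling formulas are
  documented stand-ins (frame-difference RMS normalised by mean RF
  luminance; gradient-magnitude-weighted cos²), configurable at the call
  site, since the exact published pooling was not available.
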