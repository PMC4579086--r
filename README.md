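# gammawave

Directed, stimulus-modulated information transfer between cortical sites,
inferred from multi-electrode recordings of band-limited field potentials
and firing-rate envelopes — with travelling-wave analysis of the spatial
gamma-phase pattern.

## What it does

Populations in primary visual cortex oscillate in the gamma band
(50–80 Hz).  `gammawave` quantifies whether the gamma **phase** at one
site exerts a directed (Wiener–Granger) influence on the **firing rate**
at another site, and whether the spatial pattern of phase *shifts*
behaves like a travelling wave aligned with the direction of information
flow.  The core quantities:

- **Transfer entropy** `T(Y→X) = I(X_t ; Y_past | X_past)` on
  equipopulated-binned series with limited-sampling bias correction,
  Z-scored against a **common-stimulus bootstrap null** (source and
  target series paired across different trials at identical movie time,
  removing stimulus-driven pseudo-causation).  Variants: lagged
  conditional information (condition on the sender's past rate) and its
  localized form (condition on the receiver's past phase).
- **Phase-shift statistics**: wrapped shift `φ_send − φ_recv` (positive =
  sender leads), sliding circular mean and phase-locking value, Rayleigh
  test, pair classification into strongly asymmetric / symmetric pairs,
  asymmetry index `|T_ab − T_ba| / max(T_ab, T_ba)`, and the Spearman
  correlation between mean shift and directed TE.
- **Wave speed** from the spatial phase gradient: projected distances
  along reference causal pairs (45° cone, origin at the wave's final
  target), cubic smoothing-spline fit, `v = 2πf / |slope|` at the origin.
- **Block-conditioned TE**: segment time into ≥300 ms blocks of majority
  positive or negative shift, balance total durations, and compare TE
  with the wave versus against it.
- **Sensory information**: Shannon information between movie scene
  identity and phases, phase shifts, power or rates.
- **Receptive fields and stimulus features**: reverse-correlation RF maps
  from gamma power, local time contrast, orientation activation and
  tuning, directed motion from optic-flow input.
- A **seeded synthetic-session generator** that plants a travelling wave
  with known speed and direction schedule, directional phase→rate
  coupling and scene-gated dynamics, so every stage has a ground-truth
  recovery test.

## Worked example

Generate a two-electrode session with one planted directed edge
(phase of electrode 1 drives the rate at electrode 2 with a 10 ms lag),
then test both directions:

```r
library(gammawave)

cfg <- preset_config("coupled_pair", seed = 12)
ss  <- generate_session(cfg)
an  <- analytic_series(ss)              # gamma phase via zero-phase filter + Hilbert

fwd <- transfer_entropy(ss$rate[, 2, ], an$phase[, 1, ],
                        fs_hz = 1000, n_boot = 40, seed = 1)
rev <- transfer_entropy(ss$rate[, 1, ], an$phase[, 2, ],
                        fs_hz = 1000, n_boot = 40, seed = 2)
fwd
#> info_estimate: 0.3439 bits (n = 14400, correction = panzeri-treves)
#>   bootstrap null: mean 0.0020, sd 0.0014  ->  Z = 238.06
rev
#> info_estimate: 0.0002 bits (n = 14400, correction = panzeri-treves)
#>   bootstrap null: mean -0.0002, sd 0.0002  ->  Z = 1.79
```

The planted direction carries ~0.34 bits of phase→rate transfer entropy,
overwhelmingly above the common-stimulus null; the reverse direction is
indistinguishable from the null (Z < 2).  A whole-session travelling-wave
analysis is one call — here on the distributed-propagation preset (six
collinear electrodes, all with-wave pairs coupled through direction-gated
gains, planted wave speed 0.36 m/s):

```r
rep <- run_pipeline(preset_config("distributed", seed = 3), n_boot = 40)
rep
#> pipeline_report
#>   TE: 30 ordered pairs, mean Z = 194.98
#>   pair categories: excluded_low_TE=3, other=7, strongly_asymmetric=4, symmetric=1
#>   shift-TE Spearman rho = 0.725 (p = 1.07e-05)
#>   wave speed = 0.359 m/s (slope -1.139 rad/mm)
#>   sensory info: shift -0.0390 bits (Z=-1.3), phase 0.0935 bits (Z=1.1)
#>   stage seconds: preprocess=0.5, coherence=1.28, infotheory=3.44, ...
```

Phase shifts rank-correlate with directed TE (rho = 0.73: causation flows
from the phase-leading site to the phase-lagging site), and the spline
fit of shift against projected distance recovers the planted 0.36 m/s
propagation speed.  The scene information of the phase shift is null here
because this preset keeps the wave direction fixed — the dissociation
(informative shifts, uninformative single-site phase) appears under the
`"scene_gated_pair"` preset, whose schedule flips the wave direction
between scenes.

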