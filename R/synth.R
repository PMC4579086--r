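#' Configuration for a synthetic multi-electrode session
#'
#' Defines a planted travelling narrow-band wave on a rectangular electrode
#' grid, directional phase-to-rate coupling edges, and a piecewise-constant
#' stimulus (scene) schedule that can gate both the wave direction and the
#' coupling gains.  Every random draw of the generator is reproducible from
#' `seed`.
#'
#' The planted phase field is a plane wave
#' \deqn{\phi_e(t) = 2\pi f_0 t - k(t) \cdot x_e + \eta_e(t) + \theta_{trial}}
#' with wavenumber magnitude \eqn{|k| = 2\pi f_0 / v}, so that the wave
#' travels along the per-scene unit direction at speed `speed_m_per_s`.
#' Firing-rate envelopes at "receiving" electrodes are driven by the lagged
#' cosine of the phase at "sending" electrodes (preferred-phase tuning),
#' their own one-sample history and a per-scene stimulus drive, through a
#' softplus nonlinearity that keeps rates nonnegative.
#'
#' @param n_rows,n_cols grid dimensions (default 4 x 4).
#' @param spacing_mm inter-electrode distance in mm (> 0).
#' @param fs_hz sampling rate in Hz; must exceed `2 * f0_hz`.
#' @param f0_hz wave carrier frequency in Hz (gamma-band centre by default).
#' @param speed_m_per_s planted propagation speed in m/s (> 0).
#' @param direction_schedule `n_scenes x 2` matrix of wave unit vectors, one
#'   row per scene.  A zero row means no spatial gradient (global synchrony).
#'   Default: constant propagation along +x.
#' @param phase_noise_sd stationary SD of the per-electrode phase
#'   perturbation, radians.
#' @param phase_noise_tau_ms correlation time of the per-electrode phase
#'   perturbation (AR(1)/Ornstein-Uhlenbeck, default 50 ms, i.e. a few
#'   oscillation cycles).  Local phase fluctuations of a physiological
#'   rhythm persist over cycles rather than being white; this is also what
#'   gives each site a private phase component that directed coupling can
#'   transmit.  Set to 0 for white jitter.
#' @param phase_drift_sd per-sample SD of a shared random-walk phase drift
#'   (radians), one independent walk per trial.  Emulates the finite
#'   linewidth of a physiological band-limited oscillation: the global phase
#'   diffuses within a trial, so phase at a fixed movie time is not
#'   reproducible, while phase differences between electrodes — which the
#'   drift cancels out of — stay locked.  Set to 0 for a strictly periodic
#'   carrier.
#' @param coupling_edges data frame with columns `sender`, `receiver`,
#'   `gain` (>= 0), `lag_ms` and optionally `pref_phase` (radians, default 0):
#'   the planted directed phase-to-rate coupling graph.
#' @param gate_by_direction logical; if `TRUE` each edge gain is scaled at
#'   every sample by `gate_floor + (1 - gate_floor) * max(0, khat . uhat)`,
#'   where `khat` is the instantaneous wave direction and `uhat` the unit
#'   sender-to-receiver axis (enhancement with the wave, suppression against
#'   it).
#' @param gate_floor residual gain fraction against the wave, in \[0, 1\].
#' @param scene_len_ms scene duration; must be a whole number of samples.
#' @param n_trials,n_scenes trial and scene counts.
#' @param trial_phase_offset logical; add a uniform random global phase
#'   offset per trial (phase at a fixed movie time is then not reproducible
#'   across trials, but phase differences between electrodes are).
#' @param lfp_noise_sd SD of additive broadband noise on the band signal.
#' @param rate_noise_sd SD of additive noise on the rate envelope; the
#'   default is of the same order as the stimulus- and coupling-driven
#'   modulation, matching the strong trial-to-trial variability of cortical
#'   firing-rate envelopes.
#' @param rate_baseline,rate_selfhist baseline input `b` and self-history
#'   coefficient `a` of the rate recursion (0 <= a < 1).
#' @param stim_gain gain `c` of the per-scene stimulus drive common to all
#'   trials (the common-stimulus confound the bootstrap null must remove).
#' @param amp_schedule optional length-`n_scenes` vector of nonnegative wave
#'   amplitudes (default all 1).
#' @param seed integer session seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_rows = 4, n_cols = 4, spacing_mm = 2,
                         fs_hz = 1000, f0_hz = 65, speed_m_per_s = 0.36,
                         direction_schedule = NULL, phase_noise_sd = 0.2,
                         phase_noise_tau_ms = 50, phase_drift_sd = 0.1,
                         coupling_edges = NULL, gate_by_direction = FALSE,
                         gate_floor = 0, scene_len_ms = 300,
                         n_trials = 40, n_scenes = 60,
                         trial_phase_offset = TRUE,
                         lfp_noise_sd = 0.2, rate_noise_sd = 0.5,
                         rate_baseline = 1, rate_selfhist = 0.3,
                         stim_gain = 0.5, amp_schedule = NULL, seed = 1) {
  if (spacing_mm <= 0) stop("spacing_mm must be > 0")
  if (fs_hz <= 2 * f0_hz) stop("fs_hz must exceed 2 * f0_hz")
  if (speed_m_per_s <= 0) stop("speed_m_per_s must be > 0")
  if (gate_floor < 0 || gate_floor > 1) stop("gate_floor must be in [0, 1]")
  scene_len_samples <- scene_len_ms * fs_hz / 1000
  if (abs(scene_len_samples - round(scene_len_samples)) > 1e-9) {
    stop("scene_len_ms must be a whole number of samples at fs_hz")
  }
  n_elec <- n_rows * n_cols
  if (is.null(direction_schedule)) {
    direction_schedule <- matrix(rep(c(1, 0), each = n_scenes), ncol = 2)
  }
  direction_schedule <- as.matrix(direction_schedule)
  if (nrow(direction_schedule) != n_scenes || ncol(direction_schedule) != 2) {
    stop("direction_schedule must be an n_scenes x 2 matrix")
  }
  nrm <- sqrt(rowSums(direction_schedule^2))
  bad <- nrm > 0 & abs(nrm - 1) > 1e-6
  if (any(bad)) stop("direction_schedule rows must be unit vectors (or zero)")
  if (!is.null(coupling_edges)) {
    coupling_edges <- as.data.frame(coupling_edges)
    stopifnot(all(c("sender", "receiver", "gain", "lag_ms") %in%
                    names(coupling_edges)))
    if (any(coupling_edges$gain < 0)) stop("coupling gains must be >= 0")
    if (any(coupling_edges$sender < 1 | coupling_edges$sender > n_elec) ||
        any(coupling_edges$receiver < 1 | coupling_edges$receiver > n_elec)) {
      stop("coupling edge endpoints outside the electrode grid")
    }
    if (any(coupling_edges$lag_ms * fs_hz / 1000 < 1)) {
      stop("coupling lags must be at least one sample")
    }
    if (is.null(coupling_edges$pref_phase)) coupling_edges$pref_phase <- 0
  }
  if (is.null(amp_schedule)) amp_schedule <- rep(1, n_scenes)
  if (length(amp_schedule) != n_scenes || any(amp_schedule < 0)) {
    stop("amp_schedule must be n_scenes nonnegative values")
  }
  if (rate_selfhist < 0 || rate_selfhist >= 1) {
    stop("rate_selfhist must be in [0, 1)")
  }
  cfg <- list(
    n_rows = n_rows, n_cols = n_cols, spacing_mm = spacing_mm,
    fs_hz = fs_hz, f0_hz = f0_hz, speed_m_per_s = speed_m_per_s,
    direction_schedule = direction_schedule,
    phase_noise_sd = phase_noise_sd,
    phase_noise_tau_ms = phase_noise_tau_ms,
    phase_drift_sd = phase_drift_sd,
    coupling_edges = coupling_edges,
    gate_by_direction = gate_by_direction, gate_floor = gate_floor,
    scene_len_ms = scene_len_ms, scene_len_samples = as.integer(
      round(scene_len_samples)),
    n_trials = n_trials, n_scenes = n_scenes,
    trial_phase_offset = trial_phase_offset,
    lfp_noise_sd = lfp_noise_sd, rate_noise_sd = rate_noise_sd,
    rate_baseline = rate_baseline, rate_selfhist = rate_selfhist,
    stim_gain = stim_gain, amp_schedule = amp_schedule,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

#' Electrode grid positions in mm
#'
#' Row-major electrode indexing on an `n_rows x n_cols` grid.
#' @param config a [synth_config()].
#' @return `n_elec x 2` matrix of (x, y) positions in mm.
#' @export
grid_positions <- function(config) {
  idx <- expand.grid(col = seq_len(config$n_cols), row = seq_len(config$n_rows))
  pos <- cbind(x = (idx$col - 1) * config$spacing_mm,
               y = (idx$row - 1) * config$spacing_mm)
  rownames(pos) <- NULL
  pos
}

# per-sample 2 x n_t wavevector (rad/m), piecewise constant within scenes
wave_vector_series <- function(config) {
  kmag <- 2 * pi * config$f0_hz / config$speed_m_per_s
  per_scene <- t(config$direction_schedule) * kmag        # 2 x n_scenes
  per_scene[, rep(seq_len(config$n_scenes), each = config$scene_len_samples),
            drop = FALSE]
}

#' Generate the planted travelling-wave phase field
#'
#' @param config a [synth_config()].
#' @return list with `phase`, a `n_trials x n_elec x n_t` array of wrapped
#'   phases (radians), `k_t` the 2 x n_t wavevector series (rad/m) and
#'   `trial_offsets`.
#' @export
generate_wave_field <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(split_seed(config$seed, 1L))
  n_t <- config$n_scenes * config$scene_len_samples
  n_elec <- config$n_rows * config$n_cols
  pos_m <- grid_positions(config) / 1000                   # mm -> m
  k_t <- wave_vector_series(config)                        # 2 x n_t
  tvec <- (seq_len(n_t) - 1) / config$fs_hz
  carrier <- 2 * pi * config$f0_hz * tvec                  # length n_t
  # spatial term: n_elec x n_t
  spatial <- pos_m %*% k_t
  offsets <- if (config$trial_phase_offset) {
    stats::runif(config$n_trials, -pi, pi)
  } else {
    rep(0, config$n_trials)
  }
  phase <- array(NA_real_, dim = c(config$n_trials, n_elec, n_t))
  drift_sd <- config$phase_drift_sd %||% 0
  tau <- config$phase_noise_tau_ms %||% 0
  rho <- if (tau > 0) exp(-1000 / (tau * config$fs_hz)) else 0
  for (tr in seq_len(config$n_trials)) {
    glob <- carrier + offsets[tr]
    if (drift_sd > 0) {
      glob <- glob + cumsum(stats::rnorm(n_t, sd = drift_sd))
    }
    base <- sweep(-spatial, 2, glob, "+")
    if (config$phase_noise_sd > 0) {
      innov <- matrix(stats::rnorm(n_elec * n_t), n_elec, n_t)
      if (rho > 0) {
        # AR(1) with stationary SD = phase_noise_sd
        innov <- t(apply(innov * sqrt(1 - rho^2), 1, function(e)
          as.numeric(stats::filter(e, rho, method = "recursive"))))
      }
      base <- base + config$phase_noise_sd * innov
    }
    phase[tr, , ] <- base
  }
  list(phase = wrap_phase(phase), k_t = k_t, trial_offsets = offsets)
}

#' Generate band-limited field signals from a phase field
#'
#' Signal is `A(t) * cos(phase)` plus broadband Gaussian noise; the amplitude
#' follows the per-scene `amp_schedule`.
#'
#' @param wave result of [generate_wave_field()].
#' @param config the matching [synth_config()].
#' @return array with the dimensions of `wave$phase`.
#' @export
generate_lfp <- function(wave, config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(split_seed(config$seed, 2L))
  amp <- rep(config$amp_schedule, each = config$scene_len_samples)
  lfp <- sweep(cos(wave$phase), 3, amp, "*")
  if (config$lfp_noise_sd > 0) {
    lfp <- lfp + stats::rnorm(length(lfp), sd = config$lfp_noise_sd)
  }
  lfp
}

# per-scene stimulus drive, identical across trials (the common-stimulus
# confound); n_elec x n_scenes standard normal draws
stimulus_drive <- function(config) {
  set.seed(split_seed(config$seed, 3L))
  matrix(stats::rnorm(config$n_rows * config$n_cols * config$n_scenes),
         nrow = config$n_rows * config$n_cols)
}

#' Generate firing-rate envelopes driven by lagged sender phase
#'
#' Implements the rate recursion
#' `rate_j(t) = softplus(b + sum_i g_ij(t) cos(phi_i(t - d_ij) - psi_ij)
#'  + c s_j(t) + a rate_j(t-1)) + noise`, clipped at zero.  When
#' `gate_by_direction` is set, `g_ij(t)` is scaled by the alignment of the
#' instantaneous wave direction with the sender-to-receiver axis.
#'
#' @inheritParams generate_lfp
#' @return nonnegative rate array, `n_trials x n_elec x n_t`.
#' @export
generate_mua <- function(wave, config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(split_seed(config$seed, 4L))
  dims <- dim(wave$phase)
  n_trials <- dims[1]; n_elec <- dims[2]; n_t <- dims[3]
  stim <- stimulus_drive(config)                       # n_elec x n_scenes
  scene_of <- rep(seq_len(config$n_scenes), each = config$scene_len_samples)
  edges <- config$coupling_edges
  gate <- NULL
  if (!is.null(edges) && nrow(edges) > 0) {
    pos <- grid_positions(config)
    lag_s <- as.integer(round(edges$lag_ms * config$fs_hz / 1000))
    # per-edge, per-sample gain multiplier
    gate <- matrix(1, nrow(edges), n_t)
    if (config$gate_by_direction) {
      kmag <- sqrt(colSums(wave$k_t^2))
      khat <- wave$k_t
      khat[, kmag > 0] <- sweep(khat[, kmag > 0, drop = FALSE], 2,
                                kmag[kmag > 0], "/")
      for (e in seq_len(nrow(edges))) {
        u <- pos[edges$receiver[e], ] - pos[edges$sender[e], ]
        u <- u / sqrt(sum(u^2))
        align <- pmax(0, as.numeric(u %*% khat))
        align[kmag == 0] <- 0
        gate[e, ] <- config$gate_floor + (1 - config$gate_floor) * align
      }
    }
  }
  b <- config$rate_baseline
  a <- config$rate_selfhist
  cgain <- config$stim_gain
  rate <- array(0, dim = dims)
  r_prev <- matrix(softplus(b) / (1 - a), n_trials, n_elec)  # warm start
  noise <- if (config$rate_noise_sd > 0) {
    array(stats::rnorm(prod(dims), sd = config$rate_noise_sd), dim = dims)
  } else NULL
  for (t in seq_len(n_t)) {
    drive <- matrix(b, n_trials, n_elec)
    drive <- drive + matrix(cgain * stim[, scene_of[t]], n_trials, n_elec,
                            byrow = TRUE)
    if (!is.null(gate)) {
      for (e in seq_len(nrow(edges))) {
        tp <- t - lag_s[e]
        if (tp >= 1) {
          drive[, edges$receiver[e]] <- drive[, edges$receiver[e]] +
            edges$gain[e] * gate[e, t] *
            cos(wave$phase[, edges$sender[e], tp] - edges$pref_phase[e])
        }
      }
    }
    r_now <- softplus(drive + a * r_prev)
    if (!is.null(noise)) r_now <- r_now + noise[, , t]
    r_now <- pmax(r_now, 0)
    rate[, , t] <- r_now
    r_prev <- r_now
  }
  rate
}

#' Generate a complete synthetic recording session with ground truth
#'
#' Assembles the planted wave field, band signals and firing-rate envelopes
#' into a [recording_session] with scene labels and an attached
#' `ground_truth` record (coupling graph, per-sample wavevector, per-scene
#' direction, planted speed, seed).
#'
#' @param config a [synth_config()].
#' @param seed optional override of `config$seed`.
#' @return object of class `recording_session`.
#' @export
generate_session <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  wave <- generate_wave_field(config)
  lfp <- generate_lfp(wave, config)
  rate <- generate_mua(wave, config)
  n_t <- dim(lfp)[3]
  scene <- rep(seq_len(config$n_scenes), each = config$scene_len_samples)
  gt <- list(
    coupling_edges = config$coupling_edges,
    k_t = wave$k_t,
    direction_schedule = config$direction_schedule,
    speed_m_per_s = config$speed_m_per_s,
    trial_offsets = wave$trial_offsets,
    seed = config$seed
  )
  recording_session(
    lfp = lfp, rate = rate, phase = wave$phase,
    positions = grid_positions(config), fs_hz = config$fs_hz,
    scene = scene, scene_len_ms = config$scene_len_ms,
    config = config, ground_truth = gt
  )
}
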