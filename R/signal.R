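#' Zero-phase band-pass filtering
#'
#' Band-passes a signal with an 8th-order Butterworth filter applied forward
#' and backward (`signal::filtfilt`), giving zero group delay: an in-band
#' sinusoid keeps its peak times exactly.
#'
#' @param x numeric vector (one time series).
#' @param fs_hz sampling rate.
#' @param lo_hz,hi_hz band edges; `0 < lo < hi < fs/2`.
#' @param order filter polynomial order (even; default 8).
#' @return filtered vector, same length as `x`.
#' @export
bandpass <- function(x, fs_hz, lo_hz = 50, hi_hz = 80, order = 8) {
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs_hz / 2)) {
    stop("band edges must satisfy 0 < lo < hi < fs/2")
  }
  if (order %% 2 != 0) stop("order must be even")
  settling <- filter_settling_samples(fs_hz, lo_hz)
  if (length(x) <= 3 * settling) {
    stop("signal too short for the filter settling length (need > ",
         3 * settling, " samples)")
  }
  bf <- signal::butter(order / 2, c(lo_hz, hi_hz) / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# samples within one filter settling length of an edge are masked downstream
filter_settling_samples <- function(fs_hz, lo_hz) {
  as.integer(ceiling(3 * fs_hz / lo_hz))
}

#' Analytic signal: instantaneous phase and amplitude
#'
#' Computes the analytic extension of a band-limited signal by zeroing the
#' negative-frequency half of its spectrum (the discrete Hilbert
#' construction).  For `cos(2 pi f t)` the amplitude is 1 and the unwrapped
#' phase advances `2 pi f / fs` per sample.
#'
#' @param x numeric vector (band-limited).
#' @param amp_tol amplitudes below `amp_tol * max(amplitude)` are flagged as
#'   having undefined phase (`NA`).
#' @return list with `phase` (radians, wrapped to (-pi, pi\], `NA` where
#'   undefined), `amplitude` (nonnegative) and `undefined` (logical mask).
#' @export
analytic_signal <- function(x, amp_tol = 1e-10) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  amplitude <- Mod(z)
  phase <- Arg(z)
  mx <- max(amplitude)
  undefined <- if (mx == 0) rep(TRUE, n) else amplitude < amp_tol * mx
  phase[undefined] <- NA_real_
  list(phase = phase, amplitude = amplitude, undefined = undefined)
}

#' Extract band phase and amplitude for a whole session
#'
#' Band-passes every trial/electrode series of the session's field signal
#' and applies the analytic-signal construction; samples within one filter
#' settling length of the trial edges are masked (`NA` phase).
#'
#' @param session a [recording_session] (or a bare `trials x elec x time`
#'   array with `fs_hz` supplied).
#' @param lo_hz,hi_hz analysis band (defaults: gamma, 50-80 Hz).
#' @param fs_hz sampling rate, required when `session` is a bare array.
#' @param order filter order, see [bandpass()].
#' @return list of class `analytic_series` with arrays `phase` and
#'   `amplitude` (same shape as input), the `band`, `fs_hz` and the number of
#'   edge-masked samples `edge_samples`.
#' @export
analytic_series <- function(session, lo_hz = 50, hi_hz = 80, fs_hz = NULL,
                            order = 8) {
  if (inherits(session, "recording_session")) {
    arr <- session$lfp
    fs_hz <- session$fs_hz
  } else {
    arr <- session
    if (is.null(fs_hz)) stop("fs_hz required for bare arrays")
  }
  d <- dim(arr)
  phase <- array(NA_real_, d)
  amplitude <- array(NA_real_, d)
  edge <- filter_settling_samples(fs_hz, lo_hz)
  keep <- seq_len(d[3]) > edge & seq_len(d[3]) <= d[3] - edge
  for (tr in seq_len(d[1])) {
    for (e in seq_len(d[2])) {
      bp <- bandpass(arr[tr, e, ], fs_hz, lo_hz, hi_hz, order)
      an <- analytic_signal(bp)
      p <- an$phase
      p[!keep] <- NA_real_
      phase[tr, e, ] <- p
      amplitude[tr, e, ] <- an$amplitude
    }
  }
  structure(list(phase = phase, amplitude = amplitude,
                 band = c(lo_hz, hi_hz), fs_hz = fs_hz,
                 edge_samples = edge),
            class = "analytic_series")
}

#' Firing-rate envelope from a wideband signal
#'
#' High-pass filters above `cutoff_hz`, rectifies, and low-pass smooths; the
#' standard multi-unit-activity envelope.  Only needed when raw wideband
#' input is supplied; synthetic sessions carry rate envelopes directly.
#'
#' @param x wideband series.
#' @param fs_hz sampling rate; must exceed `2 * cutoff_hz`.
#' @param cutoff_hz high-pass cutoff (default 1000 Hz).
#' @param smooth_hz low-pass smoothing cutoff for the rectified signal.
#' @return nonnegative envelope, same length as `x`.
#' @export
mua_envelope <- function(x, fs_hz, cutoff_hz = 1000, smooth_hz = 250) {
  if (cutoff_hz >= fs_hz / 2) stop("cutoff_hz must be below Nyquist")
  hp <- signal::butter(4, cutoff_hz / (fs_hz / 2), type = "high")
  rect <- abs(as.numeric(signal::filtfilt(hp, x)))
  lp <- signal::butter(4, smooth_hz / (fs_hz / 2), type = "low")
  pmax(as.numeric(signal::filtfilt(lp, rect)), 0)
}

# DPSS (Slepian) tapers from the symmetric tridiagonal eigenproblem;
# memoised because the eigendecomposition is the expensive step
.taper_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 3, k = 5) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  w <- nw / n
  i <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  # normalise and fix sign convention (positive mean for even orders)
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  .taper_cache[[key]] <- tap
  tap
}

#' Multitaper spatial coherence of a multi-electrode session
#'
#' Magnitude-squared coherence per electrode pair, estimated from Slepian
#' multitaper cross-spectra on nonoverlapping 1 s blocks (within trials),
#' then averaged across pairs.
#'
#' @param session a [recording_session] or bare `trials x elec x time` array.
#' @param fs_hz sampling rate (taken from the session when available).
#' @param block_s block duration in seconds (default 1).
#' @param n_tapers number of Slepian tapers (default 5).
#' @param nw time-bandwidth product (default 3).
#' @return list of class `coherence_spectrum` with `freq_hz`, `mean_coh`,
#'   `sd_coh` (dispersion across pairs) and the full `pair_coh` matrix
#'   (pairs x frequencies).
#' @export
spatial_coherence <- function(session, fs_hz = NULL, block_s = 1,
                              n_tapers = 5, nw = 3) {
  if (inherits(session, "recording_session")) {
    arr <- session$lfp
    fs_hz <- session$fs_hz
  } else {
    arr <- session
    if (is.null(fs_hz)) stop("fs_hz required for bare arrays")
  }
  d <- dim(arr)
  if (d[2] < 2) stop("spatial coherence needs at least 2 electrodes")
  blen <- as.integer(round(block_s * fs_hz))
  if (d[3] < blen) stop("need at least ", block_s, " s of data per trial")
  nblk_per_trial <- d[3] %/% blen
  tap <- dpss_tapers(blen, nw, n_tapers)
  nfreq <- blen %/% 2 + 1
  freq <- (0:(nfreq - 1)) * fs_hz / blen
  nblk <- d[1] * nblk_per_trial
  # tapered FFTs: [freq, taper*block, electrode]
  Xs <- array(complex(real = 0), dim = c(nfreq, nblk * n_tapers, d[2]))
  idx <- 0L
  for (tr in seq_len(d[1])) {
    for (bl in seq_len(nblk_per_trial)) {
      seg <- ((bl - 1) * blen + 1):(bl * blen)
      idx <- idx + 1L
      for (e in seq_len(d[2])) {
        xs <- arr[tr, e, seg]
        xs <- xs - mean(xs)
        ft <- stats::mvfft(tap * xs)[seq_len(nfreq), , drop = FALSE]
        Xs[, ((idx - 1) * n_tapers + 1):(idx * n_tapers), e] <- ft
      }
    }
  }
  pairs <- utils::combn(d[2], 2)
  pair_coh <- matrix(NA_real_, ncol(pairs), nfreq)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    Sxx <- rowMeans(Mod(Xs[, , a])^2)
    Syy <- rowMeans(Mod(Xs[, , b])^2)
    Sxy <- rowMeans(Xs[, , a] * Conj(Xs[, , b]))
    pair_coh[p, ] <- Mod(Sxy)^2 / (Sxx * Syy)
  }
  structure(list(
    freq_hz = freq,
    mean_coh = colMeans(pair_coh),
    sd_coh = apply(pair_coh, 2, stats::sd),
    pair_coh = pair_coh,
    n_blocks = nblk, n_tapers = n_tapers
  ), class = "coherence_spectrum")
}

#' Sliding-window circular statistics of a phase(-shift) series
#'
#' Centred moving window over a wrapped angle series; per window, the
#' circular mean (argument of the mean resultant) and the phase locking
#' value (resultant length).  `NA` angles (masked samples) are excluded from
#' the window; windows with no valid sample give `NA`.
#'
#' @param theta wrapped angle series (radians).
#' @param window_samples window length in samples (>= 3).
#' @return list with `mean` and `plv` series, same length as `theta`.
#' @export
sliding_circular_stats <- function(theta, window_samples) {
  if (window_samples < 3) stop("window must span at least 3 samples")
  if (length(theta) == 0) stop("empty series")
  valid <- !is.na(theta)
  cs <- ifelse(valid, cos(theta), 0)
  sn <- ifelse(valid, sin(theta), 0)
  kern <- rep(1, window_samples)
  csum <- stats::filter(cs, kern, sides = 2)
  ssum <- stats::filter(sn, kern, sides = 2)
  nsum <- stats::filter(as.numeric(valid), kern, sides = 2)
  plv <- sqrt(csum^2 + ssum^2) / nsum
  mn <- atan2(ssum, csum)
  mn[is.na(nsum) | nsum == 0] <- NA_real_
  plv[is.na(nsum) | nsum == 0] <- NA_real_
  list(mean = as.numeric(mn), plv = as.numeric(plv))
}
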