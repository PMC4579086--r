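#' Wrapped phase-shift series for an ordered electrode pair
#'
#' The shift is `phi_send - phi_recv`, wrapped to (-pi, pi]; a positive
#' shift means the sending site's oscillation leads the receiving site's.
#' `NA` (masked) phases propagate.
#'
#' @param phi_send,phi_recv aligned phase arrays/vectors (radians).
#' @return wrapped shift, same shape.
#' @export
phase_shift <- function(phi_send, phi_recv) {
  wrap_phase(phi_send - phi_recv)
}

#' Summary statistics of a phase-shift series
#'
#' @param shift wrapped shift series (vector, matrix or array).
#' @param window_samples optional sliding window for time-resolved circular
#'   mean and PLV (applied along the last dimension, per trial).
#' @return list with the movie-averaged circular `mean`, `plv`, `n`, and
#'   (when a window is given) `sliding`, a list of per-trial mean/PLV series.
#' @export
shift_summary <- function(shift, window_samples = NULL) {
  cs <- circular_stats(as.numeric(shift))
  out <- list(mean = cs$mean, plv = cs$plv, n = cs$n)
  if (!is.null(window_samples)) {
    m <- if (is.null(dim(shift))) matrix(shift, 1) else
      matrix(shift, nrow = prod(utils::head(dim(shift), -1)))
    out$sliding <- apply(m, 1, sliding_circular_stats,
                         window_samples = window_samples, simplify = FALSE)
  }
  out
}

#' Spatial asymmetry index of directed transfer entropy
#'
#' `|t_ab - t_ba| / max(t_ab, t_ba)` on values clipped at zero; 0 means
#' perfectly symmetric interaction, 1 purely one-directional.  Undefined
#' (`NA`) when both clipped values are zero.
#'
#' @param t_ab,t_ba directed TE values (typically Z-scored); vectorised.
#' @return asymmetry index in \[0, 1\] (or `NA`).
#' @export
asymmetry_index <- function(t_ab, t_ba) {
  a <- pmax(t_ab, 0); b <- pmax(t_ba, 0)
  mx <- pmax(a, b)
  ifelse(mx > 0, abs(a - b) / mx, NA_real_)
}

#' Classify electrode pairs by causal asymmetry
#'
#' Removes the fraction of pairs with the lowest (max-direction) TE, then
#' labels the remainder: one direction at least `asym_ratio` times the other
#' gives `strongly_asymmetric`; relative difference below `sym_reldiff`
#' gives `symmetric`; anything else `other`.
#'
#' @param pairs data frame with columns `a`, `b`, `te_ab`, `te_ba` (one row
#'   per unordered pair; TE in Z-score units).
#' @param low_frac fraction of lowest-TE pairs to exclude (default 0.2).
#' @param asym_ratio ratio threshold for strong asymmetry (default 10).
#' @param sym_reldiff relative-difference threshold for symmetry (0.2).
#' @return the input with added columns `asymmetry`, `category`
#'   (`excluded_low_TE`, `strongly_asymmetric`, `symmetric`, `other`) and
#'   `leading` (`"ab"`/`"ba"`/`NA`).
#' @export
classify_pairs <- function(pairs, low_frac = 0.2, asym_ratio = 10,
                           sym_reldiff = 0.2) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("a", "b", "te_ab", "te_ba") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 5) {
    warning("fewer than 5 pairs: classification skipped")
    pairs$asymmetry <- NA_real_
    pairs$category <- NA_character_
    pairs$leading <- NA_character_
    return(pairs)
  }
  cl_ab <- pmax(pairs$te_ab, 0); cl_ba <- pmax(pairs$te_ba, 0)
  strength <- pmax(cl_ab, cl_ba)
  n_excl <- floor(low_frac * n)
  excluded <- rank(strength, ties.method = "first") <= n_excl
  pairs$asymmetry <- asymmetry_index(pairs$te_ab, pairs$te_ba)
  lo <- pmin(cl_ab, cl_ba); hi <- strength
  ratio <- ifelse(lo > 0, hi / lo, Inf)
  reldiff <- ifelse(hi > 0, (hi - lo) / hi, NA_real_)
  category <- rep("other", n)
  category[!is.na(reldiff) & reldiff < sym_reldiff] <- "symmetric"
  category[hi > 0 & ratio >= asym_ratio] <- "strongly_asymmetric"
  category[excluded] <- "excluded_low_TE"
  pairs$category <- category
  pairs$leading <- ifelse(category == "strongly_asymmetric",
                          ifelse(cl_ab >= cl_ba, "ab", "ba"), NA_character_)
  pairs
}

#' Spearman correlation between phase shift and directed transfer entropy
#'
#' Rank correlation, over ordered pairs, between the movie-averaged phase
#' shift (sender minus receiver) and the TE Z-score of that ordered
#' direction.  A positive correlation means causation flows from the
#' phase-leading site to the phase-lagging site.
#'
#' @param shift movie-averaged circular-mean shift per ordered pair (rad).
#' @param te_z TE Z-score per ordered pair, aligned with `shift`.
#' @return list with `rho`, `p.value` and `n`.
#' @export
correlate_shift_causation <- function(shift, te_z) {
  ok <- !is.na(shift) & !is.na(te_z)
  shift <- shift[ok]; te_z <- te_z[ok]
  if (length(shift) < 10) stop("need at least 10 pairs")
  if (length(unique(shift)) < 2 || length(unique(te_z)) < 2) {
    stop("degenerate (ties-only) input")
  }
  ct <- suppressWarnings(stats::cor.test(shift, te_z, method = "spearman"))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = length(shift))
}

#' Segment a phase-shift series into single-signed blocks
#'
#' Per-sample majority vote of the shift sign across trials (exact ties
#' leave the sample unlabeled and break runs); maximal runs of constant sign
#' lasting at least `min_ms` become blocks.
#'
#' @param shift `trials x time` wrapped shift matrix (>= 3 trials).
#' @param fs_hz sampling rate.
#' @param min_ms minimum block duration (default 300 ms).
#' @return list of class `block_segmentation` with `label` (per-sample
#'   -1/0/+1) and `blocks`, a data frame of (`start`, `end`, `sign`,
#'   `n_samples`) in sample indices.
#' @export
segment_blocks <- function(shift, fs_hz, min_ms = 300) {
  shift <- as.matrix(shift)
  if (nrow(shift) < 3) stop("need at least 3 trials for the majority vote")
  sgn <- sign(shift)
  pos <- colSums(sgn > 0, na.rm = TRUE)
  neg <- colSums(sgn < 0, na.rm = TRUE)
  label <- ifelse(pos > neg, 1L, ifelse(neg > pos, -1L, 0L))
  min_samples <- as.integer(round(min_ms * fs_hz / 1000))
  r <- rle(label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= min_samples
  blocks <- data.frame(start = starts[keep], end = ends[keep],
                       sign = r$values[keep], n_samples = r$lengths[keep])
  structure(list(label = label, blocks = blocks,
                 min_samples = min_samples, fs_hz = fs_hz),
            class = "block_segmentation")
}

# balance total duration between sign conditions by randomly down-sampling
# blocks of the longer condition (and trimming the last kept block)
balance_blocks <- function(blocks, seed = NULL, tol = 0.1) {
  pos <- blocks[blocks$sign > 0, , drop = FALSE]
  neg <- blocks[blocks$sign < 0, , drop = FALSE]
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    return(list(pos = pos, neg = neg))
  }
  if (!is.null(seed)) set.seed(seed)
  dur_p <- sum(pos$n_samples); dur_n <- sum(neg$n_samples)
  shrink <- function(bl, target) {
    bl <- bl[sample.int(nrow(bl)), , drop = FALSE]
    cum <- cumsum(bl$n_samples)
    k <- which(cum >= target)[1]
    bl <- bl[seq_len(k), , drop = FALSE]
    over <- sum(bl$n_samples) - target
    if (over > 0) {                         # trim the last kept block
      bl$end[k] <- bl$end[k] - over
      bl$n_samples[k] <- bl$n_samples[k] - over
    }
    bl[bl$n_samples > 0, , drop = FALSE]
  }
  if (dur_p > dur_n * (1 + tol)) pos <- shrink(pos, dur_n)
  if (dur_n > dur_p * (1 + tol)) neg <- shrink(neg, dur_p)
  list(pos = pos, neg = neg)
}

blocks_to_strata <- function(blocks, n_trials, n_t) {
  strata <- matrix(NA_integer_, n_trials, n_t)
  if (nrow(blocks) > 0) {
    for (i in seq_len(nrow(blocks))) {
      strata[, blocks$start[i]:blocks$end[i]] <- i
    }
  }
  strata
}

#' Block-conditioned transfer entropy
#'
#' Computes TE (with its bootstrap null) separately within positive-shift
#' and negative-shift blocks of a [segment_blocks()] segmentation, after
#' randomly down-sampling the blocks of the longer condition so both
#' conditions use approximately the same total duration (within 10%).
#' Embeddings never cross block boundaries.
#'
#' @param x,y target and source `trials x time` matrices (see
#'   [transfer_entropy()]).
#' @param segmentation a `block_segmentation`.
#' @param fs_hz sampling rate.
#' @param seed seed controlling both the block down-sampling and the
#'   bootstrap derangements.
#' @param ... passed to [transfer_entropy()] (`lag_ms`, `n_bins`, `n_boot`,
#'   ...).
#' @return list with `positive` and `negative` `info_estimate`s (`NULL`
#'   when a sign has no block) and the balanced `durations` (samples).
#' @export
block_conditioned_te <- function(x, y, segmentation, fs_hz, seed = NULL,
                                 ...) {
  stopifnot(inherits(segmentation, "block_segmentation"))
  bal <- balance_blocks(segmentation$blocks,
                        seed = if (is.null(seed)) NULL else
                          split_seed(seed, 91L))
  x <- as.matrix(x)
  run <- function(bl, k) {
    if (nrow(bl) == 0) return(NULL)
    strata <- blocks_to_strata(bl, nrow(x), ncol(x))
    transfer_entropy(x, y, fs_hz = fs_hz, strata = strata,
                     seed = if (is.null(seed)) NULL else split_seed(seed, k),
                     ...)
  }
  list(positive = run(bal$pos, 92L),
       negative = run(bal$neg, 93L),
       durations = c(pos = sum(bal$pos$n_samples),
                     neg = sum(bal$neg$n_samples)))
}

#' Signed projected distance of an electrode along a reference causal axis
#'
#' The candidate is included iff the displacement from it to the reference
#' receiving electrode lies within `cone_deg` of the pair's causal
#' (sender-to-receiver) direction; its coordinate is the projection of
#' (candidate - receiver) onto the causal unit vector, so upstream
#' electrodes get negative coordinates and the receiver sits at 0.
#'
#' @param positions `n_elec x 2` matrix (mm).
#' @param sender,receiver indices of the reference causal pair.
#' @param candidate index of the electrode to project.
#' @param cone_deg half-angle of the acceptance cone (default 45).
#' @return list with `distance_mm` (signed) and `included` (logical).
#' @export
projected_distance <- function(positions, sender, receiver, candidate,
                               cone_deg = 45) {
  u <- positions[receiver, ] - positions[sender, ]
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("zero-length reference pair axis")
  u <- u / nu
  d <- positions[receiver, ] - positions[candidate, ]
  nd <- sqrt(sum(d^2))
  if (nd == 0) {                            # the receiver itself
    return(list(distance_mm = 0, included = TRUE))
  }
  ang <- acos(pmin(1, pmax(-1, sum(d * u) / nd))) * 180 / pi
  coord <- sum((positions[candidate, ] - positions[receiver, ]) * u)
  list(distance_mm = unname(coord), included = ang <= cone_deg + 1e-9)
}

#' Phase-shift versus projected-distance profile along reference causal pairs
#'
#' For each reference (strongly asymmetric) pair, selects the electrodes
#' within the 45-degree cone around the causal axis, measures their
#' movie-averaged circular-mean phase shift relative to the reference
#' receiving site, and records their projected distances.  If the minimum
#' shift is achieved not by the reference receiver but by the receiver of
#' another reference pair, the origin is re-anchored to that site, so that
#' the origin always marks the final target of the wave propagation.
#' Shifts are optionally unwrapped along each profile (ordered by distance
#' from the origin) so that steep planted gradients are not folded back
#' into (-pi, pi].
#'
#' @param phase `trials x elec x time` phase array (radians, `NA` masked).
#' @param positions `n_elec x 2` electrode positions (mm).
#' @param ref_pairs data frame with columns `sender`, `receiver` (one row
#'   per reference causal pair).
#' @param cone_deg acceptance cone half-angle (default 45).
#' @param unwrap unwrap shifts along each profile (default `TRUE`).
#' @return data frame with `ref` (pair row), `electrode`, `distance_mm`,
#'   `shift` (radians).
#' @export
wave_profile <- function(phase, positions, ref_pairs, cone_deg = 45,
                         unwrap = TRUE) {
  ref_pairs <- as.data.frame(ref_pairs)
  n_elec <- dim(phase)[2]
  receivers <- unique(ref_pairs$receiver)
  mean_shift_to <- function(anchor, others) {
    vapply(others, function(e) {
      circular_stats(phase_shift(phase[, e, ], phase[, anchor, ]))$mean
    }, numeric(1))
  }
  out <- list()
  for (i in seq_len(nrow(ref_pairs))) {
    s <- ref_pairs$sender[i]; r <- ref_pairs$receiver[i]
    proj <- lapply(seq_len(n_elec), function(e)
      projected_distance(positions, s, r, e, cone_deg))
    inc <- which(vapply(proj, `[[`, logical(1), "included"))
    if (length(inc) < 2) next
    shifts <- mean_shift_to(r, inc)
    dist <- vapply(proj[inc], `[[`, numeric(1), "distance_mm")
    ord <- order(-dist)                     # from the origin upstream
    dist <- dist[ord]; shifts <- shifts[ord]; elecs <- inc[ord]
    if (unwrap && length(shifts) > 1) {
      dphi <- diff(shifts)
      shifts <- shifts[1] + c(0, cumsum(wrap_phase(dphi)))
    }
    # re-anchor: the origin must be the final target of the propagation —
    # if the minimum (unwrapped) shift is achieved by the receiver of
    # another reference pair, that site becomes the origin
    m <- elecs[which.min(shifts)]
    if (m != r && m %in% receivers) {
      k <- which(elecs == m)[1]
      dist <- dist - dist[k]
      shifts <- shifts - shifts[k]
    }
    out[[length(out) + 1]] <- data.frame(
      ref = i, electrode = elecs, distance_mm = dist, shift = shifts)
  }
  if (length(out) == 0) {
    return(data.frame(ref = integer(), electrode = integer(),
                      distance_mm = numeric(), shift = numeric()))
  }
  do.call(rbind, out)
}

#' Travelling-wave propagation speed from a phase-gradient profile
#'
#' Fits a cubic smoothing spline (penalty chosen by generalized
#' cross-validation) to the pooled (projected distance, phase shift)
#' samples, takes the tangent slope at the origin — where the spatial
#' derivative of the phase is largest — and converts it with
#' `speed = 2 pi f / |slope|`.  Uncertainty is estimated by bootstrap over
#' reference pairs.
#'
#' @param profile data frame from [wave_profile()].
#' @param f_hz carrier frequency used in the conversion (band centre by
#'   default in the pipeline).
#' @param slope_tol slopes below this (rad/mm) flag global synchrony:
#'   `speed = Inf`, no numeric estimate.
#' @param n_boot bootstrap resamples over reference pairs (0 = none).
#' @param seed bootstrap seed.
#' @return list with `speed_m_per_s`, `slope_rad_per_mm`, `speed_sd`
#'   (bootstrap SD or `NA`), `n_points`, `infinite` flag.
#' @export
wave_speed <- function(profile, f_hz, slope_tol = 1e-3, n_boot = 0,
                       seed = NULL) {
  if (length(unique(profile$distance_mm)) < 4) {
    stop("need at least 4 distinct projected distances")
  }
  fit_slope <- function(df) {
    sp <- stats::smooth.spline(df$distance_mm, df$shift, cv = FALSE)
    stats::predict(sp, 0, deriv = 1)$y
  }
  slope <- fit_slope(profile)
  if (abs(slope) < slope_tol) {
    return(list(speed_m_per_s = Inf, slope_rad_per_mm = slope,
                speed_sd = NA_real_, n_points = nrow(profile),
                infinite = TRUE))
  }
  speed <- 2 * pi * f_hz / (abs(slope) * 1000)   # rad/mm -> m/s
  sd_boot <- NA_real_
  if (n_boot > 0) {
    refs <- unique(profile$ref)
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(refs, length(refs), replace = TRUE)
      df <- do.call(rbind, lapply(pick, function(r)
        profile[profile$ref == r, , drop = FALSE]))
      if (length(unique(df$distance_mm)) < 4) return(NA_real_)
      sl <- tryCatch(fit_slope(df), error = function(e) NA_real_)
      if (is.na(sl) || abs(sl) < slope_tol) NA_real_ else
        2 * pi * f_hz / (abs(sl) * 1000)
    }, numeric(1))
    sd_boot <- stats::sd(boots, na.rm = TRUE)
  }
  list(speed_m_per_s = speed, slope_rad_per_mm = slope, speed_sd = sd_boot,
       n_points = nrow(profile), infinite = FALSE)
}
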