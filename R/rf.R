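# separable box-filter smoothing of one frame (sliding-window average)
box_smooth <- function(frame, w) {
  k <- rep(1 / w, w)
  sm <- t(apply(frame, 1, function(r) as.numeric(stats::filter(r, k,
                                                               sides = 2))))
  sm <- apply(sm, 2, function(cl) as.numeric(stats::filter(cl, k, sides = 2)))
  # replicate edges where the window runs out of the frame
  sm[is.na(sm)] <- mean(frame)
  sm
}

#' Reverse-correlation receptive-field map from gamma power and a movie
#'
#' Each movie frame is smoothed with a sliding-window average, spatially
#' down-sampled, and optionally cleaned by removing the largest singular
#' value decomposition components of the pixels-by-time luminance matrix
#' (which carry the global correlations of natural stimuli).  Per pixel, the
#' luminance series is correlated with the band power at a fixed neural lag;
#' per-repeat correlation maps are converted to Z (Fisher transform) and
#' combined across repeats.
#'
#' @param power band-power series at the frame rate: vector (one repeat) or
#'   `repeats x frames` matrix.
#' @param movie luminance array, `ny x nx x frames`.
#' @param frame_rate_hz analysis frame rate (default 66).
#' @param lag_ms neural response lag (default 60 ms).
#' @param n_svd_remove number of leading SVD components to remove (0-2).
#' @param smooth_px sliding-window width for spatial smoothing (default 6).
#' @param downsample spatial down-sampling factor (default 4).
#' @return list of class `rf_map` with `z` (Z-scored map, down-sampled
#'   pixels), `downsample`, `n_repeats`.
#' @export
reverse_correlation_map <- function(power, movie, frame_rate_hz = 66,
                                    lag_ms = 60, n_svd_remove = 1,
                                    smooth_px = 6, downsample = 4) {
  if (is.null(dim(power))) power <- matrix(power, nrow = 1)
  n_frames <- dim(movie)[3]
  if (ncol(power) != n_frames) {
    stop("power series and movie must have the same number of frames")
  }
  lag_f <- as.integer(round(lag_ms * frame_rate_hz / 1000))
  rows <- seq(1, dim(movie)[1], by = downsample)
  cols <- seq(1, dim(movie)[2], by = downsample)
  L <- matrix(NA_real_, length(rows) * length(cols), n_frames)
  for (f in seq_len(n_frames)) {
    sm <- box_smooth(movie[, , f], smooth_px)
    L[, f] <- as.numeric(sm[rows, cols])
  }
  if (n_svd_remove > 0) {
    mu <- rowMeans(L)
    Lc <- L - mu
    sv <- svd(Lc, nu = n_svd_remove, nv = n_svd_remove)
    L <- Lc - sv$u %*% (diag(sv$d[seq_len(n_svd_remove)],
                             n_svd_remove) %*% t(sv$v)) + mu
  }
  t_stim <- seq_len(n_frames - lag_f)
  t_resp <- t_stim + lag_f
  n_eff <- length(t_stim)
  zmaps <- matrix(NA_real_, nrow(power), nrow(L))
  for (rep_i in seq_len(nrow(power))) {
    p <- power[rep_i, t_resp]
    r <- suppressWarnings(stats::cor(t(L[, t_stim, drop = FALSE]), p))
    r[is.na(r)] <- 0
    r <- pmin(pmax(r, -0.999999), 0.999999)
    zmaps[rep_i, ] <- atanh(r) * sqrt(max(n_eff - 3, 1))
  }
  z <- colMeans(zmaps) * sqrt(nrow(power))
  structure(list(z = matrix(z, length(rows), length(cols)),
                 downsample = downsample, n_repeats = nrow(power)),
            class = "rf_map")
}

#' Receptive field from a correlation map
#'
#' The RF centre is the map argmax; the extent is the smallest square
#' around it whose border values all fall below `threshold_frac` of the map
#' maximum (border pixels outside the map count as below threshold).
#'
#' @param map numeric matrix (e.g. the `z` field of an `rf_map`) or an
#'   `rf_map`.
#' @param threshold_frac border threshold as a fraction of the maximum
#'   (default 0.75).
#' @return list of class `receptive_field` with `center` (row, col),
#'   `halfwidth_px`, `side_px`, `undefined` flag (flat map).
#' @export
rf_from_map <- function(map, threshold_frac = 0.75) {
  if (inherits(map, "rf_map")) map <- map$z
  if (max(map) == min(map)) {
    return(structure(list(center = c(NA, NA), halfwidth_px = NA,
                          side_px = NA, undefined = TRUE),
                     class = "receptive_field"))
  }
  mx <- max(map)
  ctr <- which(map == mx, arr.ind = TRUE)[1, ]
  thr <- threshold_frac * mx
  nr <- nrow(map); nc <- ncol(map)
  h <- 0
  repeat {
    h <- h + 1
    rr <- (ctr[1] - h):(ctr[1] + h)
    cc <- (ctr[2] - h):(ctr[2] + h)
    border_vals <- c(
      if (ctr[1] - h >= 1) map[ctr[1] - h, cc[cc >= 1 & cc <= nc]],
      if (ctr[1] + h <= nr) map[ctr[1] + h, cc[cc >= 1 & cc <= nc]],
      if (ctr[2] - h >= 1) map[rr[rr >= 1 & rr <= nr], ctr[2] - h],
      if (ctr[2] + h <= nc) map[rr[rr >= 1 & rr <= nr], ctr[2] + h])
    if (length(border_vals) == 0 || all(border_vals < thr)) break
    if (h > max(nr, nc)) break
  }
  structure(list(center = unname(ctr), halfwidth_px = h, side_px = 2 * h + 1,
                 undefined = FALSE),
            class = "receptive_field")
}

rf_pixels <- function(rf, nr, nc) {
  rr <- max(1, rf$center[1] - rf$halfwidth_px):min(nr, rf$center[1] +
                                                     rf$halfwidth_px)
  cc <- max(1, rf$center[2] - rf$halfwidth_px):min(nc, rf$center[2] +
                                                     rf$halfwidth_px)
  list(rows = rr, cols = cc)
}

#' Local time contrast within a receptive field
#'
#' Frame-to-frame RMS luminance change over the RF pixels, normalised by
#' the mean RF luminance; the first frame gets 0.
#'
#' @param movie luminance array `ny x nx x frames`.
#' @param rf a `receptive_field` (pixel units of `movie`).
#' @return nonnegative per-frame series; if the mean luminance is zero the
#'   unnormalised RMS is returned with attribute `unnormalised = TRUE`.
#' @export
time_contrast <- function(movie, rf) {
  if (dim(movie)[3] < 2) stop("need at least 2 frames")
  px <- rf_pixels(rf, dim(movie)[1], dim(movie)[2])
  cube <- movie[px$rows, px$cols, , drop = FALSE]
  n <- dim(cube)[3]
  dif <- cube[, , 2:n, drop = FALSE] - cube[, , 1:(n - 1), drop = FALSE]
  tc <- c(0, sqrt(apply(dif^2, 3, mean)))
  mu <- mean(cube)
  if (mu == 0) {
    attr(tc, "unnormalised") <- TRUE
    return(tc)
  }
  tc / mu
}

# gradient of one frame restricted to the RF (central differences)
rf_gradient <- function(frame, px) {
  sub <- frame[px$rows, px$cols, drop = FALSE]
  nr <- nrow(sub); nc <- ncol(sub)
  if (nr < 2 || nc < 2) stop("RF must span at least 2 x 2 pixels")
  gx <- (sub[, c(2:nc, nc)] - sub[, c(1, 1:(nc - 1))]) / 2
  gy <- (sub[c(2:nr, nr), ] - sub[c(1, 1:(nr - 1)), ]) / 2
  list(mag = sqrt(gx^2 + gy^2), theta = atan2(gy, gx) %% pi)
}

#' Orientation activation of a receptive field
#'
#' Per frame, the gradient-magnitude-weighted mean over RF pixels of
#' `cos^2(theta_gradient - theta_preferred)`; lies in \[0, 1\] and is
#' invariant to luminance offset and gain.  Frames with zero gradient
#' everywhere are masked (`NA`).
#'
#' @param movie luminance array.
#' @param rf a `receptive_field` spanning at least 2 x 2 pixels.
#' @param preferred_orientation preferred gradient orientation, radians in
#'   \[0, pi).
#' @return per-frame series in \[0, 1\] (with `NA` for gradient-free frames).
#' @export
orientation_activation <- function(movie, rf, preferred_orientation) {
  px <- rf_pixels(rf, dim(movie)[1], dim(movie)[2])
  vapply(seq_len(dim(movie)[3]), function(f) {
    g <- rf_gradient(movie[, , f], px)
    w <- sum(g$mag)
    if (w == 0) return(NA_real_)
    sum(g$mag * cos(g$theta - preferred_orientation)^2) / w
  }, numeric(1))
}

#' Orientation tuning curve of firing activity from movie gradients
#'
#' Bins the RF gradient energy of each frame into orientation bins over
#' \[0, pi), then correlates each bin's energy series with the firing
#' series at a fixed lag.  Tuning similarity between two sites is the
#' covariance between their curves.
#'
#' @param mua firing series at the frame rate.
#' @param movie luminance array.
#' @param rf a `receptive_field`.
#' @param n_orientation_bins number of orientation bins (default 8).
#' @param lag_frames neural lag in frames (default 0; the caller aligns).
#' @return list of class `tuning_curve` with `orientation` (bin centres,
#'   rad), `curve` (correlations) and `preferred` (argmax orientation).
#' @export
orientation_tuning <- function(mua, movie, rf, n_orientation_bins = 8,
                               lag_frames = 0) {
  n_frames <- dim(movie)[3]
  stopifnot(length(mua) == n_frames)
  if (stats::sd(mua) == 0) stop("constant firing series")
  px <- rf_pixels(rf, dim(movie)[1], dim(movie)[2])
  edges <- seq(0, pi, length.out = n_orientation_bins + 1)
  energy <- matrix(0, n_frames, n_orientation_bins)
  for (f in seq_len(n_frames)) {
    g <- rf_gradient(movie[, , f], px)
    bin <- pmin(findInterval(as.numeric(g$theta), edges,
                             rightmost.closed = TRUE), n_orientation_bins)
    energy[f, ] <- vapply(seq_len(n_orientation_bins),
                          function(b) sum(g$mag[bin == b]), numeric(1))
  }
  t_stim <- seq_len(n_frames - lag_frames)
  resp <- mua[t_stim + lag_frames]
  curve <- suppressWarnings(
    as.numeric(stats::cor(energy[t_stim, , drop = FALSE], resp)))
  curve[is.na(curve)] <- 0
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(orientation = centres, curve = curve,
                 preferred = centres[which.max(curve)]),
            class = "tuning_curve")
}

#' Covariance similarity between two orientation tuning curves
#'
#' @param a,b `tuning_curve` objects on the same orientation grid.
#' @return covariance of the two curves.
#' @export
tuning_similarity <- function(a, b) {
  stopifnot(length(a$curve) == length(b$curve))
  stats::cov(a$curve, b$curve)
}

#' Directed motion along a receptive-field pair axis
#'
#' The positive part of the projection of the optic-flow vector at the
#' sending RF onto the unit axis from the sending to the receiving RF
#' centre (visual-field coordinates).
#'
#' @param flow `frames x 2` matrix of optic-flow vectors at the sending RF.
#' @param send_center,recv_center RF centres, length-2 (x, y) in degrees.
#' @return nonnegative per-frame series.
#' @export
directed_motion <- function(flow, send_center, recv_center) {
  u <- recv_center - send_center
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("coincident RF centres")
  pmax(0, as.numeric(as.matrix(flow) %*% (u / nu)))
}

#' Toy rigid-translation optic flow
#'
#' Constant flow field (one 2-vector per frame) for testing the directed
#' motion feature.
#'
#' @param n_frames number of frames.
#' @param velocity length-2 (x, y) flow vector, degrees per frame.
#' @return `n_frames x 2` matrix.
#' @export
rigid_translation_flow <- function(n_frames, velocity) {
  matrix(rep(as.numeric(velocity), each = n_frames), n_frames, 2)
}

#' Correlation between a (combined) stimulus feature and a neural signal
#'
#' Correlates a per-frame feature from the sending RF, the receiving RF,
#' their sum, or their difference (sender minus receiver) with a target
#' series (firing rate or windowed phase shift) across time.
#'
#' @param feat_send,feat_recv per-frame feature series.
#' @param target aligned target series.
#' @param combine one of `"send"`, `"recv"`, `"sum"`, `"diff"`.
#' @return Pearson correlation.
#' @export
feature_signal_correlation <- function(feat_send, feat_recv = NULL, target,
                                       combine = c("send", "recv", "sum",
                                                   "diff")) {
  combine <- match.arg(combine)
  if (combine != "send" && is.null(feat_recv)) {
    stop("feat_recv required for combine = ", combine)
  }
  f <- switch(combine,
              send = feat_send,
              recv = feat_recv,
              sum = feat_send + feat_recv,
              diff = feat_send - feat_recv)
  ok <- !is.na(f) & !is.na(target)
  if (stats::sd(f[ok]) == 0 || stats::sd(target[ok]) == 0) {
    stop("constant series")
  }
  stats::cor(f[ok], target[ok])
}
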