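#' Equipopulated (quantile) binning
#'
#' Rank-based discretisation into `n_bins` symbols with occupancies that
#' differ by at most one; ties are broken by stable (first-occurrence) rank,
#' so the estimators built on top are invariant to any monotone transform of
#' the input.
#'
#' @param values numeric vector; `NA` values keep an `NA` symbol.
#' @param n_bins number of bins (>= 2).
#' @return list of class `discrete_series` with integer `symbols` in
#'   `1..n_bins`, `n_bins`, and the quantile `edges` used.
#' @export
equipopulated_bin <- function(values, n_bins) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < n_bins) stop("not enough samples to fill ", n_bins, " bins")
  if (max(v) == min(v)) {
    stop("constant input: no informative equipopulated binning exists")
  }
  r <- rank(v, ties.method = "first")
  sym <- ceiling(r * n_bins / length(v))
  symbols <- rep(NA_integer_, length(values))
  symbols[ok] <- as.integer(sym)
  edges <- stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE)
  structure(list(symbols = symbols, n_bins = as.integer(n_bins),
                 edges = edges), class = "discrete_series")
}

#' Plug-in Shannon entropy in bits
#'
#' @param counts nonnegative occupancy counts; must sum to > 0.
#' @return entropy `-sum p log2 p` in bits.
#' @export
entropy_bits <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  if (n == 0) stop("all-zero counts")
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# integer symbols for the product alphabet of two symbol vectors
joint_symbols <- function(a, ka, b, kb) {
  (a - 1L) * kb + b
}

as_symbols <- function(x) {
  if (inherits(x, "discrete_series")) {
    list(sym = x$symbols, k = x$n_bins)
  } else {
    sym <- as.integer(x)
    list(sym = sym, k = max(sym, na.rm = TRUE))
  }
}

# first-order residual-bias term (occupied-bin counting) for MI(R;S):
# bias = [ sum_s (B_s - 1) - (B - 1) ] / (2 N ln 2)
pt_bias <- function(r_sym, s_sym, kr) {
  n <- length(r_sym)
  b_all <- length(unique(r_sym))
  b_per <- tapply(r_sym, s_sym, function(v) length(unique(v)))
  (sum(b_per - 1) - (b_all - 1)) / (2 * n * log(2))
}

mi_plugin_sym <- function(r_sym, s_sym) {
  tab <- table(r_sym, s_sym)
  n <- sum(tab)
  hr <- entropy_bits(rowSums(tab))
  hs <- entropy_bits(colSums(tab))
  hrs <- entropy_bits(as.numeric(tab))
  hr + hs - hrs
}

#' Mutual information between a discrete response and stimulus labels
#'
#' Plug-in MI with a limited-sampling bias correction: either the
#' first-order residual-bias (occupied-bin) term (`"panzeri-treves"`), the
#' mean of `n_shuffle` label-shuffled estimates subtracted
#' (`"shuffle"`), or none.  Joint responses can be formed with
#' [joint_response()].
#'
#' @param r response: a `discrete_series` from [equipopulated_bin()] or an
#'   integer symbol vector.
#' @param s stimulus labels (factor/integer), aligned with `r`.
#' @param correction one of `"panzeri-treves"`, `"shuffle"`, `"none"`.
#' @param n_shuffle shuffles for the shuffle correction.
#' @return object of class `info_estimate` (fields `value` in bits,
#'   `correction`, `n`).
#' @export
mutual_information <- function(r, s,
                               correction = c("panzeri-treves", "shuffle",
                                              "none"),
                               n_shuffle = 20) {
  correction <- match.arg(correction)
  rr <- as_symbols(r)
  s <- as.integer(factor(s))
  ok <- !is.na(rr$sym) & !is.na(s)
  r_sym <- rr$sym[ok]; s_sym <- s[ok]
  if (length(unique(s_sym)) < 2) stop("need at least 2 stimulus classes")
  value <- mi_plugin_sym(r_sym, s_sym)
  if (correction == "panzeri-treves") {
    value <- value - pt_bias(r_sym, s_sym, rr$k)
  } else if (correction == "shuffle") {
    sh <- replicate(n_shuffle, mi_plugin_sym(sample(r_sym), s_sym))
    value <- value - mean(sh)
  }
  info_estimate(value, correction = correction, n = length(r_sym))
}

#' Combine two discrete responses into their product alphabet
#'
#' @param a,b `discrete_series` objects or integer symbol vectors.
#' @return a `discrete_series` over the product alphabet.
#' @export
joint_response <- function(a, b) {
  aa <- as_symbols(a); bb <- as_symbols(b)
  structure(list(symbols = joint_symbols(aa$sym, aa$k, bb$sym, bb$k),
                 n_bins = aa$k * bb$k, edges = NULL),
            class = "discrete_series")
}

#' Conditional mutual information I(X; Y | Z) between discrete series
#'
#' Computed as `I(X; (Y,Z)) - I(X; Z)`, each term bias-corrected as in
#' [mutual_information()].  This is the estimator core shared by transfer
#' entropy and the lagged conditional information variants.
#'
#' @param x,y,z integer symbol vectors (or `discrete_series`).
#' @param correction,n_shuffle see [mutual_information()].
#' @return `info_estimate`; `value` in bits.
#' @export
conditional_mutual_information <- function(x, y, z,
                                           correction = c("panzeri-treves",
                                                          "shuffle", "none"),
                                           n_shuffle = 20) {
  correction <- match.arg(correction)
  xx <- as_symbols(x); yy <- as_symbols(y); zz <- as_symbols(z)
  ok <- !is.na(xx$sym) & !is.na(yy$sym) & !is.na(zz$sym)
  xs <- xx$sym[ok]; ys <- yy$sym[ok]; zs <- zz$sym[ok]
  n <- length(xs)
  if (n == 0) stop("no complete samples")
  yz <- joint_symbols(ys, yy$k, zs, zz$k)
  v1 <- mi_plugin_sym(yz, xs)
  v2 <- mi_plugin_sym(zs, xs)
  if (correction == "panzeri-treves") {
    v1 <- v1 - pt_bias(yz, xs, yy$k * zz$k)
    v2 <- v2 - pt_bias(zs, xs, zz$k)
  } else if (correction == "shuffle") {
    # shuffle Y within strata of Z: preserves I(X;Z), nulls the conditional
    sh <- replicate(n_shuffle, {
      ys_sh <- ys
      for (zl in unique(zs)) {
        i <- which(zs == zl)
        ys_sh[i] <- ys[i][sample.int(length(i))]
      }
      yz_sh <- joint_symbols(ys_sh, yy$k, zs, zz$k)
      mi_plugin_sym(yz_sh, xs) - v2
    })
    return(info_estimate(v1 - v2 - mean(sh), correction = correction, n = n))
  }
  info_estimate(v1 - v2, correction = correction, n = n)
}

info_estimate <- function(value, correction = "none", n = NA_integer_,
                          z = NA_real_, null_mean = NA_real_,
                          null_sd = NA_real_, low_confidence = FALSE) {
  structure(list(value = value, correction = correction, n = n, z = z,
                 null_mean = null_mean, null_sd = null_sd,
                 low_confidence = low_confidence),
            class = "info_estimate")
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf("info_estimate: %.4f bits (n = %d, correction = %s)\n",
              x$value, x$n, x$correction))
  if (!is.na(x$z)) {
    cat(sprintf("  bootstrap null: mean %.4f, sd %.4f  ->  Z = %.2f\n",
                x$null_mean, x$null_sd, x$z))
  }
  if (isTRUE(x$low_confidence)) cat("  flagged: low confidence (sparse joint)\n")
  invisible(x)
}

# ---- directed information on trial x time series ---------------------------

# discretise a trial x time matrix pooled across trials
bin_matrix <- function(m, n_bins) {
  b <- equipopulated_bin(as.numeric(m), n_bins)
  matrix(b$symbols, nrow = nrow(m))
}

# embedding bookkeeping shared by TE/LCI and their bootstrap nulls
build_embedding <- function(n_t, fs_hz, lag_ms, step_ms) {
  lag <- max(1L, as.integer(round(lag_ms * fs_hz / 1000)))
  step <- max(1L, as.integer(round(step_ms * fs_hz / 1000)))
  t_idx <- seq.int(lag + 1L, n_t, by = step)
  list(lag = lag, t_idx = t_idx)
}

# tabulate-based conditional MI with the first-order residual-bias term;
# identical in value to conditional_mutual_information() but O(n) per call
fast_cmi <- function(xs, ys, zs, kx, ky, kz,
                     correction = "panzeri-treves") {
  n <- length(xs)
  yz <- (ys - 1L) * kz + zs
  xz <- (xs - 1L) * kz + zs
  xyz <- (xs - 1L) * (ky * kz) + yz
  H <- function(cnt) {
    cnt <- cnt[cnt > 0]
    p <- cnt / n
    -sum(p * log2(p))
  }
  cz <- tabulate(zs, kz)
  cyz <- tabulate(yz, ky * kz)
  cxz <- tabulate(xz, kx * kz)
  cxyz <- tabulate(xyz, kx * ky * kz)
  v <- H(cxz) + H(cyz) - H(cz) - H(cxyz)
  if (correction == "panzeri-treves") {
    occ_yz_by_x <- colSums(matrix(cxyz > 0, ky * kz, kx))
    occ_z_by_x <- colSums(matrix(cxz > 0, kz, kx))
    bias1 <- (sum(occ_yz_by_x - 1) - (sum(cyz > 0) - 1)) / (2 * n * log(2))
    bias2 <- (sum(occ_z_by_x - 1) - (sum(cz > 0) - 1)) / (2 * n * log(2))
    v <- v - (bias1 - bias2)
  } else if (correction == "shuffle") {
    sh <- vapply(seq_len(20), function(b) {
      # permute y within z strata: preserves I(X;Z), nulls the conditional
      ys_sh <- as.integer(stats::ave(ys, zs, FUN = function(v)
        v[sample.int(length(v))]))
      yz_sh <- (ys_sh - 1L) * kz + zs
      xyz_sh <- (xs - 1L) * (ky * kz) + yz_sh
      H(cxz) + H(tabulate(yz_sh, ky * kz)) - H(cz) -
        H(tabulate(xyz_sh, kx * ky * kz))
    }, numeric(1))
    v <- v - mean(sh)
  }
  v
}

directed_info_core <- function(x, y, cond, fs_hz, lag_ms, step_ms, n_bins,
                               correction, n_boot, strata, seed,
                               min_cell_mean = 5) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.null(cond)) cond <- as.matrix(cond)
  stopifnot(identical(dim(x), dim(y)))
  n_tr <- nrow(x); n_t <- ncol(x)
  emb <- build_embedding(n_t, fs_hz, lag_ms, step_ms)
  t_now <- emb$t_idx; t_past <- t_now - emb$lag
  bx <- bin_matrix(x, n_bins)
  by <- bin_matrix(y, n_bins)
  bc <- if (is.null(cond)) bx else bin_matrix(cond, n_bins)
  if (is.null(strata)) strata <- matrix(1L, n_tr, n_t)
  xt <- bx[, t_now, drop = FALSE]
  cp <- bc[, t_past, drop = FALSE]
  st_now <- strata[, t_now, drop = FALSE]
  st_past <- strata[, t_past, drop = FALSE]
  same_block <- !is.na(st_now) & !is.na(st_past) & st_now == st_past
  base_ok <- same_block & !is.na(xt) & !is.na(cp)
  eval_cmi <- function(trial_perm) {
    yp <- by[trial_perm, t_past, drop = FALSE]
    ok <- base_ok & !is.na(yp)
    fast_cmi(xt[ok], yp[ok], cp[ok], n_bins, n_bins, n_bins,
             correction = correction)
  }
  value <- eval_cmi(seq_len(n_tr))
  n_used <- sum(base_ok & !is.na(by[, t_past, drop = FALSE]))
  obs <- info_estimate(value, correction = correction, n = n_used)
  n_cells <- n_bins^3
  obs$low_confidence <- obs$n < min_cell_mean * n_cells
  if (n_boot > 0) {
    if (n_tr < 2) stop("bootstrap null requires at least 2 trials")
    if (!is.null(seed)) set.seed(seed)
    null_vals <- vapply(seq_len(n_boot),
                        function(b) eval_cmi(derangement(n_tr)),
                        numeric(1))
    obs$null_mean <- mean(null_vals)
    obs$null_sd <- stats::sd(null_vals)
    obs$z <- if (obs$null_sd > 0) {
      (obs$value - obs$null_mean) / obs$null_sd
    } else NA_real_
  }
  obs
}

#' Transfer entropy from a source series to a target series
#'
#' Estimates `T(Y -> X) = I(X_t; Y_past | X_past)` on equipopulated-binned,
#' subsampled series, with embeddings of dimension one per past, a
#' configurable lag, and a limited-sampling bias correction.  Embeddings
#' never span trial boundaries; masked (`NA`) samples are dropped listwise.
#' With `n_boot > 0` the estimate is Z-scored against a common-stimulus
#' bootstrap null in which the source series of trial `m` is paired with the
#' target series of a different trial (random derangement), preserving
#' stimulus-locked structure while destroying within-trial interaction.
#'
#' @param x target (receiving) series, `trials x time` matrix; typically a
#'   firing-rate envelope.
#' @param y source (sending) series, same shape; typically a band phase.
#' @param fs_hz sampling rate of the series.
#' @param lag_ms embedding lag in ms (default 10).
#' @param step_ms evaluation step (subsampling) in ms (default 2).
#' @param n_bins equipopulated bins per variable (default 3).
#' @param correction bias correction, see [mutual_information()].
#' @param n_boot bootstrap resamples for the null (0 = no null).
#' @param strata optional `trials x time` integer matrix; embeddings are
#'   only evaluated where present and past sample share the same non-`NA`
#'   stratum (used for block-restricted estimates).
#' @param seed seed for the bootstrap derangements.
#' @return `info_estimate` with `value` (bits) and, if `n_boot > 0`, the
#'   null mean/SD and `z`.
#' @export
transfer_entropy <- function(x, y, fs_hz, lag_ms = 10, step_ms = 2,
                             n_bins = 3,
                             correction = c("panzeri-treves", "shuffle",
                                            "none"),
                             n_boot = 0, strata = NULL, seed = NULL) {
  correction <- match.arg(correction)
  directed_info_core(x, y, cond = NULL, fs_hz, lag_ms, step_ms, n_bins,
                     correction, n_boot, strata, seed)
}

#' Lagged conditional information (LCI and localized LCI)
#'
#' Same estimator core as [transfer_entropy()] but with a swapped
#' conditioner: `I(X_t; Y_past | Z_past)` where `Z` is the sender's past
#' firing rate (LCI) or the receiver's past phase (localized LCI), instead
#' of the receiver's past rate.
#'
#' @inheritParams transfer_entropy
#' @param cond conditioning series `Z`, `trials x time` matrix.
#' @return `info_estimate`.
#' @export
lagged_conditional_information <- function(x, y, cond, fs_hz, lag_ms = 10,
                                           step_ms = 2, n_bins = 3,
                                           correction = c("panzeri-treves",
                                                          "shuffle", "none"),
                                           n_boot = 0, strata = NULL,
                                           seed = NULL) {
  correction <- match.arg(correction)
  directed_info_core(x, y, cond = cond, fs_hz, lag_ms, step_ms, n_bins,
                     correction, n_boot, strata, seed)
}

#' Sensory information: mutual information between scene identity and a
#' neural response
#'
#' Reduces each (trial, scene) to one response value — the scene average for
#' slow variables, the circular mean for wrapped angle series, or the value
#' at the scene centre for fast variables such as single-site phases — then
#' bins the pooled values into equipopulated bins and computes the
#' bias-corrected mutual information with the scene label.  With
#' `n_boot > 0`, significance is assessed against a surrogate null built by
#' circularly rotating each trial's scene sequence by a random offset
#' (`null = "rotate"`, which preserves the within-trial autocorrelation of
#' the response and so calibrates correctly for slowly varying signals) or
#' by permuting scene labels independently within each trial
#' (`null = "permute"`); the estimate is Z-scored against that null.
#'
#' @param response `trials x time` numeric matrix (rate, power, phase or
#'   phase-shift series; `NA` allowed).
#' @param scene integer scene label per sample (length = `ncol(response)`).
#' @param type `"slow"` (scene mean), `"circular"` (scene circular mean) or
#'   `"point"` (scene-centre sample, for fast wrapped phases).
#' @param n_bins equipopulated response bins (default 4).
#' @param correction see [mutual_information()].
#' @param n_boot permutations for the null (0 = none).
#' @param seed seed for the permutations.
#' @return `info_estimate` (bits; plus `z` when `n_boot > 0`).
#' @export
sensory_information <- function(response, scene,
                                type = c("slow", "circular", "point"),
                                n_bins = 4,
                                correction = c("panzeri-treves", "shuffle",
                                               "none"),
                                n_boot = 0, null = c("rotate", "permute"),
                                seed = NULL) {
  type <- match.arg(type)
  null <- match.arg(null)
  correction <- match.arg(correction)
  response <- as.matrix(response)
  if (nrow(response) < 2) stop("need at least 2 trials")
  stopifnot(length(scene) == ncol(response))
  scenes <- sort(unique(scene))
  if (length(scenes) < 2) stop("need at least 2 scenes")
  per <- function(v, idx) {
    vv <- v[idx]
    switch(type,
           slow = mean(vv, na.rm = TRUE),
           circular = circular_stats(vv)$mean,
           point = vv[ceiling(length(vv) / 2)])
  }
  vals <- sapply(scenes, function(s) {
    idx <- which(scene == s)
    apply(response, 1, per, idx = idx)
  })                                       # trials x scenes
  labs <- matrix(rep(seq_along(scenes), each = nrow(vals)), nrow = nrow(vals))
  mi_of <- function(valmat) {
    b <- tryCatch(equipopulated_bin(as.numeric(valmat), n_bins),
                  error = function(e) NULL)
    if (is.null(b)) return(0)              # constant response guard
    mutual_information(b, as.integer(labs), correction = correction)$value
  }
  value <- mi_of(vals)
  est <- info_estimate(value, correction = correction, n = length(vals))
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    ns <- ncol(vals)
    nulls <- vapply(seq_len(n_boot), function(b) {
      shuf <- if (null == "rotate") {
        t(apply(vals, 1, function(v) {
          k <- sample.int(ns - 1, 1)
          v[c((k + 1):ns, 1:k)]
        }))
      } else {
        t(apply(vals, 1, sample))
      }
      mi_of(shuf)
    }, numeric(1))
    est$null_mean <- mean(nulls)
    est$null_sd <- stats::sd(nulls)
    est$z <- if (est$null_sd > 0) (value - est$null_mean) / est$null_sd else
      NA_real_
  }
  est
}

#' Scene labels of one oscillation period for phase variables
#'
#' Fast wrapped phases are evaluated against finer scene divisions than slow
#' variables: each scene lasts one oscillation period of the analysis band
#' carrier, and the phase is read at the scene centre.
#'
#' @param n_t number of samples.
#' @param fs_hz sampling rate.
#' @param f_hz oscillation frequency (scene length = one period).
#' @return integer scene label per sample.
#' @export
period_scenes <- function(n_t, fs_hz, f_hz) {
  len <- fs_hz / f_hz
  lab <- floor((seq_len(n_t) - 1) / len) + 1
  as.integer(lab)
}
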