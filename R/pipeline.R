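#' Directed transfer-entropy table for electrode pairs of a session
#'
#' Computes bootstrap-nulled transfer entropy from source band phase to
#' target firing rate for every ordered electrode pair (or a supplied
#' subset), returning a tidy table.
#'
#' @param session a [recording_session].
#' @param phase optional `trials x elec x time` phase array; defaults to the
#'   gamma analytic phase extracted from the session's field signal via
#'   [analytic_series()] (falling back to the planted phase only if the
#'   session carries no field signal).
#' @param pairs optional data frame with columns `sender`, `receiver`;
#'   default all ordered pairs.
#' @param n_boot bootstrap resamples for the common-stimulus null.
#' @param lag_ms,step_ms,n_bins,correction see [transfer_entropy()].
#' @param seed seed; each pair gets a derived sub-seed.
#' @return data frame with one row per ordered pair: `sender`, `receiver`,
#'   `te_bits`, `z`, `null_mean`, `null_sd`, `n`, `low_confidence`.
#' @export
session_te_table <- function(session, phase = NULL, pairs = NULL,
                             n_boot = 40, lag_ms = 10, step_ms = 2,
                             n_bins = 3, correction = "panzeri-treves",
                             seed = 1) {
  stopifnot(inherits(session, "recording_session"))
  if (is.null(phase)) {
    phase <- if (!is.null(session$lfp)) {
      analytic_series(session)$phase
    } else {
      session$phase
    }
  }
  n_elec <- dim(session$rate)[2]
  if (is.null(pairs)) {
    pairs <- expand.grid(sender = seq_len(n_elec), receiver = seq_len(n_elec))
    pairs <- pairs[pairs$sender != pairs$receiver, ]
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- pairs$sender[i]; r <- pairs$receiver[i]
    est <- transfer_entropy(session$rate[, r, , drop = TRUE],
                            phase[, s, , drop = TRUE],
                            fs_hz = session$fs_hz, lag_ms = lag_ms,
                            step_ms = step_ms, n_bins = n_bins,
                            correction = correction, n_boot = n_boot,
                            seed = split_seed(seed, i))
    data.frame(sender = s, receiver = r, te_bits = est$value,
               z = est$z, null_mean = est$null_mean, null_sd = est$null_sd,
               n = est$n, low_confidence = est$low_confidence)
  })
  do.call(rbind, rows)
}

#' Unordered pair table from a directed TE table
#'
#' Folds an ordered-pair TE table into one row per unordered pair with the
#' Z-scored TE in both directions, ready for [classify_pairs()].
#'
#' @param te_table output of [session_te_table()].
#' @return data frame with columns `a`, `b`, `te_ab`, `te_ba`.
#' @export
fold_te_table <- function(te_table) {
  key <- paste(pmin(te_table$sender, te_table$receiver),
               pmax(te_table$sender, te_table$receiver))
  out <- lapply(split(te_table, key), function(d) {
    a <- min(d$sender[1], d$receiver[1]); b <- max(d$sender[1], d$receiver[1])
    data.frame(a = a, b = b,
               te_ab = d$z[d$sender == a & d$receiver == b][1],
               te_ba = d$z[d$sender == b & d$receiver == a][1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Phase-shift table for ordered electrode pairs
#'
#' Movie-averaged circular mean shift, PLV and Rayleigh nonuniformity
#' p-value per ordered pair.
#'
#' @param phase `trials x elec x time` phase array.
#' @param pairs optional ordered-pair data frame (`sender`, `receiver`).
#' @param rayleigh_max_n angles are subsampled to at most this many before
#'   the Rayleigh test (the test is otherwise degenerate at huge n).
#' @return data frame: `sender`, `receiver`, `mean_shift`, `plv`,
#'   `rayleigh_p`.
#' @export
session_shift_table <- function(phase, pairs = NULL, rayleigh_max_n = 5000) {
  n_elec <- dim(phase)[2]
  if (is.null(pairs)) {
    pairs <- expand.grid(sender = seq_len(n_elec), receiver = seq_len(n_elec))
    pairs <- pairs[pairs$sender != pairs$receiver, ]
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- pairs$sender[i]; r <- pairs$receiver[i]
    sh <- phase_shift(phase[, s, , drop = TRUE], phase[, r, , drop = TRUE])
    cs <- circular_stats(as.numeric(sh))
    ang <- as.numeric(sh); ang <- ang[!is.na(ang)]
    if (length(ang) > rayleigh_max_n) {
      ang <- ang[round(seq(1, length(ang), length.out = rayleigh_max_n))]
    }
    rp <- if (length(ang) >= 10) rayleigh_test(ang)$p.value else NA_real_
    data.frame(sender = s, receiver = r, mean_shift = cs$mean, plv = cs$plv,
               rayleigh_p = rp)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on a (synthetic or loaded) session
#'
#' Sequences the analysis stages: band phase extraction, spatial coherence,
#' directed TE with the common-stimulus bootstrap null for all ordered
#' pairs, pair classification, phase-shift statistics and the shift-TE
#' Spearman correlation, travelling-wave speed estimation along strongly
#' asymmetric pairs, block-conditioned TE, and sensory information of phase
#' shifts versus single-site phase.  Deterministic given (config, seed).
#'
#' @param config a [synth_config()]; or pass a ready `session`.
#' @param session optional [recording_session] (overrides `config`).
#' @param n_boot bootstrap resamples for TE nulls.
#' @param band analysis band in Hz (default gamma 50-80).
#' @param sensory_pair ordered pair (sender, receiver) for the sensory
#'   information stage; default the first coupling edge or (1, 2).
#' @param max_block_pairs cap on strongly asymmetric pairs sent through the
#'   block-conditioned stage.
#' @param seed master analysis seed.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = NULL, session = NULL, n_boot = 40,
                         band = c(50, 80), sensory_pair = NULL,
                         max_block_pairs = 4, seed = 1) {
  if (is.null(session)) {
    stopifnot(inherits(config, "synth_config"))
    session <- generate_session(config)
  }
  fs <- session$fs_hz
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      warning("stage ", name, " failed: ", conditionMessage(e))
      NULL
    })
    log[[name]] <<- round(proc.time()[3] - t0, 2)
    out
  }
  an <- stage("preprocess", analytic_series(session, band[1], band[2]))
  coh <- stage("coherence", spatial_coherence(session))
  te <- stage("infotheory", session_te_table(session, phase = an$phase,
                                             n_boot = n_boot, seed = seed))
  pairs_cls <- if (!is.null(te)) {
    stage("classify", classify_pairs(fold_te_table(te)))
  } else NULL
  shifts <- stage("shifts", session_shift_table(an$phase))
  spearman <- NULL
  if (!is.null(te) && !is.null(shifts)) {
    spearman <- stage("shift_te_correlation", {
      m <- merge(te, shifts, by = c("sender", "receiver"))
      correlate_shift_causation(m$mean_shift, m$z)
    })
  }
  wave <- NULL
  if (is.null(session$positions)) {
    warning("no electrode positions: wave stage skipped")
  } else if (!is.null(pairs_cls)) {
    asym <- pairs_cls[!is.na(pairs_cls$category) &
                        pairs_cls$category == "strongly_asymmetric", ,
                      drop = FALSE]
    if (nrow(asym) > 0) {
      refs <- data.frame(
        sender = ifelse(asym$leading == "ab", asym$a, asym$b),
        receiver = ifelse(asym$leading == "ab", asym$b, asym$a))
      wave <- stage("waves", {
        prof <- wave_profile(an$phase, session$positions, refs)
        sp <- wave_speed(prof, f_hz = mean(band), n_boot = 100,
                         seed = split_seed(seed, 7L))
        list(profile = prof, speed = sp, ref_pairs = refs)
      })
    }
  }
  blocks <- NULL
  if (!is.null(wave) && nrow(wave$ref_pairs) > 0) {
    blocks <- stage("blocks", {
      refs <- utils::head(wave$ref_pairs, max_block_pairs)
      lapply(seq_len(nrow(refs)), function(i) {
        s <- refs$sender[i]; r <- refs$receiver[i]
        sh <- phase_shift(an$phase[, s, , drop = TRUE],
                          an$phase[, r, , drop = TRUE])
        seg <- segment_blocks(sh, fs)
        bt <- block_conditioned_te(session$rate[, r, , drop = TRUE],
                                   an$phase[, s, , drop = TRUE],
                                   seg, fs_hz = fs, n_boot = n_boot,
                                   seed = split_seed(seed, 100L + i))
        list(sender = s, receiver = r, segmentation = seg, te = bt)
      })
    })
  }
  sensory <- stage("sensory", {
    sp <- sensory_pair %||% {
      e <- session$ground_truth$coupling_edges
      if (!is.null(e) && nrow(e) > 0) c(e$sender[1], e$receiver[1]) else
        c(1L, 2L)
    }
    sh <- phase_shift(an$phase[, sp[1], , drop = TRUE],
                      an$phase[, sp[2], , drop = TRUE])
    list(
      pair = sp,
      shift = sensory_information(sh, session$scene, type = "circular",
                                  n_boot = n_boot,
                                  seed = split_seed(seed, 8L)),
      single_phase = sensory_information(an$phase[, sp[1], , drop = TRUE],
                                         session$scene, type = "point",
                                         n_boot = n_boot,
                                         seed = split_seed(seed, 9L)))
  })
  structure(list(session = session, analytic = an, coherence = coh,
                 te_table = te, pairs = pairs_cls, shift_table = shifts,
                 shift_te_spearman = spearman, wave = wave, blocks = blocks,
                 sensory = sensory, stage_seconds = log, seed = seed),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  if (!is.null(x$te_table)) {
    cat(sprintf("  TE: %d ordered pairs, mean Z = %.2f\n",
                nrow(x$te_table), mean(x$te_table$z, na.rm = TRUE)))
  }
  if (!is.null(x$pairs)) {
    tb <- table(x$pairs$category)
    cat("  pair categories:",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$shift_te_spearman)) {
    cat(sprintf("  shift-TE Spearman rho = %.3f (p = %.3g)\n",
                x$shift_te_spearman$rho, x$shift_te_spearman$p.value))
  }
  if (!is.null(x$wave) && !x$wave$speed$infinite) {
    cat(sprintf("  wave speed = %.3f m/s (slope %.3f rad/mm)\n",
                x$wave$speed$speed_m_per_s, x$wave$speed$slope_rad_per_mm))
  }
  if (!is.null(x$sensory)) {
    cat(sprintf("  sensory info: shift %.4f bits (Z=%.1f), phase %.4f bits (Z=%.1f)\n",
                x$sensory$shift$value, x$sensory$shift$z,
                x$sensory$single_phase$value, x$sensory$single_phase$z))
  }
  cat("  stage seconds:",
      paste(names(x$stage_seconds), unlist(x$stage_seconds), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
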