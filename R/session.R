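#' Recording-session container
#'
#' Holds multi-trial, multi-electrode arrays (band signal, firing-rate
#' envelope, optionally a planted/extracted phase field), electrode grid
#' positions in mm, the sampling rate, per-sample scene labels and
#' provenance.  All arrays are `n_trials x n_elec x n_t`.
#'
#' @param lfp band-limited field signal array.
#' @param rate nonnegative firing-rate envelope array (same shape).
#' @param phase optional phase array in radians, same shape.
#' @param positions `n_elec x 2` matrix of electrode positions (mm).
#' @param fs_hz sampling rate (Hz).
#' @param scene integer scene label per sample (length `n_t`).
#' @param scene_len_ms scene duration in ms.
#' @param config optional generating configuration (provenance).
#' @param ground_truth optional ground-truth record (synthetic sessions).
#' @return object of class `recording_session`.
#' @export
recording_session <- function(lfp, rate, phase = NULL, positions, fs_hz,
                              scene, scene_len_ms = NULL, config = NULL,
                              ground_truth = NULL) {
  stopifnot(length(dim(lfp)) == 3, identical(dim(lfp), dim(rate)))
  if (!is.null(phase)) stopifnot(identical(dim(phase), dim(lfp)))
  n_elec <- dim(lfp)[2]
  positions <- as.matrix(positions)
  if (nrow(positions) != n_elec || ncol(positions) != 2) {
    stop("positions must be an n_elec x 2 matrix")
  }
  if (anyDuplicated(positions)) stop("electrode positions must be unique")
  if (length(scene) != dim(lfp)[3]) {
    stop("scene labels must cover every sample")
  }
  if (any(rate < 0, na.rm = TRUE)) stop("rate envelopes must be nonnegative")
  structure(list(
    lfp = lfp, rate = rate, phase = phase, positions = positions,
    fs_hz = fs_hz, scene = as.integer(scene), scene_len_ms = scene_len_ms,
    config = config, ground_truth = ground_truth
  ), class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  d <- dim(x$lfp)
  cat("recording_session:", d[1], "trials x", d[2], "electrodes x", d[3],
      "samples @", x$fs_hz, "Hz\n")
  cat("  scenes:", length(unique(x$scene)),
      if (!is.null(x$scene_len_ms)) paste0("(", x$scene_len_ms, " ms each)"),
      "\n")
  cat("  planted phase field:", if (is.null(x$phase)) "no" else "yes", "\n")
  if (!is.null(x$ground_truth)) {
    ne <- nrow(x$ground_truth$coupling_edges %||% data.frame())
    cat("  ground truth: yes (", ne, "coupling edges )\n")
  }
  invisible(x)
}

SESSION_SCHEMA_VERSION <- "1"

write_num_text <- function(x, path) {
  writeLines(sprintf("%.17g", as.numeric(x)), path)
}

read_num_text <- function(path) {
  as.numeric(readLines(path))
}

#' Write / read a session as a plain-text directory container
#'
#' The container is a directory holding a JSON metadata file (shapes, units,
#' schema version, provenance) and one text file per array with one
#' `%.17g`-formatted value per line, which round-trips doubles exactly.
#'
#' @param session a [recording_session].
#' @param path directory to create (must not already contain a session).
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   the reconstructed [recording_session].
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    dims = dim(session$lfp),
    fs_hz = session$fs_hz,
    scene = session$scene,
    scene_len_ms = session$scene_len_ms,
    units = list(phase = "radians", positions = "mm", time = "ms"),
    has_phase = !is.null(session$phase),
    seed = session$config$seed %||% NA
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_num_text(session$lfp, file.path(path, "lfp.txt"))
  write_num_text(session$rate, file.path(path, "rate.txt"))
  if (!is.null(session$phase)) {
    write_num_text(session$phase, file.path(path, "phase.txt"))
  }
  write_num_text(session$positions, file.path(path, "positions.txt"))
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not a session container (missing meta.json): ", path)
  }
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e) stop("corrupt session metadata: ",
                                            conditionMessage(e)))
  if (!identical(as.character(meta$schema_version), SESSION_SCHEMA_VERSION)) {
    stop("unsupported session schema version: ", meta$schema_version)
  }
  dims <- as.integer(meta$dims)
  expect_len <- prod(dims)
  grab <- function(name) {
    f <- file.path(path, name)
    if (!file.exists(f)) stop("session container missing ", name)
    v <- read_num_text(f)
    if (length(v) != expect_len) {
      stop("truncated or corrupt array ", name, ": expected ", expect_len,
           " values, found ", length(v))
    }
    array(v, dim = dims)
  }
  lfp <- grab("lfp.txt")
  rate <- grab("rate.txt")
  phase <- if (isTRUE(meta$has_phase)) grab("phase.txt") else NULL
  pos <- matrix(read_num_text(file.path(path, "positions.txt")),
                nrow = dims[2], ncol = 2)
  recording_session(lfp = lfp, rate = rate, phase = phase, positions = pos,
                    fs_hz = meta$fs_hz, scene = meta$scene,
                    scene_len_ms = meta$scene_len_ms)
}
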