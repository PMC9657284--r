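# Trial bundles on disk: delimited text tables plus a JSON manifest.
#
# Layout of a bundle directory:
#   manifest.json   template fields, seed, fs_hz, schema version
#   events.csv      limb, on_s, off_s
#   accel.csv       time_s, head_mps2, withers_mps2, pelvis_mps2
#   disp.csv        time_s, head_mm, withers_mm, pelvis_mm (measured)
#   truth_disp.csv  same columns, noise-free ground truth
#   limb_signals.csv, truth_extrema.csv
# All CSV, UTF-8, "." decimal separator, times in seconds.

BUNDLE_SCHEMA_VERSION <- 1L

#' Write a trial bundle to a directory
#'
#' @param trial a `gait_trial`.
#' @param path directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tpl <- trial$template
  manifest <- list(schema_version = BUNDLE_SCHEMA_VERSION,
                   gait = tpl$gait, condition = tpl$condition,
                   fs_hz = tpl$fs_hz, seed = tpl$seed,
                   template = unclass(tpl))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(path, f), row.names = FALSE)
  wr(trial$events, "events.csv")
  wr(trial$accel, "accel.csv")
  wr(trial$disp, "disp.csv")
  wr(trial$truth_disp, "truth_disp.csv")
  wr(trial$limb_signals, "limb_signals.csv")
  wr(trial$truth_extrema, "truth_extrema.csv")
  utils::write.csv(data.frame(start_s = trial$stride_starts_s),
                   file.path(path, "stride_starts.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a trial bundle from a directory
#'
#' Validates the manifest schema version, the presence of the sampling
#' rate, event-table structure (known limbs, positive stance durations,
#' strictly increasing contact times per limb) and trace consistency,
#' producing diagnostics that name the offending file and row.
#'
#' @param path bundle directory written by [write_trial()], or containing
#'   user-supplied tables in the same schema (`truth_*` files optional).
#' @return a `gait_trial`.
#' @export
read_trial <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("%s: manifest.json not found", path), call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(manifest$schema_version) || manifest$schema_version != BUNDLE_SCHEMA_VERSION) {
    stop(sprintf("manifest.json: schema version %s not supported (expected %d)",
                 manifest$schema_version %||% "<missing>", BUNDLE_SCHEMA_VERSION),
         call. = FALSE)
  }
  if (is.null(manifest$fs_hz)) stop("manifest.json: sampling rate required (fs_hz)", call. = FALSE)

  rd <- function(f, required = TRUE) {
    p <- file.path(path, f)
    if (!file.exists(p)) {
      if (required) stop(sprintf("%s: file missing", f), call. = FALSE)
      return(NULL)
    }
    tibble::as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
  }
  events <- rd("events.csv")
  if (!all(c("limb", "on_s", "off_s") %in% names(events))) {
    stop("events.csv: columns limb, on_s, off_s required", call. = FALSE)
  }
  bad_limb <- which(!events$limb %in% c("LH", "RH", "LF", "RF"))
  if (length(bad_limb) > 0) {
    stop(sprintf("events.csv row %d: unknown limb '%s'", bad_limb[1], events$limb[bad_limb[1]]),
         call. = FALSE)
  }
  bad <- which(events$off_s <= events$on_s)
  if (length(bad) > 0) {
    stop(sprintf("events.csv row %d: %s hoof-off (%.4f s) not after hoof-on (%.4f s)",
                 bad[1], events$limb[bad[1]], events$off_s[bad[1]], events$on_s[bad[1]]),
         call. = FALSE)
  }
  for (limb in unique(events$limb)) {
    on <- events$on_s[events$limb == limb]
    if (is.unsorted(on, strictly = TRUE)) {
      stop(sprintf("events.csv: %s contact times not strictly increasing", limb), call. = FALSE)
    }
    off <- events$off_s[events$limb == limb]
    if (any(utils::head(off, -1) > utils::tail(on, -1))) {
      stop(sprintf("events.csv: %s stances overlap (hoof-off after the next hoof-on)", limb),
           call. = FALSE)
    }
  }
  accel <- rd("accel.csv")
  if (is.unsorted(accel$time_s, strictly = TRUE)) {
    stop("accel.csv: time_s must be strictly increasing", call. = FALSE)
  }
  disp <- rd("disp.csv", required = FALSE)
  truth_disp <- rd("truth_disp.csv", required = FALSE)
  limb_signals <- rd("limb_signals.csv", required = FALSE)
  truth_extrema <- rd("truth_extrema.csv", required = FALSE)
  starts <- rd("stride_starts.csv", required = FALSE)

  tpl <- manifest$template
  template <- NULL
  if (!is.null(tpl)) {
    tpl$romz_mm <- unlist(tpl$romz_mm)
    tpl$asymmetry_mm <- unlist(tpl$asymmetry_mm)
    tpl$extremum_phase <- lapply(tpl$extremum_phase, unlist)
    template <- structure(tpl, class = "gait_template")
  } else {
    template <- structure(list(gait = manifest$gait %||% NA_character_,
                               condition = manifest$condition %||% NA_character_,
                               fs_hz = manifest$fs_hz),
                          class = "gait_template")
  }
  structure(list(template = template, events = events, accel = accel,
                 truth_disp = truth_disp %||% disp, disp = disp %||% truth_disp,
                 limb_signals = limb_signals, truth_extrema = truth_extrema,
                 stride_starts_s = if (!is.null(starts)) starts$start_s else NULL),
            class = "gait_trial")
}
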