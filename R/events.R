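# Hoof event handling: surrogate detector and stride pairing.

#' Detect hoof-on/off events from a distal limb signal
#'
#' Surrogate detector for stylized metapodial signals: stance is declared
#' wherever the absolute signal stays below a configurable fraction of the
#' per-limb robust amplitude for at least a minimum dwell time. The
#' proprietary accelerometer/gyroscope detectors used with real sensor data
#' are out of scope; for simulated trials the ground-truth pass-through
#' ([trial_events()] with `mode = "truth"`) is the default analysis path and
#' this detector is the documented alternative.
#'
#' Stance runs touching the first or last sample are discarded: their onset
#' or lift-off lies outside the recording and cannot be timed.
#'
#' @param signal numeric vector, uniformly sampled at `fs_hz`, starting at
#'   time 0.
#' @param fs_hz sampling rate (samples/s).
#' @param limb limb label to attach to the returned events.
#' @param frac stance threshold as a fraction of the robust (95th
#'   percentile) absolute amplitude.
#' @param dwell_s minimum stance dwell in seconds.
#' @return tibble with columns `limb`, `on_s`, `off_s`, one row per stance.
#' @export
detect_events <- function(signal, fs_hz, limb = "LH", frac = 0.05, dwell_s = 0.04) {
  stopifnot(is.numeric(signal), length(signal) > 1, fs_hz > 0)
  amp <- stats::quantile(abs(signal), 0.95, names = FALSE)
  if (!is.finite(amp) || amp < 1e-9) {
    stop(sprintf("no events detected for %s: signal has no swing-phase activity", limb),
         call. = FALSE)
  }
  below <- abs(signal) <= frac * amp
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= max(1L, round(dwell_s * fs_hz)) &
    starts > 1 & ends < length(signal)
  if (sum(keep) == 0) {
    stop(sprintf("no events detected for %s: no stance run of at least %.0f ms", limb,
                 1000 * dwell_s), call. = FALSE)
  }
  if (sum(keep) < 2) {
    stop(sprintf("fewer than 2 stance phases detected for %s; limb excluded", limb),
         call. = FALSE)
  }
  tibble::tibble(limb = limb,
                 on_s = (starts[keep] - 1) / fs_hz,
                 off_s = ends[keep] / fs_hz)
}

#' Hoof events for a simulated trial
#'
#' @param trial a `gait_trial`.
#' @param mode `"truth"` returns the simulator's emitted event times;
#'   `"detect"` runs [detect_events()] on the stylized limb signals.
#' @param ... passed to [detect_events()] in detect mode.
#' @return tibble with columns `limb`, `on_s`, `off_s`.
#' @export
trial_events <- function(trial, mode = c("truth", "detect"), ...) {
  stopifnot(inherits(trial, "gait_trial"))
  mode <- match.arg(mode)
  if (mode == "truth") return(trial$events)
  fs <- trial$template$fs_hz
  dplyr::bind_rows(lapply(c("LH", "RH", "LF", "RF"), function(limb) {
    detect_events(trial$limb_signals[[limb]], fs, limb = limb, ...)
  }))
}

#' Pair events into stride windows
#'
#' A stride is the half-open interval between consecutive left-hind hoof
#' contacts. Each window is marked complete when all four limbs have a
#' contact inside it; incomplete windows are kept in the table (flagged)
#' but skipped by all downstream per-stride computations.
#'
#' @param events tibble with columns `limb`, `on_s`, `off_s`.
#' @return tibble with columns `stride_index`, `start_s`, `end_s`,
#'   `complete`, plus per-limb contact counts `n_LH` ... `n_RF`. Incomplete
#'   windows are reported via a message.
#' @export
pair_strides <- function(events) {
  stopifnot(all(c("limb", "on_s", "off_s") %in% names(events)))
  lh <- sort(events$on_s[events$limb == "LH"])
  if (length(lh) < 2) {
    stop("need at least 2 left-hind contacts to define a stride", call. = FALSE)
  }
  win <- tibble::tibble(stride_index = seq_len(length(lh) - 1),
                        start_s = lh[-length(lh)],
                        end_s = lh[-1])
  for (limb in c("LH", "RH", "LF", "RF")) {
    on <- events$on_s[events$limb == limb]
    win[[paste0("n_", limb)]] <- vapply(seq_len(nrow(win)), function(i)
      sum(on >= win$start_s[i] & on < win$end_s[i]), integer(1))
  }
  win$complete <- win$n_LH >= 1 & win$n_RH >= 1 & win$n_LF >= 1 & win$n_RF >= 1
  if (any(!win$complete)) {
    message(sprintf("dropping %d stride window(s) with missing limb events: %s",
                    sum(!win$complete),
                    paste(win$stride_index[!win$complete], collapse = ", ")))
  }
  win
}

# The contact (on/off) of `limb` assigned to a window: the first contact
# with on in [start, end). Complete windows are guaranteed one.
window_contact <- function(events, limb, start_s, end_s) {
  e <- events[events$limb == limb & events$on_s >= start_s & events$on_s < end_s, ]
  e[which.min(e$on_s), ]
}

#' Intervals between successive hoof placements
#'
#' Pools the contacts of all four limbs inside each complete stride window
#' and returns the intervals between successive placements as percent of
#' that stride's duration. In an ideally regular four-beat gait (walk,
#' toelt) every interval is 25 %StrD.
#'
#' @param events tibble with columns `limb`, `on_s`.
#' @param windows output of [pair_strides()].
#' @return numeric vector of intervals (%StrD), pooled over strides.
#' @export
contact_intervals <- function(events, windows) {
  windows <- windows[windows$complete, ]
  out <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    on <- sort(events$on_s[events$on_s >= w$start_s & events$on_s < w$end_s])
    # close the cycle with the next window's first contact (= window end)
    diff(c(on, w$end_s)) / (w$end_s - w$start_s) * 100
  })
  unlist(out)
}
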