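# Acceleration -> displacement, stride segmentation, time normalization.

#' Double-integrate vertical acceleration to displacement
#'
#' Cumulative trapezoidal integration performed independently within each
#' stride window, with drift correction anchored on the stride: after the
#' first pass the per-stride mean of the velocity is removed (this removes
#' exactly the linear drift that the unknown integration constant would put
#' into the displacement), and after the second pass the per-stride mean of
#' the displacement is removed. Over a full stride the true mean vertical
#' velocity of a cyclic gait is zero, so the correction does not distort the
#' waveform.
#'
#' @param accel tibble with `time_s` and one `<segment>_mps2` column per
#'   axial segment (m/s^2), uniformly sampled.
#' @param windows stride windows from [pair_strides()]; only complete
#'   windows are integrated. Windows with fewer than 4 samples, or
#'   extending past the end of the trace, are dropped with a message.
#' @return tibble with `time_s` and `<segment>_mm` columns; samples outside
#'   any integrated window are `NA`.
#' @export
integrate_displacement <- function(accel, windows) {
  stopifnot("time_s" %in% names(accel))
  acols <- grep("_mps2$", names(accel), value = TRUE)
  if (length(acols) == 0) stop("no acceleration columns (*_mps2) found", call. = FALSE)
  tt <- accel$time_s
  windows <- windows[windows$complete, , drop = FALSE]
  out <- tibble::tibble(time_s = tt)
  for (ac in acols) {
    out[[sub("_mps2$", "_mm", ac)]] <- NA_real_
  }
  h <- tt[2] - tt[1]
  for (i in seq_len(nrow(windows))) {
    # one-sample margin on both sides: boundary samples must not drop out
    # to floating-point jitter, and the endpoint interpolation below needs
    # support at both window edges
    idx <- which(tt >= windows$start_s[i] - 1.5 * h & tt <= windows$end_s[i] + 1.5 * h)
    if (length(idx) < 4) {
      message(sprintf("stride window %d has fewer than 4 samples; dropped",
                      windows$stride_index[i]))
      next
    }
    if (max(tt[idx]) < windows$end_s[i]) {
      message(sprintf("stride window %d extends past the end of the trace; dropped",
                      windows$stride_index[i]))
      next
    }
    dur <- windows$end_s[i] - windows$start_s[i]
    tw <- tt[idx]
    in_period <- tw >= windows$start_s[i] - 0.5 * h & tw < windows$end_s[i] - 0.5 * h
    for (ac in acols) {
      a_mm <- accel[[ac]][idx] * 1000
      v <- as.numeric(pracma::cumtrapz(tw, a_mm))
      v <- v - mean(v[in_period])
      z <- as.numeric(pracma::cumtrapz(tw, v))
      # over one stride of a cyclic gait the displacement returns to its
      # starting value; any difference is residual linear drift from the
      # unknown initial velocity, removed by anchoring the endpoints
      z_ends <- stats::approx(tw, z, xout = c(windows$start_s[i], windows$end_s[i]),
                              rule = 2)$y
      z <- z - (z_ends[2] - z_ends[1]) / dur * (tw - windows$start_s[i])
      z <- z - mean(z[in_period])
      out[[sub("_mps2$", "_mm", ac)]][idx] <- z
    }
  }
  out
}

#' Segment displacement into time-normalized strides
#'
#' Resamples each complete stride window to a fixed grid of `n_points`
#' phases from 0 to 100 % of stride (inclusive) by piecewise-cubic
#' interpolation, and removes the per-stride mean, so that horses with
#' different stride durations are directly comparable. Stance boundaries
#' are re-expressed in normalized units and attached as the `stance_pct`
#' attribute.
#'
#' @param disp tibble with `time_s` and `<segment>_mm` columns.
#' @param windows stride windows from [pair_strides()].
#' @param events event tibble (for the stance metadata); optional.
#' @param n_points number of grid points (default 101: integer percent).
#' @return long tibble `stride_index`, `segment`, `phase_pct`, `disp_mm`
#'   with attribute `stance_pct` (tibble: stride_index, limb, on_pct,
#'   off_pct) when `events` is supplied. Windows not fully covered by
#'   non-missing displacement are dropped with a message.
#' @export
segment_and_normalize <- function(disp, windows, events = NULL, n_points = 101) {
  stopifnot(n_points >= 2)
  dcols <- grep("_mm$", names(disp), value = TRUE)
  tt <- disp$time_s
  windows <- windows[windows$complete, , drop = FALSE]
  grid <- seq(0, 100, length.out = n_points)
  rows <- list()
  stance_rows <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    dur <- w$end_s - w$start_s
    xout <- w$start_s + grid / 100 * dur
    idx <- which(tt >= w$start_s - 2 * (tt[2] - tt[1]) & tt <= w$end_s + 2 * (tt[2] - tt[1]))
    ok <- TRUE
    for (dc in dcols) {
      y <- disp[[dc]][idx]
      keep <- !is.na(y)
      if (sum(keep) < 4 || max(tt[idx][keep]) < w$end_s || min(tt[idx][keep]) > w$start_s) {
        ok <- FALSE
        break
      }
      z <- stats::spline(tt[idx][keep], y[keep], xout = xout, method = "fmm")$y
      rows[[length(rows) + 1]] <- tibble::tibble(
        stride_index = w$stride_index,
        segment = sub("_mm$", "", dc),
        phase_pct = grid,
        disp_mm = z - mean(z))
    }
    if (!ok) {
      message(sprintf("stride window %d not covered by displacement; dropped", w$stride_index))
      next
    }
    if (!is.null(events)) {
      for (limb in intersect(c("LH", "RH", "LF", "RF"), unique(events$limb))) {
        ct <- window_contact(events, limb, w$start_s, w$end_s)
        if (nrow(ct) == 1) {
          stance_rows[[length(stance_rows) + 1]] <- tibble::tibble(
            stride_index = w$stride_index, limb = limb,
            on_pct = (ct$on_s - w$start_s) / dur * 100,
            off_pct = (ct$off_s - w$start_s) / dur * 100)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (length(stance_rows) > 0) {
    attr(out, "stance_pct") <- dplyr::bind_rows(stance_rows)
  }
  out
}
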