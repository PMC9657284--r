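# Per-stride variables: temporal limb metrics, extrema, symmetry indices,
# and the lameness-screening inclusion filter.

#' Temporal limb variables per stride
#'
#' For each complete stride window: stride duration, fore/hind stance and
#' swing durations (left/right averaged), duty factors, diagonal and lateral
#' dissociation, and suspension. Dissociations are signed percent of stride,
#' positive when the hind hoof contact precedes that of the (diagonal or
#' ipsilateral) fore hoof; each is computed for both limb pairs of the
#' stride (LH-RF and RH-LF diagonals; LH-LF and RH-RF lateral pairs) with
#' nearest-contact pairing wrapped to half a stride, and reported as the
#' mean of the two. Diagonal dissociation is reported for walk and trot
#' only. Suspension is the percent of stride during which no stance
#' interval of any limb covers the instant.
#'
#' @param events tibble `limb`, `on_s`, `off_s`.
#' @param windows stride windows from [pair_strides()].
#' @param gait gait label; controls whether diagonal dissociation is
#'   reported and enables a consistency warning when stance overlap
#'   contradicts the labeled gait (e.g. suspension found in a walk).
#' @return tibble, one row per complete stride.
#' @export
temporal_variables <- function(events, windows, gait = c("walk", "trot", "tolt", "pace")) {
  gait <- match.arg(gait)
  windows <- windows[windows$complete, , drop = FALSE]
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    dur <- w$end_s - w$start_s
    ct <- lapply(c("LH", "RH", "LF", "RF"), function(l) window_contact(events, l, w$start_s, w$end_s))
    names(ct) <- c("LH", "RH", "LF", "RF")
    st <- vapply(ct, function(e) e$off_s - e$on_s, numeric(1))
    stance_fl <- mean(st[c("LF", "RF")])
    stance_hl <- mean(st[c("LH", "RH")])

    diss <- function(hind, fore) {
      f_on <- events$on_s[events$limb == fore]
      d <- wrap_signed(f_on - ct[[hind]]$on_s, dur)
      d[which.min(abs(d))] / dur * 100
    }
    dd <- mean(c(diss("LH", "RF"), diss("RH", "LF")))
    ld <- mean(c(diss("LH", "LF"), diss("RH", "RF")))

    covered <- interval_union_length(events$on_s, events$off_s, w$start_s, w$end_s)
    susp <- max(0, (dur - covered) / dur * 100)

    tibble::tibble(stride_index = w$stride_index,
                   stride_duration_s = dur,
                   stance_duration_fl_s = stance_fl,
                   stance_duration_hl_s = stance_hl,
                   swing_duration_fl_s = dur - stance_fl,
                   swing_duration_hl_s = dur - stance_hl,
                   duty_factor_fl = stance_fl / dur,
                   duty_factor_hl = stance_hl / dur,
                   diagonal_dissociation_pct = if (gait %in% c("walk", "trot")) dd else NA_real_,
                   lateral_dissociation_pct = ld,
                   suspension_pct = susp)
  })
  out <- dplyr::bind_rows(rows)
  if (gait %in% c("walk", "tolt") && any(out$suspension_pct > 1)) {
    warning(sprintf("suspension found in a stride labeled %s; metrics computed anyway", gait),
            call. = FALSE)
  }
  out
}

# Parabolic (three-point) refinement of a sampled extremum at global index i.
refine_extremum <- function(tt, yy, i) {
  y1 <- yy[i - 1]; y2 <- yy[i]; y3 <- yy[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * 100) {
    return(c(tt[i], y2))
  }
  dx <- 0.5 * (y1 - y3) / denom
  h <- tt[i + 1] - tt[i]
  c(tt[i] + dx * h, y2 - 0.25 * (y1 - y3) * dx)
}

# indices of strict interior local minima of y restricted to idx
local_minima <- function(y, idx) {
  i <- idx[idx > 1 & idx < length(y)]
  i[!is.na(y[i]) & !is.na(y[i - 1]) & !is.na(y[i + 1]) & y[i] < y[i - 1] & y[i] < y[i + 1]]
}

# pick the two best extrema (lowest minima / highest maxima) at least
# min_sep apart in time
pick_two <- function(cand_t, cand_v, decreasing, min_sep) {
  o <- order(cand_v, decreasing = decreasing)
  picked <- integer(0)
  for (j in o) {
    if (all(abs(cand_t[j] - cand_t[picked]) >= min_sep)) picked <- c(picked, j)
    if (length(picked) == 2) break
  }
  picked
}

#' Locate the two minima and two maxima of each segment per stride
#'
#' Works on the raw-sample displacement within each stride window, with
#' three-point parabolic refinement of extremum time and value (sub-sample
#' accuracy; a dense brute-force argmin/argmax agrees to within the sample
#' spacing). Each extremum is assigned to the left- or right-referenced half
#' of the stride by wrapped proximity to the reference limb stance midpoint
#' (left/right forelimb for head and withers, left/right hindlimb for
#' pelvis), and its timing is expressed as percent of that limb's stance,
#' `(t - hoof_on) / (hoof_off - hoof_on) * 100`, with values below 0 or
#' above 100 denoting extrema before contact or after lift-off.
#'
#' @param disp tibble `time_s` + `<segment>_mm` columns.
#' @param windows stride windows from [pair_strides()].
#' @param events event tibble (reference limb stances).
#' @param gait gait label; sets the expected stance phase of the maxima
#'   used to disambiguate the left/right assignment (lift-off for trot and
#'   pace, midstance for walk, the stance boundary for toelt).
#' @return tibble, one row per stride x segment x side: `min_time_s`,
#'   `min_mm`, `min_pct_stance`, `max_time_s`, `max_mm`, `max_pct_stance`,
#'   `ref_limb`. Stride/segment combinations without two strict minima and
#'   maxima are skipped with a warning.
#' @export
find_extrema <- function(disp, windows, events, gait = c("trot", "walk", "tolt", "pace")) {
  gait <- match.arg(gait)
  dcols <- grep("_mm$", names(disp), value = TRUE)
  tt <- disp$time_s
  windows <- windows[windows$complete, , drop = FALSE]
  ref_of <- function(seg) if (seg == "pelvis") c("LH", "RH") else c("LF", "RF")
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    dur <- w$end_s - w$start_s
    idx <- which(tt >= w$start_s & tt < w$end_s)
    for (dc in dcols) {
      seg <- sub("_mm$", "", dc)
      y <- disp[[dc]]
      mins <- local_minima(y, idx)
      maxs <- local_minima(-y, idx)
      if (length(mins) < 2 || length(maxs) < 2) {
        warning(sprintf("stride %d, %s: fewer than two strict minima/maxima (flat or short trace)",
                        w$stride_index, seg), call. = FALSE)
        next
      }
      rmin <- vapply(mins, function(j) refine_extremum(tt, y, j), numeric(2))
      rmax <- vapply(maxs, function(j) refine_extremum(tt, y, j), numeric(2))
      pm <- pick_two(rmin[1, ], rmin[2, ], decreasing = FALSE, min_sep = 0.2 * dur)
      px <- pick_two(rmax[1, ], rmax[2, ], decreasing = TRUE, min_sep = 0.2 * dur)
      if (length(pm) < 2 || length(px) < 2) {
        warning(sprintf("stride %d, %s: could not isolate two separated minima/maxima",
                        w$stride_index, seg), call. = FALSE)
        next
      }
      refs <- ref_of(seg)
      ctL <- window_contact(events, refs[1], w$start_s, w$end_s)
      ctR <- window_contact(events, refs[2], w$start_s, w$end_s)
      if (nrow(ctL) == 0 || nrow(ctR) == 0) next
      pct_of <- function(t, ct) {
        stance <- ct$off_s - ct$on_s
        (wrap_signed(t - ct$on_s - stance / 2, dur) + stance / 2) / stance * 100
      }
      assign_sides <- function(t2, kind) {
        # t2: times of the two extrema; returns order c(left_idx, right_idx).
        # The two extrema sit half a stride apart, so either could be
        # expressed relative to either reference stance; the left one is
        # whichever lies nearest the gait's expected stance phase: minima
        # near midstance in all gaits, maxima near lift-off in the running
        # gaits but near midstance in the vaulting walk and at the stance
        # boundary in toelt.
        anchor <- if (kind == "min") 35 else
          switch(gait, walk = 60, tolt = 50, 100)
        p <- c(pct_of(t2[1], ctL), pct_of(t2[2], ctL))
        if (abs(p[1] - anchor) <= abs(p[2] - anchor)) c(1L, 2L) else c(2L, 1L)
      }
      am <- assign_sides(rmin[1, pm], "min")
      ax <- assign_sides(rmax[1, px], "max")
      for (s in 1:2) {
        side <- c("left", "right")[s]
        ct <- if (s == 1) ctL else ctR
        tmin <- rmin[1, pm[am[s]]]; vmin <- rmin[2, pm[am[s]]]
        tmax <- rmax[1, px[ax[s]]]; vmax <- rmax[2, px[ax[s]]]
        rows[[length(rows) + 1]] <- tibble::tibble(
          stride_index = w$stride_index, segment = seg, side = side,
          ref_limb = c(refs[1], refs[2])[s],
          min_time_s = tmin, min_mm = vmin,
          min_pct_stance = pct_of(tmin, ct),
          max_time_s = tmax, max_mm = vmax,
          max_pct_stance = pct_of(tmax, ct))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Movement-symmetry indices and vertical range of motion per stride
#'
#' The D-indices are the signed differences between the two extrema of a
#' segment within a stride, left-referenced half minus right-referenced
#' half: `HDmin`/`HDmax` for the head, `WDmin`/`WDmax` for the withers,
#' `PDmin`/`PDmax` for the pelvis. All are identically zero for a perfectly
#' symmetric stride and invariant to adding a constant to the trace. ROMz
#' per segment is the highest minus the lowest position over the stride.
#'
#' @param extrema output of [find_extrema()].
#' @return tibble, one row per stride, with the six D-indices (mm) and
#'   `romz_head`, `romz_withers`, `romz_pelvis` (mm).
#' @export
symmetry_indices <- function(extrema) {
  prefix <- c(head = "H", withers = "W", pelvis = "P")
  long <- extrema |>
    dplyr::group_by(.data$stride_index, .data$segment) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(
      Dmin = .data$min_mm[.data$side == "left"] - .data$min_mm[.data$side == "right"],
      Dmax = .data$max_mm[.data$side == "left"] - .data$max_mm[.data$side == "right"],
      romz = max(.data$max_mm) - min(.data$min_mm),
      .groups = "drop") |>
    dplyr::mutate(
      d_min_name = paste0(prefix[.data$segment], "Dmin"),
      d_max_name = paste0(prefix[.data$segment], "Dmax"),
      romz_name = paste0("romz_", .data$segment))
  dmin <- tidyr::pivot_wider(long, id_cols = "stride_index",
                             names_from = "d_min_name", values_from = "Dmin")
  dmax <- tidyr::pivot_wider(long, id_cols = "stride_index",
                             names_from = "d_max_name", values_from = "Dmax")
  romz <- tidyr::pivot_wider(long, id_cols = "stride_index",
                             names_from = "romz_name", values_from = "romz")
  dplyr::left_join(dplyr::left_join(dmin, dmax, by = "stride_index"),
                   romz, by = "stride_index")
}

#' Lameness-screening inclusion filter
#'
#' A horse's straight-line trot is acceptably symmetric when the absolute
#' head differences do not exceed 16 mm and the absolute pelvis differences
#' do not exceed 8 mm. "Exceed" is strict: a value exactly at the threshold
#' is included. The decision lists every violated criterion.
#'
#' @param indices named numeric vector (typically per-horse trot medians)
#'   with elements `HDmin`, `HDmax`, `PDmin`, `PDmax` (mm).
#' @param head_threshold_mm,pelvis_threshold_mm thresholds (mm).
#' @return list with `decision` (`"include"`, `"exclude"` or
#'   `"indeterminate"` when any index is missing) and `reasons` (character
#'   vector of violated indices).
#' @export
inclusion_filter <- function(indices, head_threshold_mm = 16, pelvis_threshold_mm = 8) {
  need <- c("HDmin", "HDmax", "PDmin", "PDmax")
  if (!all(need %in% names(indices)) || any(is.na(indices[need]))) {
    return(list(decision = "indeterminate",
                reasons = setdiff(need, names(indices)[!is.na(indices)])))
  }
  thr <- c(HDmin = head_threshold_mm, HDmax = head_threshold_mm,
           PDmin = pelvis_threshold_mm, PDmax = pelvis_threshold_mm)
  viol <- need[abs(indices[need]) > thr[need]]
  list(decision = if (length(viol) > 0) "exclude" else "include",
       reasons = viol)
}
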