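# Between-segment timing differences of the vertical extrema.

#' Between-segment phase differences of minima and maxima
#'
#' For each stride (left-hind hoof-on stride split) and each segment pair
#' (head-withers, head-pelvis, withers-pelvis), the timing difference
#' between the left-referenced extrema of the two segments, in percent of
#' stride, matched nearest-in-time and wrapped to `(-50, 50]`. Positive
#' means the first-named segment reaches the extremum first. Walk and toelt
#' show offsets near a quarter stride between some segments, where naive
#' index pairing would alias by half a stride; nearest matching with the
#' signed wrap avoids that.
#'
#' @param extrema output of [find_extrema()].
#' @param windows stride windows from [pair_strides()].
#' @return tibble, one row per stride, with columns `hw_min`, `hp_min`,
#'   `wp_min`, `hw_max`, `hp_max`, `wp_max` (signed %StrD; `NA` when a
#'   segment's extremum is missing for the stride).
#' @export
phase_differences <- function(extrema, windows) {
  windows <- windows[windows$complete, , drop = FALSE]
  pairs <- list(hw = c("head", "withers"),
                hp = c("head", "pelvis"),
                wp = c("withers", "pelvis"))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    dur <- w$end_s - w$start_s
    ex <- extrema[extrema$stride_index == w$stride_index, ]
    pct <- function(seg, kind, sides) {
      t <- ex[[paste0(kind, "_time_s")]][ex$segment == seg & ex$side %in% sides]
      if (length(t) == 0) return(NA_real_)
      (t - w$start_s) / dur * 100
    }
    out <- list(stride_index = w$stride_index)
    for (pn in names(pairs)) {
      a <- pairs[[pn]][1]; b <- pairs[[pn]][2]
      for (kind in c("min", "max")) {
        ta <- pct(a, kind, "left")
        # nearest-in-time match: the two segments may be referenced to
        # different limbs (fore vs hind), so the partner extremum is
        # whichever of the second segment's two is closest under the wrap
        tb <- pct(b, kind, c("left", "right"))
        out[[paste0(pn, "_", kind)]] <- if (anyNA(c(ta, tb[1]))) NA_real_ else {
          d <- wrap_signed(tb - ta, 100)
          d[which.min(abs(d))]
        }
      }
    }
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}
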