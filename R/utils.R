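# shared small helpers

#' Wrap a time difference onto a signed half-period interval
#'
#' Maps `x` onto `(-period/2, period/2]`. Used wherever two cyclic event
#' times (footfalls, extrema) must be compared within a stride: the shorter
#' signed separation is the physically meaningful one.
#'
#' @param x numeric vector of differences (same units as `period`).
#' @param period cycle length (stride duration in seconds, or 100 for
#'   percent-of-stride quantities).
#' @return numeric vector in `(-period/2, period/2]`.
#' @export
wrap_signed <- function(x, period) {
  y <- x %% period
  ifelse(y > period / 2, y - period, y)
}

# evaluate expr with a fixed RNG state when seed is given, leaving the
# caller's RNG untouched
with_seed_if <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# total length of the union of intervals [on, off), clipped to [lo, hi)
interval_union_length <- function(on, off, lo, hi) {
  on <- pmax(on, lo)
  off <- pmin(off, hi)
  keep <- off > on
  if (!any(keep)) return(0)
  on <- on[keep]; off <- off[keep]
  o <- order(on)
  on <- on[o]; off <- off[o]
  tot <- 0
  cur_on <- on[1]; cur_off <- off[1]
  for (i in seq_along(on)[-1]) {
    if (on[i] > cur_off) {
      tot <- tot + (cur_off - cur_on)
      cur_on <- on[i]; cur_off <- off[i]
    } else {
      cur_off <- max(cur_off, off[i])
    }
  }
  tot + (cur_off - cur_on)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
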