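# Full per-trial analysis chain: events -> strides -> displacement ->
# extrema -> per-stride variable table.

#' Analyze a trial end to end
#'
#' Chains stride pairing, double integration (or ground-truth displacement),
#' time normalization, extremum location, temporal variables, symmetry
#' indices and between-segment phase differences into a single per-stride
#' variable table.
#'
#' @param trial a `gait_trial` from [simulate_trial()] or [read_trial()].
#' @param events `"truth"` (simulator pass-through, default) or
#'   `"detected"` (surrogate detector on the limb signals).
#' @param displacement `"integrated"` (double-integrate the acceleration,
#'   default) or `"truth"` (use the emitted ground-truth displacement;
#'   useful to isolate integration error).
#' @param n_points normalized stride grid length.
#' @return object of class `gait_analysis`: list with `strides` (one row
#'   per stride: temporal variables, ROMz, left-referenced extremum timing
#'   as percent of reference stance, D-indices, phase differences),
#'   `extrema`, `windows`, `events`, `displacement`, `normalized` and
#'   `template`.
#' @examples
#' trial <- simulate_trial(make_template("trot", "warmblood", list(n_strides = 4)))
#' an <- analyze_trial(trial)
#' an$strides
#' @export
analyze_trial <- function(trial, events = c("truth", "detected"),
                          displacement = c("integrated", "truth"),
                          n_points = 101) {
  stopifnot(inherits(trial, "gait_trial"))
  events <- match.arg(events)
  displacement <- match.arg(displacement)
  ev <- if (events == "truth") trial$events else trial_events(trial, "detect")
  win <- pair_strides(ev)
  disp <- if (displacement == "integrated") {
    integrate_displacement(trial$accel, win)
  } else {
    trial$disp
  }
  tv <- temporal_variables(ev, win, trial$template$gait)
  ex <- find_extrema(disp, win, ev, gait = trial$template$gait)
  sym <- symmetry_indices(ex)
  ph <- phase_differences(ex, win)
  norm <- segment_and_normalize(disp, win, ev, n_points = n_points)

  # left-referenced extremum timing, Table-style: % of reference stance
  timing <- ex[ex$side == "left", c("stride_index", "segment",
                                    "min_pct_stance", "max_pct_stance")] |>
    tidyr::pivot_wider(names_from = "segment",
                       values_from = c("min_pct_stance", "max_pct_stance"),
                       names_glue = "{segment}_{.value}")

  strides <- tv |>
    dplyr::left_join(sym, by = "stride_index") |>
    dplyr::left_join(timing, by = "stride_index") |>
    dplyr::left_join(ph, by = "stride_index") |>
    dplyr::mutate(gait = trial$template$gait,
                  condition = trial$template$condition,
                  .before = 1)

  structure(list(strides = strides, extrema = ex, windows = win, events = ev,
                 displacement = disp, normalized = norm,
                 template = trial$template),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf("<gait_analysis> %s / %s: %d strides analyzed\n",
              x$template$gait, x$template$condition, nrow(x$strides)))
  invisible(x)
}
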