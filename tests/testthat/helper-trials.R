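# Shared fixtures, built in code. Analyses of the reference templates are
# memoised because several test files probe the same noiseless trials.

.trial_cache <- new.env(parent = emptyenv())

cached_analysis <- function(gait, condition, n_strides = 4, ...) {
  key <- paste(gait, condition, n_strides, sep = "|")
  if (is.null(.trial_cache[[key]])) {
    tpl <- make_template(gait, condition, list(n_strides = n_strides), ...)
    .trial_cache[[key]] <- suppressMessages(suppressWarnings(
      analyze_trial(simulate_trial(tpl))))
  }
  .trial_cache[[key]]
}

# events of a perfectly regular gait with contacts at the given stride
# phases, for constructing analytic test cases without the simulator
regular_events <- function(stride_s, n_strides, phases, stance_fl_s, stance_hl_s) {
  stance <- c(LH = stance_hl_s, RH = stance_hl_s, LF = stance_fl_s, RF = stance_fl_s)
  rows <- lapply(names(phases), function(l) {
    on <- (seq_len(n_strides) - 1 + phases[[l]]) * stride_s
    if (phases[[l]] > 0) on <- c((phases[[l]] - 1) * stride_s, on)
    if (l == "LH") on <- c(on, n_strides * stride_s)
    tibble::tibble(limb = l, on_s = on, off_s = on + stance[[l]])
  })
  dplyr::bind_rows(rows)
}

ideal_walk_events <- function(stride_s = 1.1, n_strides = 4,
                              stance_fl_s = 0.65 * stride_s,
                              stance_hl_s = 0.6 * stride_s) {
  regular_events(stride_s, n_strides,
                 c(LH = 0, LF = 0.25, RH = 0.5, RF = 0.75),
                 stance_fl_s, stance_hl_s)
}
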