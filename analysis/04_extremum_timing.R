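#!/usr/bin/env Rscript
# Timing of the vertical minima and maxima of head, withers and pelvis:
# per-gait medians as percent of the reference limb stance (left fore for
# head/withers, left hind for pelvis; values < 0 or > 100 are before
# contact / after lift-off), and between-segment timing differences as
# percent of stride.

library(hoofbeat)
suppressMessages(library(dplyr))
suppressMessages(library(tidyr))

strides <- tibble::as_tibble(utils::read.csv("results/stride_vars.csv"))

timing <- strides |>
  select(gait, condition, ends_with("_pct_stance")) |>
  pivot_longer(-c(gait, condition), names_to = "variable") |>
  group_by(gait, condition, variable) |>
  summarise(median = median(value), iqr = IQR(value), .groups = "drop")
utils::write.csv(timing, "results/extremum_timing.csv", row.names = FALSE)

phase <- strides |>
  select(gait, condition, hw_min, hp_min, wp_min, hw_max, hp_max, wp_max) |>
  pivot_longer(-c(gait, condition), names_to = "pair") |>
  group_by(gait, condition, pair) |>
  summarise(median = median(value), iqr = IQR(value), .groups = "drop")
utils::write.csv(phase, "results/phase_differences.csv", row.names = FALSE)

cat("Extremum timing, % of reference stance (median):\n")
print(pivot_wider(timing[, -5], names_from = "variable", values_from = "median"),
      width = Inf)
cat("\nBetween-segment timing differences, % of stride (median;\npositive = first-named segment reaches the extremum first):\n")
print(pivot_wider(phase[, -5], names_from = "pair", values_from = "median"),
      width = Inf)
cat("\nNote the trot warmblood pelvis maximum after lift-off (~110 % of\nstance) and the quarter-stride walk head-withers offset.\n")
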