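#!/usr/bin/env Rscript
# Simulate one reference trial per gait/condition pair and store the bundles.
#
# Each bundle holds the limb hoof events, the vertical acceleration of the
# head/withers/pelvis sensors, the ground-truth displacement the
# acceleration derives from, and the stylized limb signals for the
# surrogate detector. Everything downstream (02-05) reads these bundles.

library(hoofbeat)

out_dir <- "results/trials"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

gc <- gait_conditions()
for (i in seq_len(nrow(gc))) {
  tpl <- make_template(gc$gait[i], gc$condition[i],
                       overrides = list(n_strides = 8), seed = 100 + i)
  trial <- simulate_trial(tpl)
  path <- file.path(out_dir, paste(gc$gait[i], gc$condition[i], sep = "_"))
  write_trial(trial, path)
  cat(sprintf("%-5s %-17s stride %.2f s, %d strides -> %s\n",
              gc$gait[i], gc$condition[i], tpl$stride_duration_s,
              tpl$n_strides, path))
}
cat(sprintf("\n%d trial bundles written under %s\n", nrow(gc), out_dir))
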