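#!/usr/bin/env Rscript
# Step 1: lay out the treatment schedules for the two pen analogues and
# record the ground-truth inner school radius over each trial, so later
# steps can be judged against known behaviour.

source("analysis/00_common.R")

for (pen in names(pen_params)) {
  sch <- pen_schedule(pen_seeds[[pen]])
  sch$pen <- pen
  write.csv(as.data.frame(sch),
            file.path(results_dir, sprintf("schedule_pen%s.csv", pen)),
            row.names = FALSE)
  tt <- seq(0, max(sch$onset) + 180, by = 5)
  truth <- data.frame(
    pen = pen, t = tt,
    true_radius_m = school_radius(pen_params[[pen]], tt, sch))
  write.csv(truth,
            file.path(results_dir, sprintf("ground_truth_pen%s.csv", pen)),
            row.names = FALSE)
  d400 <- pen_params[[pen]]$displacement_factor[["400Hz"]]
  cat(sprintf(
    "pen %s: %d events, 400 Hz target radius %.2f m (baseline %.2f m, +%d%%)\n",
    pen, nrow(sch), 2.0 * (1 + d400), 2.0, round(100 * d400)))
}
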