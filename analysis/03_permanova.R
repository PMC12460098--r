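#!/usr/bin/env Rscript
# Step 3: permutational ANOVA on the assembled avoidance-distance table:
# Timing (before/during/after, fixed) x Frequency (fixed) x Pen (random),
# 9999 Freedman-Lane permutations, pooling of terms with p >= 25%, and
# pairwise Timing comparisons within each frequency.

source("analysis/00_common.R")

measurements <- read.csv(file.path(results_dir, "measurements.csv"))
measurements$phase <- factor(measurements$phase,
                             levels = c("before", "during", "after"))
measurements$level <- factor(measurements$level)
measurements$pen <- factor(measurements$pen)

fit <- permanova(distance_m ~ phase * level * pen, measurements,
                 random = "pen", n_perm = 9999, seed = 99)
cat("== full model ==\n"); print(fit)
write.csv(fit$aov.tab, file.path(results_dir, "permanova_full.csv"),
          row.names = FALSE)

pooled <- pool_terms(fit, threshold = 0.25,
                     keep = c("phase", "phase:level"))
cat("\n== pooled model ==\n"); print(pooled)
write.csv(pooled$aov.tab, file.path(results_dir, "permanova_pooled.csv"),
          row.names = FALSE)

pw <- do.call(rbind, lapply(levels(measurements$level), function(lv) {
  sub <- measurements[measurements$level == lv, ]
  out <- pairwise_permanova(distance_m ~ phase, sub, n_perm = 9999,
                            seed = 123)
  cbind(level = lv, out)
}))
cat("\n== pairwise Timing within frequency ==\n")
print(pw, row.names = FALSE)
write.csv(pw, file.path(results_dir, "pairwise_timing.csv"),
          row.names = FALSE)

sig <- pw[pw$p_perm <= 0.05, ]
cat(sprintf("\n%d of %d pairwise contrasts significant at 5%%\n",
            nrow(sig), nrow(pw)))
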