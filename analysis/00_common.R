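# Shared study configuration for the analysis scripts: two pen analogues
# exposed to a 400 Hz tone (displacement +28% in pen A, +12% in pen B,
# the effect sizes under study) and a 200 Hz control tone (no response),
# 3 replicates each, 60-s stimuli with 10-min breaks, 5-s transition trim.

library(pensonar)

study_config <- sonar_config()          # 10 m range, 0.05 m bins, 8 s/rev

pen_params <- list(
  A = school_params(displacement_factor = c("400Hz" = 0.28, "200Hz" = 0)),
  B = school_params(displacement_factor = c("400Hz" = 0.12, "200Hz" = 0)))

pen_seeds <- c(A = 1L, B = 2L)

pen_schedule <- function(seed)
  make_schedule(c("400Hz", "200Hz"), repetitions = 3, duration = 60,
                break_duration = 600, order = "random", seed = seed)

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)
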