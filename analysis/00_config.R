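# Shared study definition for the numbered analysis scripts.
# Two synthetic groups of 20 resting-state "subjects" (60 s at 128 Hz,
# 19-channel 10-20 montage): pink-noise controls, and an altered group
# with three extra quarter-cycle-lagged alpha1 couplings — a known
# ground truth for every downstream stage.

library(lpcnet)

study_seed <- 1L

alpha1_couplings <- list(
  list(i = 1, j = 12, band = c(8, 10), lag = pi / 2, amplitude = 2),
  list(i = 4, j = 16, band = c(8, 10), lag = pi / 3, amplitude = 2),
  list(i = 7, j = 19, band = c(8, 10), lag = -pi / 2, amplitude = 2))

study_config <- pipeline_config(
  n_subjects = 20, n_channels = 19, duration_s = 60,
  groups = list(control = list(),
                altered = list(couplings = alpha1_couplings)),
  seed = study_seed)

results_dir <- function(stage) {
  d <- file.path("results", stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
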