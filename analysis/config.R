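# Shared settings for the numbered analysis scripts: one seeded demo
# population re-derivable in every script, plus the output directory.

library(spikehist)

demo_seed <- 20260901L
demo_schedule <- stimulus_schedule()          # 4 x 150 ms bursts, 120 trials
demo_mix <- c(transient_depressing = 40, sustained_facilitating = 25,
              offset_only = 25, onset_and_offset = 35,
              suppressed = 15, unresponsive = 10)
results_dir <- file.path("results", "demo")
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

demo_dataset <- function() {
  generate_dataset(demo_mix, demo_schedule, seed = demo_seed)
}
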