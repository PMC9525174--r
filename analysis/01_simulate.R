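#!/usr/bin/env Rscript
# Simulate the demo population: 150 units drawn from six response archetypes
# under the 4 x 150 ms noise-burst protocol, with per-unit ground truth
# (planted per-repetition gains, analytic FDIs, cell classes, depths).
# Writes results/demo/spikes.tsv and results/demo/ground_truth.tsv.

source(file.path("analysis", "config.R"))

gen <- demo_dataset()
ds <- gen$dataset
gt <- gen$ground_truth

cat(sprintf("simulated %d units, %d trials, %d spikes\n",
            nrow(ds$units), demo_schedule$n_trials, nrow(ds$spikes)))
cat("archetype counts:\n")
print(table(gt$archetype))
cat(sprintf("analytic onset FDI by archetype (NA = no onset response):\n"))
print(tapply(gt$expected_fdi_onset, gt$archetype, unique))

write_spikes(ds, file.path(results_dir, "spikes.tsv"))
write_ground_truth(gt, file.path(results_dir, "ground_truth.tsv"))
cat("wrote", file.path(results_dir, "spikes.tsv"), "and ground_truth.tsv\n")
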