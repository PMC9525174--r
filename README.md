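# spikehist

Quantifying the short-term history dependence of sound **onset** and
**offset** spiking responses in auditory cortex recordings.

When a sound is repeated in quick succession, cortical responses to it
change: most onset responses shrink (depress), while responses to the
sound's termination behave differently, often staying stable or growing
(facilitating). `spikehist` is an analysis pipeline for measuring this from
per-unit, per-trial spike times recorded under a repeating noise-burst
protocol (by default 4 × 150 ms bursts separated by 150 ms of silence,
120 trials, ≥ 4 s of pre-stimulus baseline per trial). It is written for
electrophysiologists who have spike-sorted single units and want the full
chain — screening, detection, quantification, cell typing, population
structure — as tested, seeded, reusable code.

The pipeline stages, each an exported function:

1. **PSTHs** (`build_psth`, `zscore_and_normalize`): 10 ms-bin trial
   averages with baseline z-scoring and absolute-maximum normalization.
2. **Stimulus-locked firing screen** (`reliability_screen`): split-half
   PSTH reliability (mean Pearson correlation over random trial halves)
   against a shuffled-interspike-interval permutation null, BH-corrected;
   units pass at score ≥ 0.3 and adjusted p < 0.01.
3. **Unambiguous response detection** (`detect_response`): a window holds a
   response when its maximal rate exceeds baseline + 0.025 spikes/bin/trial,
   a z-score of 3, and 3× the prior 50 ms rate — all three at once.
4. **History dependence** (`fdi`): the facilitation–depression index of
   repetition *n*,

   FDI&#8345; = (m&#8345; − m₁) / max(m₁…m₄),

   computed under prior-subtracted, baseline-subtracted, prior-zero and
   area-under-curve response magnitudes; FDI₄ is the headline. Negative =
   depression, positive = facilitation.
5. **Cell typing** (`classify_ns_bs`, `optotag`): narrow- vs broad-spiking
   split at a 600 µs trough-to-peak boundary, and four-criterion
   opto-tagging (spike counts, light-evoked elevation, ≤ 5 ms latency,
   waveform identity r ≥ 0.95).
6. **Site QC** (`detect_mua_crossings`, `ftc_tuned`, `site_inclusion`,
   `fractional_depth`): multiunit threshold crossings at 5 robust-MADs,
   frequency-tuning tests with an ISI-shuffled null, primary-like latency
   gates, and fractional cortical depth.
7. **Population structure** (`distribution_match`, `build_offset_template`,
   `match_to_template`, `cluster_psths`): firing-rate distribution matching
   across groups, transient-offset template matching, and hierarchical
   clustering of normalized PSTHs with a 1 − correlation distance.

A seeded inhomogeneous-Poisson generator (`generate_dataset`,
`generate_waveforms`, `generate_opto_trials`, `generate_voltage_snippet`)
produces datasets with known ground truth — planted per-repetition gains
give a closed-form expected FDI of (f₄ − f₁)/max(f) — so every stage is
validated by parameter recovery.

## Worked example

Generate a small population with planted depression and recover it:

```r
library(spikehist)
sch <- stimulus_schedule()
#> Stimulus schedule: 4 x 150 ms bursts, 150 ms gaps, 120 trials
#>   analysis span [-0.200, 1.200] s, baseline 4.0 s, ITI 4.5 s

gen <- generate_dataset(c(transient_depressing = 3, offset_only = 2),
                        sch, seed = 1)
gen$dataset
#> Spike dataset: 5 units, 120 trials, 10756 spikes

p <- build_psth(gen$dataset, "u0001")
p <- zscore_and_normalize(p, baseline_stats(gen$dataset, "u0001"))
det <- detect_all_windows(p, make_windows(sch))
det[det$kind == "onset",
    c("index", "max_rate", "max_z", "prior_fr", "detected", "mag_minus_prior")]
#>   index  max_rate    max_z   prior_fr detected mag_minus_prior
#> 1     1 1.0333333 73.51194 0.01333333     TRUE       1.0200000
#> 3     2 0.7750000 54.77162 0.02333333     TRUE       0.7516667
#> 5     3 0.7083333 49.93541 0.01833333     TRUE       0.6900000
#> 7     4 0.3666667 25.14982 0.03000000     TRUE       0.3366667

on <- det[det$kind == "onset", ]
fdi(on$mag_minus_prior[order(on$index)])
#> [1] -0.6699346
gen$ground_truth$expected_fdi_onset[1]
#> [1] -0.5
```

All four onset windows clear the three detection thresholds; the measured
FDI₄ of −0.67 says the fourth response is depressed to roughly a third of
the first (this single 120-trial unit scatters around the planted −0.5;
averaged over seeds the estimate is unbiased, which is what the calibration
test checks). `run_pipeline()` chains all stages from a configuration list
and `write_report()` writes the per-unit tables plus a JSON manifest.

## The analysis workflow

The numbered scripts under `analysis/` run the full study on a 150-unit
simulated population and narrate what they find, writing tables under
`results/demo/`:

```sh
Rscript analysis/01_simulate.R            # population + ground truth
Rscript analysis/02_reliability_screen.R  # stimulus-locked firing screen
Rscript analysis/03_responses_and_fdi.R   # detection, FDIs, onset-vs-offset
Rscript analysis/04_cell_types.R          # NS/BS split and opto-tagging
Rscript analysis/05_population.R          # clustering, matching, templates
```

On the demo population the screen passes 140/150 units (all ten
unresponsive units fail), onset FDIs have median −0.43 versus +0.03 for
offsets (rank-sum p ≈ 5 × 10⁻⁸), the conclusion is unchanged under all
three magnitude methods, and clustering recovers the planted archetype
structure.

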