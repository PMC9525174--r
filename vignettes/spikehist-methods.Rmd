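---
title: "Measuring history dependence of onset and offset spiking responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring history dependence of onset and offset spiking responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Neurons in auditory cortex respond to the start of a sound (an *onset*
response) and, in many cells, to its termination (an *offset* response).
Both responses change when a sound is repeated in quick succession: they may
shrink (depression) or grow (facilitation). `spikehist` implements a
complete, testable pipeline for quantifying this short-term history
dependence from per-trial spike times recorded under a repeating noise-burst
protocol: four 150 ms noise bursts separated by 150 ms of silence, presented
for 120 trials, with at least 4 s of spontaneous activity recorded before
each presentation.

Because the pipeline is intended to be verifiable end to end without access
to recordings, the package also contains a seeded spike-train generator with
exact ground truth. Every stage of the analysis can therefore be checked as
a parameter-recovery problem: plant a per-repetition gain, measure it back.

## The response measure and the FDI

For each unit a peristimulus time histogram (PSTH) is built at 10 ms
resolution over the span from 200 ms before the first burst to 150 ms past
the last one, in units of spikes/bin/trial. Baseline statistics (mean and SD
across the 10 ms bins of the trial-averaged baseline trace, computed over
the 4 s of pre-stimulus activity) give a z-scored view, and dividing the
z-scored PSTH by its absolute maximum gives a normalized view with
`max(abs(.)) == 1`.

Each burst defines an onset window (the burst itself) and an offset window
(the following silence). A window holds an *unambiguous response* when the
maximal rate in it clears three thresholds simultaneously:

1. an absolute excess of 0.025 spikes/bin/trial above the baseline mean,
2. a z-score above 3, and
3. three times the mean rate in the 50 ms immediately before the window
   (the *prior rate*), which excludes lingering firing from the previous
   response.

Response magnitude in a window is measured under three subtraction methods:
`minus_prior` (maximal rate minus the prior rate), `minus_baseline`
(maximal rate minus the baseline mean), and `auc` (the prior-subtracted
rate summed over the window's bins). History dependence is summarised by
the facilitation–depression index

$$\mathrm{FDI}_n = \frac{m_n - m_1}{\max(m_1,\dots,m_4)},$$

where $m_k$ is the magnitude of the response to repetition $k$. Depression
gives negative values, facilitation positive ones; when magnitudes are
non-negative the index lies in $[-1, 1]$. The headline value is
$\mathrm{FDI}_4$, where the effect of repetition is strongest;
$\mathrm{FDI}_2$ and $\mathrm{FDI}_3$ are computed and stored as well. A
fourth variant, `prior_zero`, equals `minus_baseline` but is flagged
eligible only for units whose four prior rates all returned to within one
baseline SD of the baseline mean.

## The stimulus-locked firing screen

Units whose firing carries no trial-locked structure should not enter the
response analysis. The screen scores each unit by split-half reliability:
trials are split at random into two disjoint halves, a PSTH is built from
each half, and the Pearson correlation of the two PSTH vectors is averaged
over iterations (1000 by default; the packaged demo configurations use 200).
Significance comes from a permutation null in which every trial's
interspike intervals are shuffled independently — this preserves each
trial's spike count, first spike time and total span while destroying
stimulus locking — and the split-half score is recomputed per surrogate.
The one-sided p-value uses the add-one permutation formula, p-values are
Benjamini–Hochberg adjusted across units, and a unit passes when its score
is at least 0.3 *and* its adjusted p is below 0.01.

Numerical choices here:

* An iteration in which either half-PSTH has zero variance contributes a
  correlation of 0, so silent units score approximately 0 rather than `NA`.
* Odd trial counts drop one random trial per iteration, splitting the rest
  evenly.
* One common set of random splits is reused across the null surrogates
  (scores are compared conditional on the splits); this halves the cost
  without changing the null distribution.
* The permutation p can never be exactly 0, so with `n_null = 200` the
  smallest attainable p is 1/201 — comfortably below the 0.01 cutoff,
  which is why the demo configurations use at least 200 surrogates.
* By default (`compute_p = "auto"`), the permutation p is computed only
  for units whose score already reaches the cutoff: a unit below 0.3 fails
  the combined screen whatever its p, so the verdict is identical and the
  p is reported as `NA`.

## The synthetic generator and what it does (not) emulate

Units are inhomogeneous Poisson processes: a homogeneous spontaneous rate
plus additive response kernels at each burst onset and offset, scaled by a
deterministic per-repetition gain vector $f = (1, f_2, f_3, f_4)$. Because
the gains are deterministic, the expected FDI has the closed form
$(f_4 - f_1)/\max(f)$, which is what the recovery tests check against.
Spikes are drawn exactly by superposition (homogeneous spontaneous spikes
over the whole trial; per-response Poisson counts with kernel-density times
via inverse CDF), so no discretisation error enters the generator.

The archetype library mirrors the response patterns seen in awake auditory
cortex: transient depressing onsets (narrow-spiking, PV-like), sustained
facilitating onsets (SST-like), offset-only units, units with both onset
and offset responses, sound-suppressed units (spontaneous firing thinned to
a fraction of its rate during each burst), and unresponsive units. Onset
kernels are exponential decays (default time constant 20 ms) or boxes
(sustained archetype); offset kernels default to a 20 ms exponential so
that offset responses are transient, peaking within the first 50 ms of the
gap. Default amplitudes were chosen so that evoked peaks sit one to two
orders of magnitude above the baseline-bin noise at 120 trials — a regime
comparable to well-isolated cortical units — and are fixed; tests that need
a different noise regime (e.g. the single-unit recovery example) override
the amplitude explicitly, not the defaults.

The inter-trial interval is compressed to 4.5 s rather than the 8 s of a
typical recording protocol: the baseline definition needs only 4 s of
pre-stimulus activity, and nothing downstream depends on the silence beyond
it. Facilitation/depression is a deterministic per-repetition gain, not a
stochastic synapse model — that is exactly what makes closed-form recovery
tests possible, and is a deliberate non-goal boundary. Real recordings add
trial-to-trial rate covariation; the generator exposes this as a
Fano-factor-like `dispersion` knob (a per-trial Gamma gain on the whole
rate profile, default 0 = pure Poisson) rather than asserting a value the
protocol does not constrain. Consequently, passing tests demonstrate
correctness of the estimators under Poisson variability and known kernels;
they do not certify behaviour under bursting, slow drift, or spike-sorting
contamination.

Opto-tagging fixtures: waveform snippets are a canonical biphasic template
(unit-amplitude trough, positive peak at the unit's trough-to-peak delay)
plus seeded noise, spanning −330 to 570 µs around the trough — the window
used for the tagging correlation. For trough-to-peak *measurement* of
broad-spiking units whose peak falls beyond 570 µs, the generator accepts a
wider `span_us`. Light-pulse trials follow the standard protocol: 75 trials
of a 10 ms pulse; tagged units fire a high-rate burst starting at their
light latency, untagged units fire only spontaneously.

## Interpretive choices the source protocol leaves open

Several details are under-determined by the protocol the pipeline
implements; each is surfaced as a documented default rather than a silent
assumption:

* **Baseline SD across bins, not trials.** The baseline SD is taken across
  time bins of the trial-averaged baseline trace, because the detection
  thresholds are expressed in spikes/bin/trial. Baseline bins use the same
  10 ms width as the response PSTH.
* **Bins are half-open** `[t, t + bin)`, so a spike exactly at a burst
  onset belongs to the first in-burst bin.
* **Prior window of the first onset response** is the last 50 ms of the
  pre-stimulus span, where the prior rate reduces to baseline; when the
  prior rate is zero the 3× gate is vacuous and deemed passed (the gate
  exists to exclude lingering firing, which is then absent).
* **Degenerate baselines** (SD = 0) raise an error rather than silently
  substituting a floor; pipeline configurations may enable an explicit
  floor of one spike in all trials (`1/n_trials` spikes/bin/trial).
* **ISI shuffling scope**: intervals are shuffled within each trial
  independently, preserving the per-trial structure of the data.
* **Reliability correlation** is the Pearson correlation at zero lag; the
  0.3 cutoff and the score range only make sense for a correlation
  coefficient.
* **Multiunit threshold crossings** use the normal-consistent MAD
  (`stats::mad`, i.e. the robust SD). Five *raw* MADs equal only 3.4
  Gaussian SDs, which at a 24414 Hz sampling rate would produce several
  false events per second on pure noise; five robust SDs give well under
  one event per minute, matching how robust thresholds are used in
  extracellular spike detection.
* **Frequency-tuning criterion A** is read as "best-frequency rate exceeds
  the non-best mean *by* 50%" (best > 1.5 × mean of the others); the
  literal reading (best > 0.5 × mean) is vacuously true.
* **Tuned-fraction denominator** for site inclusion counts only channels
  with significantly elevated tone-evoked firing.
* **Tone/light-evoked significance tests** (per channel and tagging
  criterion 2) are one-sided paired Wilcoxon signed-rank tests across
  presentations; the light-evoked window is the 10 ms pulse plus a 15 ms
  tail, covering sub-5 ms-latency responses without swallowing rebound.
* **Savitzky–Golay smoothing** for latency uses order 3 over a 10 ms
  window, which at 2 ms bins is 5 points — the smallest odd window valid
  for a cubic fit.
* **Clustering linkage** is average linkage on the 1 − Pearson-correlation
  distance (the distance is standard; the linkage is configurable, with
  complete and Ward available), with k = 4 clusters and clusters under 10
  units dropped.
* **Template matching** selects on squared correlation r² ≥ 0.75, which is
  sign-blind; an additional positive-correlation guard (switchable off)
  rejects anti-correlated matches.
* **Distribution matching** uses 6 equal-width bins over the pooled range
  of the groups' firing rates; per-bin selection counts are
  floor-plus-largest-remainder allocations of overlap × group size, capped
  at the cells available, so the worked example (10% vs 5% in a bin of a
  100-cell group) retains exactly 5 cells.

## Problem sizes used by the packaged runs

The test suite and the acceptance script run entirely on generated data at
sizes chosen to make every stochastic check statistically decisive while
staying desk-scale: 120-trial units throughout; 500 Poisson units for the
screen's false-positive rate; 200 units for FDI parameter recovery
(regression slope within [0.9, 1.1], r > 0.9); 300 units with depressing
onsets and stable offsets for the headline onset-vs-offset contrast
(rank-sum p < 0.001); 4 × 30 units for clustering recovery (adjusted Rand
index > 0.9); 200 split-half iterations and 200 permutation surrogates for
reliability. The demo analysis scripts under `analysis/` use a 150-unit
mixed population.

## Known limitations

* The generator's archetypes are caricatures: real populations mix
  response shapes continuously, and cluster boundaries on real data will be
  softer than the near-perfect recovery seen on planted archetypes.
* The detection rule's false-positive rate is a property of the rule, not
  of this implementation: at low firing rates, the maximum over 15 bins
  occasionally clears all three thresholds by chance, so a small fraction
  of "responsive" labels on weak units is expected — with ground truth
  available this is measurable, and the tests assert the planted responses
  are found rather than that no spurious window ever passes.
* Aligned-rank-transform two-way ANOVAs are out of scope; the pipeline's
  group comparisons are the rank-sum / signed-rank / Kruskal–Wallis family
  delegated to `stats`.
* Spike sorting, filtering design, and continuous-voltage processing beyond
  MAD threshold crossings are out of scope; the voltage entry point assumes
  a pre-filtered trace.
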