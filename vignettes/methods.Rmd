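---
title: "Handwriting and sEMG biomarkers for PD: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handwriting and sEMG biomarkers for PD: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdscribe)
```

## The analysis in one paragraph

Parkinson's Disease alters handwriting in two characteristic ways:
progressive shrinking of character size (micrographia) and irregular,
bradykinetic movement (slower, with unstable velocity and acceleration and
superimposed 4–6 Hz tremor). `pdscribe` quantifies both from two synchronous
streams recorded during short writing tasks — a pen-tablet stream (position,
pressure, azimuth/altitude tilt) and an 8-channel forearm surface-EMG
stream — and feeds the resulting feature vectors to a small feed-forward
neural classifier whose topology is chosen by a multi-objective genetic
algorithm. Two binary tasks are supported: *detection* (PD patients vs
healthy controls) and *rating* (mild vs moderate patients). Three writing
tasks are analysed separately: a five-turn anticlockwise spiral (dataset A),
and sequences of eight letter "l" at 2.5 cm and 5 cm (datasets B and C).

## Feature model

Each analysed repetition yields one feature vector of fixed, documented
order: 41 entries for spirals, 43 for letter tasks.

**Muscle activity (16 features).** Per channel, after DC-offset removal
(raw armband signals are offset-prone), the RMS
$\sqrt{\tfrac1n\sum_i x_i^2}$ and a tolerance-gated zero-crossing rate: a
pair of consecutive samples counts only when the sign strictly changes
*and* the jump magnitude $|x_k - x_{k+1}|$ reaches the tolerance, which is
the mean of the eight per-channel standard deviations of that recording;
the count is divided by the sample count. The gate applies symmetrically
to both crossing directions (the asymmetric reading of the rule would make
the index depend on the sign convention of the electrodes, which has no
physical meaning here). Samples exactly at zero carry no sign, so a
zero-touching pair never counts. Standard deviations use the population
(1/n) convention throughout the package.

**Kinematics (18 features) and pen posture (6).** The x–y trace, resampled
to a uniform grid (pen default 140 Hz, sEMG 200 Hz — configurable; the
armband's native rate is 200 Hz), is differentiated three times by interior
central differences, giving velocity, acceleration and jerk in X, Y and
Cartesian magnitude; each series is summarised by mean and population sd.
Because raw third derivatives are noise-dominated, a zero-phase 2nd-order
Butterworth low-pass (default 12 Hz cutoff, disableable) is applied to x
and y first; the signal is detrended on its endpoint line before filtering
and the trend restored afterwards, which removes start/end transients and
makes the filter exactly transparent to translations and to linear motion.
Pressure, azimuth and altitude are summarised over pen-down samples
(pressure > 0); azimuth is circular, so its statistics are computed on the
phase-unwrapped series (a pen hovering around the ±π cut must not produce
a spurious sd of ≈ π).

**Micrographia (letters; 3 features).** Prominent upper and lower peaks of
the y-trace (topographic prominence ≥ 20 % of the y-range by default; the
threshold is configurable since no universal criterion exists) are each fit
with an ordinary least-squares line against peak time; the features are the
unsigned angle α between the two lines, folded into [0, π/2] (only the
magnitude of convergence carries clinical meaning), and the two
coefficients of determination, with $R^2 = 1$ defined when SST = 0.
Constant-height writing gives two horizontal lines and α = 0; micrographia
tilts the upper line down and opens the angle.

**Spiral precision (spirals; 1 feature).** For every interior pen-down
point, β is the unsigned angle between the radius vector from the
trajectory centroid and the local direction of travel (central
difference); the feature is the population sd of β. A perfect circle gives
β ≡ π/2 and index 0; the index is invariant to translation, rotation and
uniform scaling, and grows with radial tremor. One caveat discovered while
validating against closed forms: the equiangular ("constant pitch angle")
property of a logarithmic spiral holds about its *pole*, and the centroid
of a sampled log spiral is measurably offset from the pole at any sampling
density, so the index of a plain log spiral is ≈ 0.1 rather than ≈ 0.
`spiral_precision()` therefore accepts an optional explicit `center`; the
test suite verifies the closed form both about the pole and on a
point-symmetric two-arm log spiral whose centroid provably coincides with
the pole.

## The synthetic cohort

No public recordings exist for this protocol, so the generator is a
first-class module. It emulates the reference cohort — 11 healthy, 12
mild, 9 moderate subjects; three analysed repetitions of each of the three
tasks (the familiarisation repetition is never generated) — with graded
pathological signatures:

| parameter | healthy | mild | moderate | units |
|---|---|---|---|---|
| micrographia rate | 0 | 0.03 | 0.08 | height decay / stroke |
| tremor amplitude | 0 | 0.4 | 0.9 | mm @ 5 Hz |
| speed scale | 1.00 | 0.85 | 0.70 | × |
| pressure mean (sd) | 0.55 (0.03) | 0.50 (0.05) | 0.45 (0.07) | normalized |
| sEMG tremor gain | 0 | 0.5 | 1.0 | — |
| positional noise | 0.05 | 0.10 | 0.15 | mm |

Micrographia, tremor and speed follow the calibrated presets above; the
pressure, sEMG and noise magnitudes are this package's own calibration
(chosen once for plausibility — reduced and more variable pressure,
tremor-band sEMG modulation, shakier traces — not fitted to any outcome).
Letter strokes are smooth sinusoidal arches, not a handwriting-synthesis
model: only the peak structure and kinematics matter downstream. Tremor is
injected radially on spirals and vertically on letters, where the β-index
and α-angle are most sensitive to it. sEMG channels are zero-mean
band-limited Gaussian noise (20 Hz to min(150, 0.45·rate) Hz; the upper
edge is clipped below the 200 Hz Nyquist) amplitude-modulated by a 4–6 Hz
envelope.

Per-subject random effects are drawn once per subject (log-normal for
positive parameters, so every invariant is preserved and repetitions
within a subject correlate): 12 % sd on speed and pressure, 25–35 % on
tremor, noise, sEMG modulation and micrographia, and 35 % per-channel
electrode-placement gains. Everything is reproducible from one integer
seed.

**What passing tests do and do not show.** The generator produces the
*direction* of every pathological effect with realistic between-subject
spread, but its signatures are cleaner than clinical data: the healthy
preset has exactly zero tremor and micrographia, so single features
(notably α) can separate groups almost perfectly, the decision tree often
keeps only 1–3 features (clinically 5–7 were observed), and end-to-end
accuracies on default synthetic cohorts approach 1.0. Passing the
end-to-end criterion therefore shows the pipeline is correctly wired and
statistically sane — not that clinical accuracy would reach these values.

## Classifier and topology search

The classifier is a feed-forward network with 1–3 hidden layers over the
activation vocabulary logsig / tansig / purelin / satlins and a fixed
2-neuron softmax output. Training details are this package's choices (the
reference protocol names none): inputs are z-scored with training-fold
statistics, weights are Glorot-initialised from the seed, and full-batch
Adam (lr 0.02) minimises the cross-entropy with early stopping on
validation loss (cap 500 epochs, patience 20, best weights restored).

Train/validation splits default to *subject-wise* stratified 70/30 —
repetitions of one subject never straddle the split, preventing identity
leakage — with a repetition-wise policy available for comparison; the
reference protocol does not document its split. The repeated-evaluation
harness draws `n_reps` independent (split, initialisation) pairs,
expresses each validation confusion matrix in percent, and averages;
metric means and sds are taken over repetitions. Note that a mean of
per-repetition metric ratios need not equal the metric of the mean
confusion matrix: in the reference study's own printed tables three of
twelve cases differ by up to 0.016 on exactly this point, which the
consistency tests record.

The topology search is an NSGA-II-style genetic algorithm: fixed-length
genomes (layer count, three size genes in 1–256 / 1–255, three activation
genes; inactive genes ride along and are ignored at decode), binary
tournament on (nondomination rank, crowding distance), uniform crossover
(rate 0.9), per-gene mutation (0.15), elitist μ+λ survival. Objectives:
maximise mean validation accuracy over a few short training runs (default
3, reduced epoch budget — fitness only needs to *rank* topologies) and
minimise total hidden neurons, the natural complexity counterweight since
the reference protocol reports only accuracy per chosen topology. Defaults
(population 30, 20 generations) are desk-scale; fitness values are cached
per genome, and training failures mark a genome worst rather than aborting
the run. The best topology is the front member with highest accuracy, ties
to fewer neurons.

## The six-case experiment

Cases 1–3 use all features of datasets A/B/C; cases 4–6 first reduce the
dataset with a single CART tree (Gini impurity, depth ≤ 5, min leaf 3,
no surrogate or competitor credit): the selected set is exactly the
features the fitted tree uses, ranked by normalized impurity decrease.
Selection runs on the full dataset before classification, mirroring the
sequential reference scheme; this is an optimistic-bias source on real
data and is deliberately reproduced, not fixed. The analysis unit is one
repetition (the reference protocol does not state whether repetitions
were pooled or averaged); subject ids are kept so the subject-wise split
compensates. A master seed fans out to per-stage sub-seeds (cohort,
selection, search, evaluation), making every report bit-for-bit
reproducible.

Problem sizes used by the test-suite and the acceptance script — chosen as
sensible desk-scale analogues of the 250-repetition reference protocol:
100 evaluation repetitions for the end-to-end and null-calibration checks,
search population 30 × 20 generations, 20 trials for planted-feature
recovery, 50-seed Monte-Carlo for generator effect directions.

## Numerical choices and degenerate inputs

* Derivatives need ≥ 7 uniform-grid samples (three central-difference
  stages each trim one sample per end); shorter streams raise classed
  errors rather than returning truncated values.
* Peak detection reduces plateaus to their first sample and measures
  prominence against strictly higher terrain, so equal-height apices keep
  full prominence.
* Resampling interpolates angles on the shortest arc (unwrap → linear →
  re-wrap), so a step from −3.1 to +3.1 rad passes through ±π.
* Zero sample-variance features are given unit scale during z-scoring.
* Metric denominators of zero yield `NA`, excluded from harness averages.
* Splits that leave a fold single-class are redrawn (bounded), then fail
  with a classed error.
* Ties between equal-gain tree splits resolve to the lowest canonical
  feature index, so row order never changes a selection.

## Known limitations

* The generator does not model in-air (pen-up) trajectories, letterform
  variability, medication state, or biomechanically realistic sEMG; its
  effect sizes are calibrations, not estimates from data.
* Feature selection before the train/validation split inflates selected
  datasets' accuracy on real data (kept for protocol fidelity, above).
* The classifier is deliberately small and CPU-bound; no probability
  calibration is attempted.
* Reported clinical accuracies from the reference cohort cannot be
  reproduced here because those recordings are private; the acceptance
  suite replaces them with arithmetic consistency checks on the printed
  tables plus synthetic-cohort analogues.
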