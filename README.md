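# pdscribe

Handwriting and forearm-sEMG biomarkers for Parkinson's Disease (PD)
detection and rating.

PD alters handwriting in two hallmark ways: characters shrink as writing
progresses (micrographia) and movement becomes slow and irregular
(bradykinesia, 4–6 Hz tremor). `pdscribe` implements a complete,
reproducible pipeline for a tablet-plus-armband recording protocol aimed at
clinicians and biosignal researchers who want to study these effects
quantitatively:

1. **Feature extraction** from a pen stream (x, y, pressure, azimuth,
   altitude) and an 8-channel surface-EMG stream, per repetition of three
   writing tasks — a five-turn anticlockwise spiral, and sequences of eight
   letter "l" at 2.5 cm and 5 cm. Each repetition yields a canonical
   41-feature (spiral) or 43-feature (letters) vector:
   * per-channel sEMG RMS, $\sqrt{\frac1n \sum_i x_i^2}$, and
     tolerance-gated zero-crossing rates (the gate is the mean of the eight
     per-channel sds; the count is normalized by signal length);
   * mean/sd of velocity, acceleration and jerk (X, Y, Cartesian), computed
     by central differences on a uniform grid after zero-phase low-pass
     filtering, plus pressure and pen-tilt summaries;
   * micrographia descriptors: the angle $\alpha$ between the regression
     lines through the upper and lower peaks of the y-trace, with both
     $R^2$ values; and the spiral precision index, the sd of the angle
     $\beta$ between the centroid-to-point radius and the local direction
     of travel.
2. **Feature selection** with a single Gini-impurity decision tree: the
   selected set is exactly the features the fitted tree uses, ranked by
   normalized impurity decrease.
3. **Classification** with a feed-forward network (1–3 hidden layers,
   activations logsig/tansig/purelin/satlins, 2-neuron softmax output) and
   a repeated train/evaluate harness reporting averaged percentage
   confusion matrices with accuracy, specificity and sensitivity
   (mean ± sd over repetitions).
4. **Topology search** with an NSGA-II-style multi-objective genetic
   algorithm (maximise validation accuracy, minimise hidden-neuron count).
5. A **synthetic cohort generator** (11 healthy / 12 mild / 9 moderate
   subjects, 3 repetitions × 3 tasks by default) with seeded, graded
   pathological signatures, so the entire pipeline is testable without
   clinical data — no public recordings exist for this protocol.

The two classification objectives are *detection* (PD vs healthy) and
*rating* (mild vs moderate), each run over six cases: datasets A/B/C
(spiral, small letters, large letters) with all features (cases 1–3) or
with the tree-selected subset (cases 4–6).

## Worked example

```r
library(pdscribe)

recs <- generate_cohort(cohort_spec(seed = 42))   # 288 synthetic recordings
ds   <- build_dataset(recs, "C", objective = 1)   # large letters, PD vs healthy
ds
#> <labeled_dataset C, objective 1> 96 rows x 43 features; labels: healthy=33, PD=63

sel <- select_features(ds)
sel
#> <selection_result> 1 features (tree depth 1):
#>   alpha_deg        1.000

ev <- repeated_eval(subset_features(ds, sel$selected),
                    parse_topology("17/2", "tansig/softmax"),
                    n_reps = 25, base_seed = 42)
ev
#> <eval_summary over 25 repetitions>
#>   mean confusion (%): TP 66.67  FP 0.00  FN 0.00  TN 33.33
#>   accuracy     1.0000 [0.0000]
#>   specificity  1.0000 [0.0000]
#>   sensitivity  1.0000 [0.0000]
```

The 96 rows are 32 subjects × 3 repetitions; splits are subject-wise by
default so repetitions of one subject never straddle train and validation.
The tree keeps a single feature here — `alpha_deg`, the micrographia
angle — and classification is perfect because the synthetic healthy preset
has exactly zero micrographia and tremor, which makes groups cleaner than
clinical cohorts (see the methods vignette for what this does and does not
demonstrate). `run_experiment()` wraps the same chain, adding the genetic
topology search and a JSON case report; `cli_main()` (wrapped by
`inst/cli/pdscribe.R`) exposes `simulate` / `extract` / `select` / `train` /
`moga` / `run` / `report` subcommands.

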