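# gazetraits

Predicting **personality-trait score ranges from everyday eye movements**.

People differ stably in how they move their eyes — how long fixations last,
how far and where saccades jump, how often they blink, how the pupil
behaves. `gazetraits` implements an end-to-end analysis pipeline that asks
whether such oculomotor statistics, recorded by a head-mounted eye tracker
during everyday behaviour, predict where a person falls on standard
personality questionnaires: the NEO-FFI five (neuroticism, extraversion,
openness, agreeableness, conscientiousness), Perceptual Curiosity (PCS)
and the Curiosity and Exploration Inventory (CEI). Trait scores are not
regressed directly; each trait is binned into **low / medium / high**
ranges at the cohort's 1/3 and 2/3 score percentiles and a classifier
predicts the range.

The pipeline:

1. **Preprocessing** — samples are erroneous when the pupil is undetected
   or gaze lies beyond 150% of the tracking range (outside
   [−0.25, 1.25] per normalised axis); participants with > 50% erroneous
   samples or > 30% constant gaze are screened out.
2. **Event detection** — dispersion-threshold (I-DT) fixations
   (dispersion = x-extent + y-extent ≤ 0.025 of the range, ≥ 100 ms),
   inter-fixation saccades (≤ 500 ms, peak velocity ≥ 2 range/s), blinks
   as 75–500 ms pupil-loss runs.
3. **Sliding windows** — 50% overlap; windows with > 50% erroneous
   samples, < 2 valid samples or no fixation/saccade are discarded.
4. **Features** — a fixed 207-dimensional vector per retained window:
   34 raw-gaze statistics ⊕ 64-cell 8×8 gaze heatmap ⊕ 53 oculomotor
   event statistics ⊕ 56 gaze n-gram histogram features (n = 1..4 over
   16-symbol saccade and 18-symbol fixation–saccade alphabets).
5. **Classification** — per trait, a random forest (100 trees, depth ≤ 5,
   ≤ 15 features per split) on standard-scaled window features; a
   participant's prediction is the majority vote over their windows.
   **Nested cross-validation** rotates contiguous participant blocks
   (test 5 / validation 5 / train the rest), selects window size and
   feature subset on the validation block, retrains on train ∪ validation
   and scores only held-out test participants.
6. **Evaluation** — macro F1 over the three ranges; uniform-random,
   most-frequent and label-permutation baselines; percentile-bootstrap
   95% CIs over repetitions; context-split prediction reliability
   (split halves, way I vs way II, shop vs way) via Fisher-averaged
   correlations; impurity-based feature importances; feature–trait
   correlations at 15 s windows.

Because real recordings are not redistributable, the package ships a
**synthetic cohort generator** (`generate_cohort()`) producing gaze
recordings with fixation/saccade/blink structure, pupil dynamics, track
loss, way1/shop/way2 context segments, Gaussian trait scores — and
configurable trait→oculomotor effect sizes, so that signal recovery and
null behaviour are both testable. See the methods vignette
(`vignettes/gaze-personality-pipeline.Rmd`) for the model, parameter and
design details.

## Worked example: the analysis workflow

The numbered scripts under `analysis/` run the whole study on a simulated
42-participant cohort (150 s recordings; extraversion wired to fixation
duration, saccade amplitude, blink rate and pupil baseline at ~1
parameter-SD per trait SD) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R        # cohort, screening, tertile bins
Rscript analysis/02_detect_events.R          # I-DT events + detector scores
Rscript analysis/03_extract_features.R       # 207-dim windows at 15/30 s
Rscript analysis/04_train_evaluate.R         # nested CV + baselines + importances
Rscript analysis/05_reliability_correlations.R
```

Output from a run of the above (abridged):

```
Screening: 42/42 retained (erroneous>0.5: 0, constant-gaze: 0)
Detector vs ground truth: mean recall 0.943, precision 0.984
  15 s: 775 retained windows (18.5 per participant), all finite: TRUE
Evaluating extraversion (10 repetitions, with permutation baseline) ...
  classifier mean F1 0.939 [0.925, 0.953]
Top 5 features by median importance (extraversion):
             feature     median        max
 fix_pupil_mean_mean 0.09672259 0.20646185
          pupil_mean 0.08776407 0.28852598
           pupil_max 0.06547506 0.09254733
        fix_dur_mean 0.06199396 0.14601816
Context-split reliability (extraversion, Fisher-averaged r):
   comparison         r n_pairs
 split_halves 0.8937701      10
 way1_vs_way2 0.8894479      10
  shop_vs_way 0.9275577      10
```

Reading the numbers: the detector recovers ~94% of recoverable generated
fixations; the classifier recovers the planted extraversion signal almost
perfectly (macro F1 0.94 against a label-permutation baseline of 0.28, a
uniform-random baseline of 0.30 and a most-frequent baseline of 0.09 —
see `results/f1_scores.csv`), the most important features are exactly the
pupil- and fixation-duration statistics the generator modulated, and
predictions agree strongly across recording contexts (r ≈ 0.89–0.93).
Traits with no planted signal score at or below chance, as they should —
the methods vignette explains why a nested-CV classifier on truly null
labels lands *below* 1/3 rather than at it.

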