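# scandecode

Decoding yes/no answers from single whole-brain fMRI scans.

## What this is for

Brain-based communication for people who cannot respond behaviorally
(e.g., disorders of consciousness) usually monitors activity in a few
preselected regions over tens of seconds per answer. An alternative is to
classify the *whole-brain activity pattern of every single scan*: a
participant answers a spoken yes/no question by performing one of two
self-paced mental tasks — counting down numbers for *yes*, recalling
positive autobiographical memories for *no* — during a 24 s response
period, and a previously trained classifier labels each scan of that
period. The answer is the majority label. `scandecode` implements this
scheme end-to-end, together with a synthetic BOLD generator that emulates
the two-day experiment, so the whole pipeline can be exercised, tested,
and studied without access to human data.

## The method in brief

* **Training data.** Eight day-1 runs alternating task A (32 s) and task B
  (32 s) with 16 s rests, three cycles per run (147 scans at TR = 2 s,
  first 3 discarded). Scan windows are shifted by 4 s (2 TR) for the
  hemodynamic delay; each 32 s block contributes 16 scans, so 8 fully
  acknowledged runs give 384 scans per class. Datasets are strictly
  balanced: a block whose start cue was missed is dropped together with
  its counterpart block of the other task.
* **Preprocessing (multivariate branch).** Per voxel: nuisance regression
  (6 motion parameters, WM/CSF proxies, global signal, session constant)
  → DCT high-pass at 0.008 Hz → session grand-mean scaling to 100 →
  z-scoring with day-pooled statistics.
* **Feature selection (optional).** Voxelwise GLM (boxcar ⊗ canonical HRF,
  AR(1) prewhitening, 0.0078 Hz high-pass in-design) on 8-mm-smoothed
  data; union of the one-sided `A > B` and `B > A` masks at `p < 0.001`
  uncorrected (P001) or Bonferroni `p < 0.05` (FWE05); computed split-half
  (odd runs select voxels for even-run training and vice versa).
* **Classifier.** Linear soft-margin SVM, `C = 1`, on per-voxel min-max
  `[-1, 1]` scaled features (training statistics only). Validated by
  leave-one-run-out cross-validation (pooled accuracy = total correct /
  total scans) and by cross-day transfer.
* **Inference.** Balanced-block permutation test: labels are permuted at
  block granularity within each run, the classifier is retrained each
  time, and the null accuracy is evaluated on the held-out response-period
  scans; `p = (1 + #{null ≥ obs}) / (1 + n)`.
* **Answer retrieval.** Majority vote over the first k = 11 of the 12
  response scans (odd k — no ties), per-run correct counts, cross-run
  consistency, and an accuracy-versus-duration curve at k = 3, 5, 7, 9, 11.

## Worked example

```r
library(scandecode)

report <- run_pipeline(pipeline_config(seed = 11, n_permutations = 200))

report$design$train_scans_per_class
#> [1] 384
round(report$day1_lorocv$pooled_accuracy, 3)
#> [1] 0.742
round(report$binary$single_scan_accuracy, 3)
#> [1] 0.786
report$binary$n_correct_per_run
#> [1] 6 6 6 5 6
report$binary$consistent_correct
#> [1] 5
```

Reading: the day-1 classifier labels 74.2% of held-out same-day single
scans correctly; applied to the five binary-answer runs of day 2 it labels
78.6% of the 360 response-period scans correctly, and after the majority
vote it retrieves 5-6 of the 6 answers in every run, with 5 sentences
decoded correctly in *all* runs. (The permutation p-value for the
single-scan accuracy is in `report$permutation$p_value`.)

The command line exposes the same stages on disk:

```sh
Rscript inst/cli/scandecode.R simulate --seed 1 --out data/
Rscript inst/cli/scandecode.R preprocess --in data/ --out prep/
Rscript inst/cli/scandecode.R train --in prep/ --out model.json
Rscript inst/cli/scandecode.R decode --in prep/ --model model.json --out decoded/
```

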