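---
title: "Single-scan decoding of yes/no answers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-scan decoding of yes/no answers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scandecode)
```

## The communication scheme

`scandecode` studies a brain-based binary communication protocol. A
participant learns two self-paced mental tasks — counting down numbers
("task A") and recalling positive autobiographical memories ("task B") —
and answers yes/no questions by performing task A for *yes* and task B for
*no* while whole-brain BOLD fMRI is acquired every `TR = 2` s. A linear
classifier trained on alternating-task runs assigns a label to every single
scan of a 24 s response period; the majority over the first `k` (odd,
default 11 of 12) scan labels becomes the decoded answer.

The package implements the full analysis chain and a synthetic-data
generator that emulates the experiment, so that every stage is testable
end-to-end without human data:

1. **Paradigm** — run schedules: 8 alternating runs on day 1 (3 cycles of
   32 s task A / 16 s rest / 32 s task B / 16 s rest after a 3-scan
   lead-in; 147 scans, 294 s), and on day 2 another 3 alternating runs plus
   5 binary-answer runs (6 sentences; 12 s sentence-to-prompt, 24 s
   response, 16 s rest; 159 scans, 318 s).
2. **Simulation** — planted two-class activation with realistic nuisance
   structure.
3. **Preprocessing** — nuisance regression, discrete-cosine high-pass,
   grand-mean scaling, day-level standardization (multivariate branch);
   Gaussian smoothing (GLM branch).
4. **Feature selection** — voxelwise GLM task contrasts thresholded at
   `p < 0.001` uncorrected ("P001") or Bonferroni-corrected `p < 0.05`
   ("FWE05"), computed split-half so selection never sees training data.
5. **Classification** — soft-margin linear SVM (`C = 1`) on min-max scaled
   single scans; leave-one-run-out cross-validation; cross-day transfer.
6. **Inference** — balanced-block permutation test of single-scan accuracy.
7. **Answer retrieval** — majority vote, per-run scoring, cross-run
   consistency, and the accuracy-versus-response-duration curve.

## The forward model

Each voxel's simulated time series is

$$ y_v(t) = B\,\bigl(1 + \beta_A(v)\,x_A(t) + \beta_B(v)\,x_B(t)\bigr)
   + d_v(t) + g(t) + m_v(t) + \varepsilon_v(t), $$

where $B$ is the baseline intensity (1000 by default), $x_A, x_B$ are task
boxcars convolved with the canonical double-gamma HRF and scaled to unit
plateau (so $\beta$ reads directly as fractional signal change), $d_v$ is a
slow cosine drift, $g$ a global AR(1) fluctuation shared by all in-mask
voxels, $m_v$ a motion-coupled component built from the simulated
realignment parameters, and $\varepsilon_v$ voxelwise AR(1) Gaussian noise.
In binary-answer runs each response window carries the boxcar of the task
matching the trial's factual answer; the answer key is stored as ground
truth for scoring only and is never read by any decoding operation.

The HRF uses the common double-gamma parameterization (response gamma with
shape 6 and scale 1, undershoot gamma with shape 16 scaled by 1/6, 32 s
kernel, peak normalized to 1). On a fine grid its peak falls near 5 s after
onset, which motivates the 4 s (2 TR) label shift applied to every scan
window.

### Ground truth and what the generator does not emulate

The discriminative structure is two partially overlapping Gaussian blobs
inside an ellipsoidal "brain" on a small grid (12 x 12 x 8 voxels of
3 x 3 x 5 mm by default): $\beta_A$ peaks in one half, $\beta_B$ in the
other, both truncated at 1% of peak so far-field voxels are exactly
inactive (numerically tiny activations would otherwise be inflated into
junk features by the day-level standardization). Defaults are
`beta_max = 0.04` (4% peak signal change) and `sigma = 0.01` (temporal SNR
100). These were chosen once so that the default protocol yields
leave-one-run-out accuracies in the high range reported for this kind of
two-task single-scan classification: with ~440 in-mask voxels instead of
tens of thousands, each informative voxel must carry more contrast, so the
per-voxel effect size is larger than a typical single real voxel would
show.

Two structural properties of this synthetic world are worth keeping in
mind when interpreting green tests:

* After day-level z-scoring, every purely signal-driven voxel carries the
  *same* standardized differential time course, so patterns concentrate in
  a two-dimensional subspace spanned by the two task regressors. Accuracy
  is then limited by the temporal overlap of windows (the HRF tail of a
  32 s block extends 32 s past its end, into the next block's shifted
  window under 16 s rests), not by voxel count. Real multi-region brain
  dynamics are richer, which is one reason real whole-brain
  cross-validation accuracies can exceed the synthetic ceiling here.
* There is no between-day effect: day-2 transfer in the simulator is as
  easy as same-day cross-validation. Passing transfer tests therefore shows
  correctness of the plumbing, not robustness to scanner or state drift.

The simulated confound series themselves (motion random walks, WM/CSF
proxies) scale with `confound_amplitude`. Setting it to 0 along with the
noise amplitudes gives a *fully deterministic* run — the meaning of
"noiseless" used by the end-to-end recovery tests. This matters: leaving
stochastic slow regressors on and regressing them out of noise-free data
distorts the (equally slow) task signal enough to occasionally flip a
vote, which is a nuisance-regression property worth knowing about, not a
decoding failure.

Cardiac/respiratory waveform noise, motion artifacts in k-space, slice
timing, realignment and spatial normalization are outside the generator's
scope; runs are simulated directly on the analysis grid.

## Preprocessing choices

The multivariate branch applies, per run: ordinary-least-squares nuisance
regression (6 motion parameters, white-matter and CSF proxy series, the
global in-mask mean, and a session constant), then discrete-cosine
high-pass filtering at 0.008 Hz, then grand-mean scaling of the session to
100, and finally voxelwise standardization with mean and SD pooled over
*all* of the day's runs. Because residualization removes the session mean,
the session-mean image is added back before grand-mean scaling — a
zero-mean series cannot be scaled to a positive grand mean, and this
ordering keeps every step meaningful. Whether the original SPM-based
chain handled the session mean the same way is not determinable from its
description; the add-back is this package's documented reading.

The high-pass is implemented as residualization against the DCT-II columns
whose frequency $j/(2D)$ lies strictly below the cutoff ($D$ = run duration
after discarding lead-in scans; 288 s gives 4 regressors at both 0.008 and
0.0078 Hz). The GLM branch keeps its slightly different traditional cutoff
(0.0078 Hz) inside the design matrix; both defaults are intentional and
kept distinct. Note a paradigm-design constraint this makes visible: the
task alternation must sit above the high-pass band. The default 96 s cycle
(0.0104 Hz) does; lengthening rests to 32 s would move the differential
signal to 0.0078 Hz, *inside* the stopband, and erase it.

Gaussian smoothing (8 mm FWHM default, GLM branch only) is separable with
zero padding at the volume edges; the synthetic mask is interior, so the
padding choice is immaterial but documented. All preprocessing operations
are mask-respecting: out-of-mask voxels pass through untouched.

### Numerical guards

* Rank-deficient nuisance matrices are residualized on their column space
  with a warning.
* A voxel is "flat" (set to zero by standardization, with a warning) when
  its pooled SD is below `1e-9` of its own mean magnitude — an exact zero
  test would let accumulated float residue be amplified to unit variance.
* A decision value of exactly 0 is labeled +1; ties in the majority vote
  are excluded by requiring odd `k` rather than broken by a rule.
* Scan indices are 0-based (scan *i* covers `[i*TR, (i+1)*TR)`), which
  makes every window computation exact integer arithmetic; array slicing
  converts internally to R's 1-based convention.

## GLM feature selection

The GLM operates on smoothed, unstandardized runs — the two branches share
only the raw data. The design has the two convolved 32 s task boxcars
(acknowledged blocks only), six motion parameters, one constant per run,
and each run's DCT set. Serial correlation is handled with a single pooled
AR(1) coefficient estimated from the lag-1 autocorrelation of OLS
residuals (within runs), followed by prewhitening by differencing; pooling
one rho rather than per-voxel estimates is deliberately conservative on
small synthetic grids. One-sided t thresholds are applied in the direction
of each contrast (A > B and B > A; the surviving sets are disjoint and
their union is the feature mask). Family-wise error control uses
Bonferroni over the tested voxels: the random-field-theory correction used
with real, smoothness-estimated data is out of scope, and Bonferroni is
conservative and fully specified.

Masks are computed separately from the odd-numbered and the even-numbered
day-1 runs; the mask from one half selects features for classifiers
trained on the *other* half, so selection and training never share scans
(at the cost of halving the training set to 192 scans per class, which is
also why the package evaluates both pairings and averages them).

## Classification and inference

Datasets are strictly balanced by construction: a task block whose start
cue went unacknowledged is dropped *together with* its same-ordinal
counterpart block of the other task in the same run (the GLM branch, by
contrast, drops only the unacknowledged block itself). Features are scaled
per voxel to `[-1, 1]` using the training minimum and maximum; test data
reuse the training scaling without clipping, and a constant training
feature maps to zero. The classifier is the standard L2-regularized
hinge-loss linear soft-margin model with `C = 1`; any solver reaching the
QP optimum is acceptable, and the implementation is checked against a
brute-force SMO oracle in the tests.

The balanced-block permutation test retrains the classifier under label
permutations that reassign labels at *block* granularity, independently
within each run, by permuting each run's multiset of block labels across
its blocks. This preserves the three structures the design imposes — run
membership, block membership (hence within-block temporal autocorrelation),
and per-run class balance. The cited construction for this family of tests
is not restated in detail in the source literature; within-run shuffling is
this package's documented choice. Evaluation uses a held-out scan set
(by default the 360 response-period scans), the scaler is fitted once
(it depends on features only, never labels), and the p-value uses the
add-one estimator `p = (1 + #{null >= observed}) / (1 + n)`, so `p = 0` is
impossible.

One open timing question is where the 12-scan response window is anchored.
The package anchors it at the answer prompt plus the 4 s hemodynamic
shift — the response period is when the participant executes the task — so
trial 1 of a default run maps to scans 11-22 (0-based).

## Problem sizes used by the tests and the bundled report

The default grid (12 x 12 x 8) keeps a full 16-run experiment around a
dozen seconds to simulate and preprocess. Replicate-heavy properties use a
reduced world chosen to keep the suite comfortably interactive while
leaving the statistics meaningful: the permutation-null calibration uses
20 zero-effect datasets of 4 training runs on an 8 x 8 x 6 grid with 200
permutations each; the duration-curve monotonicity property uses 20
replicates of a 4-run/3-run design at moderate noise; the chance-level
cross-validation check uses the full 8-run, 768-scan design. The
acceptance report runs the complete default protocol and reports the
permutation test at 500 iterations (the package default for a single
analysis remains 5,000).

## Known limitations

* The synthetic ceiling on single-scan accuracy (temporal window overlap,
  two-dimensional pattern subspace) means synthetic cross-validation
  accuracy is *not* a forecast of real-data performance in either
  direction.
* Nonlinear kernels, across-participant classification, recursive feature
  elimination, and repeated-question designs are out of scope.
* The permutation test's cost is one classifier fit per iteration; at
  null labels the fits are the slowest (many support vectors), which is
  why report-scale runs use fewer iterations than the package default.
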