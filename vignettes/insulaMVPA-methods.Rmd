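---
title: "Decoding vitality-form versus velocity processing: models, simulator and design choices"
author: "insulaMVPA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding vitality-form versus velocity processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind the synthetic generator, the numerical
choices, and the places where the design was genuinely open and a choice
had to be made.

# The question and the analysis

An observed action can be judged for its velocity or for its *vitality
form* (gentle / neutral / rude) — two readings of identical kinematics.
The analysis asks whether insular voxel patterns distinguish the two
task contexts. Because the tasks occupy separate runs (vitality: runs
1–2, velocity: runs 3–4), the decoding problem is "same stimulus level,
different task", e.g. *rude vs fast*, and the cross-validation scheme
must break the task–run confound as far as the design allows: each fold
trains on one vitality and one velocity run and tests on the other two
({1,3}|{2,4}, {2,4}|{1,3}, {2,3}|{1,4}, {1,4}|{2,3}).

The pipeline is: single-trial beta estimation → per-subject linear SVM
decoding with a permutation chance level → exact Wilcoxon signed-rank
group inference → group discriminative overlap maps with an
independence null and Benjamini–Hochberg FDR.

# Single-trial model

Each trial's response is fitted, voxel-wise, inside a six-volume
peristimulus window: the volume acquired at onset (the hemodynamic
response is still zero there, so it acts as the pre-response sample)
plus the five following volumes — 0 to 10 s after onset at TR 2 s. The
design matrix is `[HRF-convolved 2 s event, constant]`; the event
coefficient is scaled to percent signal change.

Two numerical choices matter here:

* **Kernel support.** The double-gamma HRF convolved with the 2 s boxcar
  is truncated at 12 s (six TR samples, unit peak). Because the minimum
  inter-stimulus interval is 12 s, consecutive trial responses are then
  strictly non-overlapping, and with noise switched off the windowed fit
  returns the embedded amplitude *exactly* — the round-trip identity the
  test suite asserts at 1e-6 relative error. The price is dropping the
  shallow post-12 s undershoot tail of the canonical shape; in a
  generator whose noise floor is ~1.6% signal this is far below
  detectability, and simulator and estimator share one kernel so the
  omission cancels.

* **Percent-change reference.** The beta is normalized by the window's
  fitted constant (the local baseline) rather than the voxel's whole-run
  mean. The run mean contains the run's own evoked signal (~0.4%
  relative bias at these trial densities), which would break the exact
  noiseless round trip; the local constant is unbiased in that limit,
  and `scale = "run_mean"` remains available for the conventional
  variant.

Catch trials (5 of 50 per run, followed by an explicit question) are
simulated as ordinary stimulus events but excluded from pattern
matrices: the decodable pool is the 45 experimental trials per run, 15
per level, giving 180 trials per subject and ROI.

# Decoding and inference

Per fold, features are z-scored with training-set statistics only, and a
linear soft-margin SVM (cost 1) is trained on 15 + 15 trials. Cost and
scaling are fixed, not tuned: with 30 training points and hundreds of
features the linear SVM is effectively a regularized mean-difference
direction, and tuning on the test side would leak information.

**Permutation null.** Training labels are shuffled *across the pooled
training trials of each fold* and the model retrained; test labels stay
intact. Shuffling within runs — a phrasing sometimes used for
within-run designs — is degenerate here: in a cross-task contrast every
training run contributes exactly one class, so within-run shuffles are
the identity. Per permutation, the four fold accuracies are averaged;
the chance estimate is the mean of the 1000 permutation accuracies
(≈50% for this balanced design), and empirical p-values use the
add-one formula (1 + #{null ≥ observed}) / (n + 1).

**Group test.** The one-sided Wilcoxon signed-rank test is computed from
its exact null distribution by convolving the generating function over
the (mid-)ranks. This stays exact under tied accuracies, where the
standard implementation falls back to a normal approximation; zero
differences are discarded (the classic convention). For n = 16 the most
extreme outcome has p = 2⁻¹⁶.

**Univariate control.** Mean ROI signal per task, compared by paired
t-test across subjects, verifies that decodable patterns are not a
global amplitude difference between vitality and velocity runs.

# Group discriminative maps

Signed SVM weights (positive = vitality-preferring) are averaged over
folds and over the three cross-task contrasts — the "collapsed" map; a
rank-then-average variant is exposed as `method = "rank_vote"`. Voxels
are ranked by |weight| (ties broken by voxel id), the top fraction f
(0.5 or 0.35) selected, and the per-voxel signed overlap counted over
subjects. Under the independence null each subject selects round(f·V)
voxels uniformly at random, so the overlap count is Binomial(S, f); the
Monte Carlo simulation reproduces this closed form and is retained both
as a validity check and as the basis of a maximum-overlap (family-wise)
variant. Monte Carlo tail probabilities pool iteration–voxel pairs,
valid because voxels are exchangeable under this null; its default is
10,000 iterations.

One structural fact deserves emphasis: the marginal tail probability of
an overlap of 10/16 at f = 0.5 is ≈0.227, which no Benjamini–Hochberg
step-up at q = 0.05 can admit. A per-voxel independence null therefore
demands overlaps of ~14/16 before anything survives in ROIs of a few
hundred voxels. Published overlap thresholds as low as 10/16 imply some
other null detail (e.g. cluster-level or maximum-statistic calibration);
this package implements the literal per-voxel procedure and the
max-statistic variant and does not claim either reproduces such a
threshold. The sign of a surviving group voxel is the side (positive /
negative) with the larger overlap count.

# The synthetic cohort

The generator encodes the claimed signal structure, not a biophysical
model:

* **Geometry.** Ball-shaped masks on a compact lattice with the
  published sizes (1533 / 1346 / 500 / 750 voxels at 2.5 mm); `scale`
  shrinks all counts proportionally. Within each insula, a contiguous
  dorso-central cluster is vitality-preferring and a smaller ventral one
  velocity-preferring.
* **Signal.** Every mask voxel receives a common response (1% signal
  change) per trial. Tuned voxels add `delta` (× a per-voxel jitter, SD
  0.3) in their preferred task. Deviations are demeaned within each
  insula per task, so the region-mean response is identical across
  tasks *by construction* — the generator builds in the study's claimed
  dissociation: multivoxel-decodable, univariately silent. A
  `task_mean_offset` knob deliberately breaks the balance as the
  positive control. `level_delta = 0` leaves levels within a task
  indistinguishable, so within-task contrasts decode at chance.
* **Subjects.** Tuned clusters share their centres across the cohort up
  to a rounded Gaussian displacement with SD 0.05 × ROI radius
  (≈1 mm at full scale — residual inter-subject registration error);
  each subject's effect size is log-normally scaled (SD 0.25).
* **Noise.** AR(1) Gaussian noise (marginal SD 1.6% signal, φ = 0.3)
  plus a slow sinusoidal drift (0.5%, 120–240 s periods, random phase)
  on a baseline of 100. Runs are independent; the drift and
  autocorrelation leak a run-level component into betas, which is what
  makes the alternate-run scheme and the permutation null meaningful.

**Calibration.** The defaults `delta = 0.60`, 12% vitality-preferring,
1% velocity-preferring voxels were fixed once by simulation so that a
16-subject reduced-resolution cohort (scale 0.125) lands its cross-task
insula decoding in the 55–60% band while control ROIs and within-task
contrasts stay at 49–53% and the FDR-surviving group-map voxels
concentrate in the planted vitality cluster with positive sign
dominating. Accuracy grows with ROI size at fixed per-voxel signal, so
the band statement is tied to that cohort scale; the permutation chance
level is calibrated at the full 1533-voxel geometry, where it is
scale-free. The sparser-than-generous tuning fraction (12% rather than
a third of the ROI) is what makes individual weight maps consistent
enough across subjects for overlap maps to recover the cluster — many
weak voxels produce the same accuracy but unrankable weights.

What the generator does *not* emulate: spatially correlated noise,
motion and physiological artifacts, anatomical variability beyond
cluster displacement, surface geometry, or nonlinear HRF variation.
Passing tests therefore demonstrate the correctness and calibration of
the *analysis machinery* under the stated signal model, not claims about
real insular data.

# Kinematics

Stimulus velocity profiles use the minimum-jerk form v(τ) ∝ τ²−2τ³+τ⁴,
scaled so the time integral equals the path length, decomposed into a
gently arched 3-D reach and sampled at 100 Hz at interval midpoints
(discrete mean speed = path length / duration to ~1e-4). Path lengths
for arbitrary execution times interpolate the three calibrated stimuli
(0.636 / 0.570 / 0.532 m at 600 / 1000 / 1400 ms), reproducing the mean
velocities 1.06 / 0.57 / 0.38 m/s. A small seeded smooth perturbation
(2% of peak) differentiates the three objects.

DTW is the classic dynamic program with |aᵢ−bⱼ| local cost and
insert/delete/match steps, returning the unnormalized terminal cost;
the in-row recursion is unrolled into a cumulative-minimum over prefix
sums, so each row is a vectorized O(m) update. Because no normalization
was specified in the procedure this re-implements, a path-length
normalization (divide by n+m) is exposed as an option but off by
default; resampling to common length is deliberately *not* performed —
duration differences are the signal of interest. The 36×36 matrix over
the stimulus set separates duration levels by an order of magnitude
(within-level ≈ 0.7 vs between-level ≈ 16 in the default set), the
basis for pooling objects into per-duration average profiles.

Judgments follow score = clip(a + b·ln t, 1, 5) + noise with per-task
intercepts; the defaults place the velocity curve slightly above the
vitality curve (group means ≈ 2.83 vs 2.66) with a common slope −2.58
and noise SD 0.4 for 18 subjects. The fitted regression of mean score
on ln(execution time) recovers the generating parameters and yields R²
in the 0.9+ range at these settings. Scores are continuous: the
analysis target is the regression on means, and a clipped continuous
scale is the natural simulation of a 5-point scale averaged over
repetitions.

# Scheduling details

Runs start with 12 s of fixation; onsets then advance by 2 s (event) +
jitter. Jitter values come from a balanced multiset of {12, 14, 16} s
permuted per seed rather than iid draws: iid worst cases (49 × 16 s)
overflow the 416-volume run, while the balanced multiset guarantees fit
for every seed and keeps the 14 s mean. Onsets stay on the TR grid, so
the six-volume windows align exactly with acquisition; the ≥12 s gap
means a trial's window never reaches the next trial's onset volume, an
invariant the tests assert for every generated design.

# Problem sizes

Cohort-level analyses (tests and examples) run at scale 0.125 — insulas
of 192 / 168 voxels — where a full 16-subject pipeline takes well under
a minute; per-voxel marginal behavior (chance levels, overlap nulls) is
scale-free and spot-checked at the published 1533-voxel geometry. The
Monte Carlo overlap null uses 300-voxel panels for its agreement checks
with the exact binomial tail.

# Known limitations

* The task–run confound is intrinsic to the emulated design; the
  alternate-run scheme mitigates but cannot remove it, which is why the
  permutation null (not nominal 50%) is the reference.
* The per-voxel independence null for overlap maps is conservative with
  respect to any spatial structure in real selections.
* Group-map recovery depends on cross-subject alignment of the planted
  clusters; beyond ~0.15 × ROI radius of displacement the overlap
  signal washes out — a faithful miniature of why real group maps need
  good spatial normalization.
* The exact Wilcoxon convolution is O(n·Σrank²) and intended for small
  cohorts (n ≤ ~30), ample here.
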