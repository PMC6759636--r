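---
title: "Classifying upper-limb functional primitives from body-worn IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying upper-limb functional primitives from body-worn IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantifying the dose of upper-extremity rehabilitation requires counting
its elementary units: *functional primitives* — reach (move the hand
into contact with a target object), transport (convey the object),
reposition (move the empty hand back toward the object) and idle (stand
at the ready). Trained observers can label primitives from video, but
only slowly and expensively. A practical alternative is to instrument
the patient with body-worn inertial measurement units (IMUs) and train a
classifier to recognize primitives from the motion signals.

`primsense` implements that pipeline end to end for a structured
tabletop task: an object is moved between a centre target and radially
arrayed targets, each move eliciting the sequence idle → reach →
transport → reposition. Eleven sensor sites are modeled (head, sternum,
pelvis, and bilateral scapula, upper arm, forearm and hand), each full
IMU yielding 10 channels — 3 linear accelerations, 3 angular velocities
and a 4-component orientation quaternion — at a configurable sampling
rate.

Because patient recordings of this kind are not publicly available, the
package ships a synthetic-data generator that emulates the study
conditions, so every method in the package can be exercised, tested and
benchmarked under known ground truth.

## Pipeline and model

1. **Normalization.** Each channel is z-scored, $(x - \mu)/\sigma$, with
   population (divide-by-$n$) statistics.
2. **Windowing.** The signal is cut into sliding windows of width 0.25 s
   advancing by 0.1 s. A span of $T$ seconds yields
   $\lfloor (T - w)/s \rfloor + 1$ windows. A window takes the label of
   the primitive segment owning the majority of its samples.
3. **Featurization.** Per channel and window, five statistics: mean,
   standard deviation, minimum, maximum and root mean square
   ($\mathrm{rms} = \sqrt{\overline{x^2}}$). Eleven IMUs × 10 channels ×
   5 statistics = 550 features per window.
4. **Classification.** Four algorithms under one contract:
   * **LDA** — pooled-covariance linear discriminant
     $\delta_k(x) = x^\top \Sigma^{-1}\mu_k -
     \tfrac12 \mu_k^\top \Sigma^{-1}\mu_k + \log \pi_k$;
   * **NBC** — Gaussian naive Bayes with per-class, per-feature means
     and variances, computed in log space;
   * **SVM** — RBF-kernel support vector machine (delegated to libsvm
     via the `e1071` package);
   * **KNN** — k-nearest neighbors with uniform weights.
5. **Evaluation.** Stratified 60/40 splits repeated 10 times (or
   leave-one-subject-out), positive predictive value
   $\mathrm{PPV}_c = 100\,TP_c/(TP_c+FP_c)$ per class one-vs-all, the
   micro-pooled overall PPV, row-percent confusion matrices, and
   one-vs-all ROC curves with trapezoidal AUC.
6. **Sensor search.** An exhaustive wrapper search over all $2^{11}-1$
   site subsets and both sensor types (IMU: 10 channels/site;
   accelerometer: the 3 acceleration channels), every configuration
   evaluated on identical splits.

## Design choices where the procedure was genuinely open

**Unit of splitting.** Overlapping windows from the same primitive are
near-duplicates; splitting at the window level would leak them across
the train/test boundary and inflate performance. Splits are therefore
drawn at the *segment* level: all windows of a primitive travel
together. Stratification keeps each class's segment share within one
segment of the target fraction.

**Primitive-level prediction.** Window predictions within a ground-truth
segment are aggregated by majority vote (ties resolve to the earliest
class in the canonical order reach, transport, reposition, idle),
producing one label per primitive. Headline metrics are primitive-level;
`level = "window"` is available.

**Window labels at boundaries.** A window spanning a boundary takes the
label of the segment owning most of its samples; exact ties go to the
earlier segment. Windows slide across the whole recording, not within
segments, because the window/stride arithmetic implies a continuous
slide.

**Normalization scope.** `zscoreNormalize()` accepts externally supplied
(e.g. training-set) statistics, but the default pipeline normalizes each
recording with its own statistics. Splits are drawn at the segment level
*within* recordings, so training-portion signal statistics would force
re-featurization in every repeat for marginal benefit: LDA and NBC are
exactly invariant to per-feature affine maps, and for the
scale-sensitive KNN and SVM, `evaluatePrimitives()` standardizes the
*features* with training-set statistics inside every split, which is
where leakage could actually matter.

**sd and rms conventions.** Population (divide-by-$n$) normalization for
the standard deviation feature and for z-scoring. The "±" reported
across repeats is the sample (n−1) standard deviation over repeats.

**Quaternions** are treated as four ordinary real channels for
normalization and featurization; their non-Euclidean geometry is
ignored.

**KNN defaults.** $k = 5$, Euclidean distance, uniform weights; vote
ties break by smaller summed neighbor distance, then canonical class
order, making predictions deterministic.

**LDA numerics.** The pooled covariance uses the $n - K$ denominator
plus a ridge $\lambda \,\mathrm{tr}(\Sigma)/p \cdot I$ with
$\lambda = 10^{-6}$ — enough to make the solve stable without visibly
biasing the discriminant; a singular system despite the ridge raises an
error advising a larger $\lambda$.

**SVM scores.** libsvm's probability outputs depend on an internal
randomized cross-validation, which would break the package's
determinism contract. Instead, one-vs-rest machines are fitted alongside
the multiclass machine and their decision values are mapped to $(0,1)$
by a logistic; AUC is invariant to this monotone map. Hard labels always
come from the delegated multiclass prediction. Defaults $C = 1$,
$\gamma = 1/(p \cdot \mathrm{var}(X))$.

**Optimal operating point.** Defined as the threshold maximizing
Youden's $J = \mathrm{TPR} - \mathrm{FPR}$; the distance-to-$(0,1)$
criterion is available via `opCriterion = "closest"`.

**Search objective.** Mean overall (micro) PPV across repeats, subsets
of whole sites only. The best-per-count path is derived from the
exhaustive results rather than by a separate greedy pass. Ties go to the
lexicographically smallest site set. For LDA the search uses a
sufficient-statistics fast path — class means and the pooled
within-class SSCP are computed once per fold on the full feature set,
and each subset solves on the corresponding submatrices — which is
algebraically identical to refitting per subset (verified exactly in the
tests), and turns the 2047-configuration search into minutes of work.

## What the generator emulates — and what it does not

Each virtual subject performs the task protocol with lognormal primitive
durations (mean 1.0 s, CV 0.25, scaled by a per-subject speed factor, so
a primitive spans roughly eight analysis windows). Moving primitives
carry a minimum-jerk acceleration burst: the horizontal components point
along the target direction for all moving classes, while the vertical
component's sign separates transport (object-loaded) from
reach/reposition. Reach additionally carries a biphasic forearm
supination burst on the angular-velocity channels — the grasp-related
wrist motion — which reposition lacks; this is deliberately the *only*
strong cue separating reach from reposition, so discarding gyroscope and
orientation channels (the accelerometer-only condition) measurably hurts
exactly where it hurt with real sensors. Orientation quaternions are
obtained by integrating the clean angular velocity about each site's
fixed rotation axis from identity and renormalizing; noise is added
afterwards. A shared slow postural-sway process (two incommensurate
sinusoids, random phase) is mixed into the acceleration channels of the
seven signal-bearing sites — strongest at the trunk, emulating the
compensatory proximal motion common in hemiparesis — which makes
adjacent-site channels substantially correlated. The non-active arm's
four sites carry pure sensor noise.

Key defaults, chosen once: sensor noise sd 0.22 (channel units),
sway sd 0.7, signal loadings decaying from 1.0 at the active hand to 0.5
at the head, subject speed sd 0.12, gain sd 0.15, loading-jitter sd 0.45
(lognormal). The `separation` dial scales every class-dependent term; at
0 the class-conditional distributions coincide exactly, giving a
null-calibration condition where any classifier's accuracy must fall to
chance. Conditions used by the package's own end-to-end tests:
the correlated-channel condition (sway sd 2.5, noise 0.4) under which
naive Bayes's independence assumption is maximally violated, and the
subject-offset condition (gain sd 0.5, loading-jitter sd 1.3) under
which leave-one-subject-out transfer is clearly harder than stratified
splitting.

For sensor-subset questions the generator also provides
`kinematicClassMoments()`: analytic class moments over the full
550-feature layout in which exactly the seven active-arm/trunk/head
sites carry class-separated means (the four non-active-arm sites have
identical moments across classes), paired with
`simulateFeaturePopulation()` for arbitrarily large moment-matched
Gaussian feature tables. This is the reference condition for verifying
that the exhaustive search recovers the signal-bearing sites: with
recording-level desk-scale data the marginal value of the sixth and
seventh redundant site falls below subset-selection noise, whereas the
population route makes the comparison statistically identifiable at
modest cost.

The generator does **not** emulate: a biomechanical skeleton (sites are
statistical channels, not linked segments), orientation-filter artifacts
or magnetic drift, labeling noise in the ground truth, gaps between
primitives, heavy-tailed or non-stationary sensor noise, or the
between-patient heterogeneity of real impairment. Passing tests
therefore show that the pipeline's *machinery* is correct and that the
documented orderings follow from their stated mechanisms — not that any
particular accuracy level would be attained on real patient data.

## Problem sizes used by the tests

The test-suite conditions are desk-scale by design: 6 virtual subjects ×
48 primitives (1 trial × 6 targets × 2 objects × 4 primitives) at the
60 Hz generator mode, about 2,900 windows × 550 features; the
correlated-channel condition doubles the trial count. The exhaustive
search runs on a 6,000-row moment-matched population with 3 stratified
repeats; the timing harness uses an 800-row, 50-feature grid for all
four algorithms (SVM training is quadratic in $n$) and a 16,000 × 550
grid for the LDA/NBC/KNN comparison, sized so that LDA training is well
above clock resolution when the KNN ratio is asserted. Full-fidelity settings (240 Hz,
5 × 8 × 2 protocol, 10 repeats) are the documented defaults of
`taskProtocol()` and `simulateRecording()`.

## Known limitations

* The SVM is a delegated implementation; its serialization stores
  training data and refits on load rather than exporting libsvm's
  internal state.
* PPV is undefined for a class never predicted; such classes are
  reported as missing rather than zero, and the micro-pooled overall PPV
  (which equals accuracy) is unaffected.
* `timingBenchmark()` measures wall-clock times, which are
  hardware-dependent; only relative statements (scaling shape, KNN's
  near-zero training cost) are meaningful.
* The window-count formula is exact when width and stride are integer
  multiples of the sample period; other combinations are rounded to the
  nearest sample.
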