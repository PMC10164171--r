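---
title: "Methods: simulating and decoding event-file binding in oscillatory EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding event-file binding in oscillatory EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bindecode)
```

# The scientific problem

In a feature-overlap Go/Nogo task, Nogo stimuli either share letter/color
features with the Go stimuli (*overlapping* condition, which forces a
reconfiguration of the stimulus-response binding — the "event file") or do
not (*non-overlapping*). Behaviorally, feature overlap inflates the Nogo
false-alarm rate (the *binding effect*, defined throughout as overlapping
minus non-overlapping). Neurophysiologically, theta-band activity (TBA,
4–7 Hz) is stronger under overlap with a condition-difference peak near
0.52 s after stimulus onset, alpha-band activity (ABA, 8–12 Hz) is weaker
under overlap with a later peak near 0.59 s, and multivariate condition
information is partially shared between the two bands, so that a
classifier trained on theta patterns transfers to alpha patterns.

`bindecode` implements the full analysis chain for this design —
preprocessing, Morlet band power, cluster-based permutation statistics,
LCMV beamforming, MVPA decoding (temporal, temporal generalization,
theta→alpha transfer, per-voxel), DBSCAN localization, and brain-behavior
regression — together with a synthetic-data generator whose ground truth
makes every stage testable without access to recorded EEG.

# The synthetic generator

## What it emulates

* **Task design** (`task_design()`): 196 trials per Go condition, 84 per
  Nogo condition (70:30 Go:Nogo), seven equal blocks with balanced,
  pseudorandomized conditions, 450 ms stimuli, a 1700 ms response window,
  inter-trial intervals jittered uniformly in 700–1100 ms.
* **Behavior** (`simulate_behavior()`): per-subject condition means drawn
  around the study's values (Go hits 99.3 vs 98.7 %, Go RT 439 vs 450 ms,
  Nogo false alarms 2.2 % non-overlapping; overlapping = 2.2 % plus the
  configured binding effect, 35.3 points by default), with the study's
  between-subject spreads, values clipped to their valid ranges. The
  overlap false-alarm SD is scaled with the planted binding effect
  (17.1 points at the full effect, 3.0 at zero): rates near the floor
  cannot vary as widely as mid-range rates, and a fixed wide SD would bias
  the clipped mean of a null effect upward.
* **Sensor EEG** (`simulate_subject_eeg()`): 60-channel/256 Hz full scale,
  20-channel scaled default, channels on an upper spherical cap, epochs
  of [-1, 1.75) s by default. Sources project through a configurable lead
  field: a current-dipole-in-homogeneous-conductor forward model (gain
  decays with sensor-source distance; a spherical boundary correction
  would only rescale the synthetic SNR and is omitted) or a seeded random
  full-rank gain for fast unit tests. Source orientations are radial and
  fixed, so all subjects share the generative geometry.

## The planted effects

Each frequency band carries an ongoing band-center oscillation
(theta 5.5 Hz, alpha 10 Hz, amplitude `base_amp`, default 10 source
units ≈ 10 µV at the sensors after gain normalization) at the effect
voxels. Per trial, a Gaussian amplitude envelope (SD 0.15 s) centered at
the subject's peak latency adds `± effect_amplitude/2` depending on the
condition, with the sign pattern of the study: theta higher under
overlap, alpha lower. Subject peak latencies are drawn as
theta ~ N(0.52 s, 0.16 s) with the alpha peak trailing by a
truncated-positive lag of mean 0.07 s, so theta precedes alpha within
every subject — the group ordering is then a property of the generative
model rather than a sampling accident. Oscillation phase is drawn per
trial; the voxels of one effect blob share the trial's phase (a locally
coherent cortical patch). This coherence matters: with independent
per-voxel phases the LCMV reconstruction of the incoherent mixture peaks
just *outside* the patch and per-voxel decoding systematically
mislocalizes; a coherent patch is both the physiologically standard
assumption and the configuration under which localization is
recoverable.

## The shared cross-band pattern

The study's three requirements — theta power higher under overlap, alpha
power lower under overlap, and *positive* theta→alpha decoding transfer —
cannot all be produced by a single spatial pattern: if the alpha
condition-difference vector were exactly the sign-flipped theta vector, a
classifier trained on theta would necessarily transfer *below* chance.
The generator therefore separates the two phenomena:

* band-specific **mean-power effects** with opposite signs (above), which
  drive the sensor-level statistics and the peak latencies; and
* a **zero-mean, mixed-sign spatial pattern** over `shared_voxels`, whose
  condition modulation has the *same* sign in both bands. Because the
  pattern sums to zero over voxels it leaves band-mean power untouched,
  but it carries linearly decodable condition information that transfers
  from theta to alpha. With `shared_pattern = FALSE` the two bands get
  orthogonal patterns and transfer collapses to chance.

This is the package's resolution of an under-determined corner of the
design; the simulated transfer (`transfer_experiment()`) behaves exactly
like the study's: above-chance matched-time transfer when the pattern is
shared, chance when not.

## What the generator does not emulate

No realistic anatomy (template head models, AAL parcellation — the
synthetic atlas assigns octant-based region names and marks a cerebellar
slab plus a random unlabeled fraction purely for exclusion logic), no
ocular/muscular artifacts (hence no ICA stage), no 1/f background
spectrum (sensor noise is white), no trial-history effects. Passing
recovery tests therefore demonstrates that the *analysis chain* is
correct and calibrated, not that it would be robust to every property of
recorded EEG.

# Preprocessing

Fixed order: zero-phase 4th-order Butterworth band-pass (0.5–40 Hz) with
a zero-phase band-stop at 50 ± 5 Hz; polyphase resampling (500 → 256 Hz
for real recordings; synthetic data is generated at the target rate);
common-average reference; selection of correctly rejected Nogo trials (no
response before 1500 ms) with artifact rejection (±200 µV amplitude
limit; peak-to-peak below 0.5 µV within any sliding 100 ms window); and
baseline correction over -200–0 ms. The forward-backward IIR realization
is chosen so filtering cannot shift the latencies that the peak analysis
later compares; the filter order is a documented free choice. The
flat-signal rule is interpreted as a peak-to-peak range criterion within
a sliding window, the standard flat-channel semantics.

# Time-frequency analysis

Complex Morlet wavelets with a fixed number of cycles m = 5 (the "Morlet
parameter"), temporal SD `m/(2*pi*f)`, unit-energy normalization,
FFT-based convolution, power as squared magnitude. Samples within three
temporal SDs of an epoch edge are set to `NA` and excluded from all
downstream statistics; epochs must therefore extend ~0.6 s beyond the
analysis window at 4 Hz. Band power averages the bins whose centers fall
inside the band, inclusive (theta 4–7 Hz; alpha 8–12 Hz; the full-scale
source decomposition uses 2–15 Hz in 0.5 Hz steps = 27 bins; the scaled
pipeline decomposes only the band bins it needs, in 1 Hz steps, and
decimates the power time course — problem-size choices, not analysis
changes). Peak latencies are the largest *local* maximum of the
cluster-averaged, sign-aligned condition-difference course in 0–1 s;
courses without an interior maximum return the window argmax with a
boundary flag.

# Cluster-based permutation statistics

Element statistics are paired t values (condition contrasts) or signed
Wilcoxon rank sums against a reference (AUC vs 0.5). Supra-threshold
(p < 0.05) elements of equal sign are joined over spatial adjacency ×
temporal contiguity; channel-domain clusters must contain at least two
distinct adjacent channel pairs at some time sample; the cluster
statistic is the sum of its element statistics. Significance comes from
the permutation distribution of the maximal same-sign cluster statistic
under subject-level sign flips, `p = 2 (1 + #{max >= observed}) /
(n_permutations + 1)`, capped at 1 — with 1000 draws the attainable floor
is 0.002, matching the convention of the study's reported cluster
p-values. Positive and negative clusters are searched separately.

Channel adjacency is distance-thresholded (neighbors within 1.5 × the
median nearest-neighbor spacing) — on the regular synthetic montages this
coincides with a capped triangulation, without requiring a
computational-geometry dependency. Voxel adjacency is 6-connectivity on
the grid; the train-time axis of a generalization matrix uses chain
adjacency. An `exact = TRUE` mode enumerates all `2^n` sign patterns for
oracle comparisons.

# LCMV beamforming

The spatial filter per voxel is `w = C_r^{-1} l / (l' C_r^{-1} l)` with
`C_r = C + 0.05 * mean(diag(C)) * I` (5 % diagonal loading — the
regularization is a documented choice, configurable), `C` the channel
covariance of the trial-averaged data over the whole epoch, and `l` the
lead field along the max-power orientation (principal eigenvector of
`(L' C_r^{-1} L)^{-1}`; orientation handling is not specified by the
source methods and the scalar max-power beamformer is the field's
default). Unit gain `w'l = 1` holds by construction and is asserted in
the tests. One common filter per subject is computed from all Nogo trials
and applied to both conditions, avoiding condition-specific filter bias;
condition-specific covariance windows are available through the same
functions. Unlabeled and cerebellar voxels are excluded from source
analysis (full-scale reference counts: 1254 of 2020 voxels; the synthetic
atlas reproduces the *mechanism*, not those numbers).

# Decoding

The classifier is a linear support vector machine (cost parameter 1 by
default) with continuous decision values; performance is the rank-based
AUC of the decision values pooled over the held-out folds of a stratified
5-fold cross-validation. Fold assignment is fixed per trial before any
feature extraction, features are z-scored with training-fold statistics
only, and a label-independent noise feature decodes at chance in the test
suite (leakage canary). Temporal MVPA uses the voxel pattern per time
sample; temporal generalization trains at each time and tests at all
times within the same folds; the cross-band transfer trains on theta
features and tests the *held-out* trials on alpha features; the spatial
MVPA uses the significant time samples of the band-power course as the
feature vector of each voxel, yielding one AUC per voxel. Voxel maps are
re-inserted into the full grid with zeros at excluded positions, paired
with a chance map (0.5 at included, 0 at excluded positions). The
generalization "duration around the diagonal" is defined as the mean, over
train times, of the contiguous significant test-time run containing the
diagonal element (0 where the diagonal is not significant) — the
contiguous-run reading of an otherwise unspecified summary.

# DBSCAN localization

The top 2 % of AUC values over *included* voxels (ties at the threshold
kept; excluded voxels carry re-inserted zeros and would distort a
whole-grid quantile) are clustered with DBSCAN, Euclidean metric,
`eps = 1.5 ×` grid spacing, `min_pts = 2` ("at least one neighbor") —
under which DBSCAN provably equals the connected components of the
eps-neighborhood graph with singletons as noise; the test suite asserts
this equivalence against an independent graph implementation. Summaries
report member counts, mean AUC, centroid and atlas labels per cluster.

# Behavioral and brain-behavior statistics

Wilcoxon signed-rank tests drop zero differences and use midranks; p is
exact (signed-rank distribution) for tie-free n ≤ 25, otherwise the
normal approximation with tie-corrected variance. The normal deviate
follows the SPSS convention — computed from the smaller rank sum without
continuity correction, hence always ≤ 0 — because the published effect
sizes (`r = Z/sqrt(n)`, Rosenthal, with n = number of pairs) reproduce
exactly under that convention: a maximal effect over 79 pairs gives
`Z = -1580/204.62 = -7.72` and `r = -0.869`. Backward elimination starts
from the full linear model and repeatedly removes the predictor whose
partial F-test (equivalently, coefficient t-test) is least significant,
stopping when every remaining predictor's removal would change R² at
p < 0.10 (the SPSS default criterion); reported diagnostics are
standardized coefficients, adjusted R², the overall F, the Durbin-Watson
statistic, variance inflation factors at every step, and the extreme
standardized residuals. Perfectly collinear predictors are an error named
after the offending columns.

# Pipeline, seeds and problem sizes

`run_pipeline()` executes simulate → preprocess → sensor statistics →
beamform → source band power → decode (theta, alpha, theta→alpha) →
DBSCAN → regression, writing one artifact per stage plus a JSON manifest
of parameters, seeds and artifact hashes. A master seed fans out to
per-stage (and per-subject) seeds through a fixed affine map, so re-runs
are byte-identical and any stage can be reproduced in isolation;
artifacts are plain `.rds` files in the user's run directory.

The validation suite runs on deliberately scaled-down geometry chosen
once as this package's study conditions: 15 subjects × 20 channels for
calibration and sensor recovery, a 5×5×5–6×6×6 voxel grid at 1 cm,
8–40 Nogo trials per condition, 128–256 Hz sampling, 150–500
permutations, and high-SNR settings (`effect_amplitude` 15–20 against
`noise_sd` 3–5) where ground-truth recovery is the claim under test. The
null-calibration experiment uses 200 Monte-Carlo repetitions of a
15-subject group with `effect_amplitude = 0`, under which the two
conditions are exchangeable by construction.

# Known limitations

* The forward model is a homogeneous-conductor dipole approximation on a
  synthetic montage; absolute gain scales and localization accuracy do
  not transfer to real head geometry.
* Spectral leakage is real: a 5.5 Hz effect leaks ~2 % of its power into
  the 8–12 Hz average. The transfer experiments therefore plant the
  shared pattern with `effect_amplitude = 0`, isolating the transfer
  claim from leakage.
* The Wilcoxon element threshold is attainable only for n ≥ 6 subjects
  (the two-sided exact p of a maximal effect at n = 5 is 0.0625), so
  group decoding tests need at least six subjects.
* Backward elimination reproduces the partial-F stopping rule, not any
  particular software's tie-breaking; exact agreement with other
  implementations is not claimed.
* `report_run()` only reads artifacts; deleting an artifact requires
  re-running the pipeline (stages are cheap and deterministic, so no
  partial-recompute cache is kept).
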