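---
title: "Digital assessment of dog coping styles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital assessment of dog coping styles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In a Stranger Test, a dog is released into a fenced 4.7 x 4.7 m arena in
which an unfamiliar test person (TP) sits motionless at the center while a
familiar person waits in a corner. Behavior experts watch the ~40 s test
phase and score the dog's *coping style* on a five-point scale from -2 to
+2: positive scores for reacting *towards* the stressor (approaching,
jumping up), negative for reacting *away* (avoiding, keeping distance),
zero for neutral, stable coping. For analysis the scale is collapsed by
sign into three classes ('-', '0', '+') and the three raters' scores are
aggregated by majority vote.

`caninecoping` implements a human-free counterpart to that scoring: from
per-frame dog/person detections in overhead video it builds standardized
trajectories, embeds them in a learned "movement space", clusters dogs
into coping profiles without supervision, validates the clusters against
expert scores and owner-reported C-BARQ categories, and finally trains
supervised models that predict the expert label and the C-BARQ scores
directly from the movement representation.

Because the original video cohort is not publicly available, the package
ships a synthetic cohort generator that reproduces the *statistical
structure* the analysis assumes. Every stage is exercised and tested on
generated data; the acceptance checks compare only against quantities
whose inputs are printed (agreement counts, exclusion counts) or against
simulation targets at the reference sample sizes and class balance.

# The synthetic cohort generator

## Motion model

The dog's center of mass follows a discrete-time Ornstein-Uhlenbeck-like
walk at `fps = 24`:

$$x_{t+1} = x_t + a\,(m(x_t) - x_t)\,\Delta t + w(x_t)\,\Delta t +
  \sigma \sqrt{\Delta t}\;\epsilon_t,$$

where the set point $m(x)$ lies on the ray from the TP through the dog at
the style's preferred TP distance, $w$ is a soft wall repulsion active
within 0.25 m of the fence, walls reflect, and $\epsilon_t$ is standard
2-D Gaussian noise. The person path is constant at the arena center. All
dogs enter at the gate (middle of the front fence).

The style parameters are calibration knobs, not estimates of the real
cohort (no distributional facts about the real dogs' motion are
published). The defaults are:

| style   | $a$ (1/s) | $\sigma$ (m/$\sqrt{s}$) | preferred TP distance (m) |
|---------|-----------|--------------------------|---------------------------|
| towards | 2.0       | 0.35                     | 0.4                       |
| neutral | 0.25      | 0.12                     | 1.5                       |
| away    | 1.2       | 0.18                     | 3.1                       |

They encode the scoring rubric's qualitative picture: *towards* dogs move
fast and hold a short distance to the stranger; *neutral* dogs are
low-energy, drifting slowly from the entry region towards a moderate
distance ("slowly approaching ... then moving on exploring"); *away* dogs
retreat quickly to the fence. An earlier calibration in which neutral dogs
actively patrolled a 1.5 m ring at ~1.4 m/s was rejected: each trial then
parked at a persistent random ring angle, which is neither realistic for a
relaxed dog nor compatible with the generator's contract that the default
cohort contains exactly two recoverable movement profiles. Under the
defaults, mean TP distance orders towards < neutral < away in at least
95 of 100 seeds, and increasing the towards attraction strictly decreases
its mean TP distance (sign test, p < 0.01).

Durations are jittered uniformly by ±2 s around 40 s so that the
shortest-duration truncation downstream is always exercised.

## Detections, ratings, C-BARQ

Detections emulate an imperfect object detector: each frame independently
loses each object with probability `miss_rate` (default 0.05; 0.35 for
deliberately under-tracked trials used to exercise the quality gate) and
detected centers get isotropic Gaussian noise (`noise_sd` = 0.02 m).
Coordinates are generated in meters with an identity calibration; a pixel
cohort only rescales.

Ratings are generated directly on the collapsed three-class scale: a trial
is unanimous with probability `unanimity_fraction` (default 0.76, the
empirical fraction in a 38-of-50 breakdown), otherwise one randomly chosen
rater moves to an ordinally adjacent category, so the majority always
equals the true style. The -2..+2 to sign collapse is handled separately
for real rating tables by `collapse_and_vote()`.

Each of the 8 C-BARQ categories (SDA, ODA, SDF, NSF, SRB, ASB, EXC, PS) is
a clipped-to-[0,4] linear function of the style indicator and two activity
covariates (mean speed in m/s; fraction of frames within 1 m of the TP)
plus Gaussian noise. Stranger-directed fear is coupled to style and
calibrated so neutral trials have median 0.00 and towards trials 0.42;
excitability is coupled to the activity covariates with noise sd 0.1;
the other categories are only weakly coupled (noise sd 0.3). The clipping
means the noiseless limit is exactly linear only while scores stay inside
(0, 4), which the default covariate ranges guarantee.

What the generator does **not** emulate: the TP's three scripted actions
as time-locked stimuli, multi-dog or side-view footage, posture and
body-language cues, and any within-trial change of coping style. Passing
tests therefore show that the pipeline recovers structure of this kind
when present; they do not certify performance on real video.

# Trajectory preprocessing

The post-detection chain is: quality gate, gap filling, smoothing,
frame-rate standardization, shortest-duration truncation.

* **Quality gate.** Joint coverage is the fraction of frames with *both*
  objects detected; trials below 0.80 are excluded ("at least 80%" read
  inclusively, so a coverage of exactly 0.80 is retained).
* **Gap filling.** Interior gaps are linearly interpolated between the
  flanking detections. Leading/trailing gaps hold the nearest detected
  value: slope extrapolation can exit the arena, clamping cannot. A
  centered moving average of width 5 frames (edges shrunk) then smooths
  the completed track; width 1 disables smoothing and preserves observed
  points exactly. A trial with no gaps is returned untouched, which makes
  the operation idempotent. Post-fill coverage is 1.0 by construction,
  clearing the "above 95%" requirement.
* **Resampling.** Linear interpolation at the 24 fps timestamps; the
  output frame count is `floor((n-1)/fps * 24) + 1`, so the last target
  timestamp never leaves the sampled range (no extrapolation) and the
  duration is preserved to within one frame period.
* **Truncation.** All trials are cut to the shortest trial's frame count,
  anchored at the trial start (the test phase begins at entry; the tail is
  the most variable part). The dataset is the n x (4 m) matrix of
  time-major frames with channels (dog_x, dog_y, person_x, person_y).

Smoothing operates on calibrated coordinates (meters); with an identity
calibration this is also pixel-space smoothing, so the pixel-vs-meter question is immaterial here.

# The movement-space autoencoder

The encoder is fixed: 1-D convolution (window 3, same padding, ReLU),
dropout p = 0.1, max-pooling (window 2). The decoder mirrors it: upsample
by repetition, window-3 convolution back to 4 channels, linear output.
Training minimizes mean absolute reconstruction error with Adam;
hyperparameters come from a grid search selected on validation MAE
(25% of trials held out, split by trial). Odd input lengths drop the last
frame internally so pooling and upsampling mirror exactly. The movement
embedding of a trial is the flattened pooled feature map:
`floor(m/2) * n_filters` values.

Choices the architecture sketch leaves open, and what this package does:

* **Nonlinearity, padding, decoder form**: ReLU, same padding, stride 1,
  upsample-by-repeat — the minimal reading of a mirrored architecture.
* **Channels**: the dog and person series are embedded jointly as a
  4-channel input, since the per-trial sample is defined as the
  concatenation of both series.
* **Standardization**: channels are centered individually but scaled by a
  *single pooled* standard deviation. Per-channel z-scoring was tried and
  rejected: the person sits still, so that channel's sd is just the 2 cm
  detection noise, and dividing by it amplifies pure noise ~80-fold until
  it dominates every embedding distance. Pooled scaling preserves the
  common metric geometry of the four coordinate channels.
* **Default grid**: `n_filters` in {4, 8}, learning rate 1e-3, batch size
  8, up to 150 epochs with early stopping (patience 15). On cohorts of
  ~46 trials the validation MAE plateaus well before 150 epochs and wider
  grids (16 filters, lr 1e-4) never won while tripling cost; the grid is
  an argument, so a larger search is one call away.
* **Determinism**: weight init, the train/validation split, batch order
  and dropout masks all derive from the one training seed; identical
  configurations reproduce identical weights.

# Clustering

On fixed-length, time-aligned embedding vectors, time-series k-means
reduces to ordinary Euclidean k-means — no warping is needed when every
series shares the clock — so the package implements Lloyd's algorithm
with k-means++ seeding, best of 10 restarts. Assignment ties break to the
lowest cluster index; a cluster emptied during an update is re-seeded at
the farthest point. Tests verify the implementation against both
`stats::kmeans` and an exhaustive-partition oracle at small n.

The number of clusters is chosen by the elbow rule, implemented as the
kneedle-style maximum perpendicular distance to the chord of the
min-max-normalized inertia curve over k = 1..8; an exactly linear curve
(no elbow) returns k = 1. The detector is invariant under affine
rescaling of the inertia axis.

Before clustering, an outlier screen excludes trials whose embedding
distance to the cohort medoid exceeds median + 3.5 MAD (a single pass).
A single extreme trial is a typical finding at this cohort size; the
MAD rule makes the screen explicit, and exclusions are reported per run.

The 2-D cluster maps use an exact (dense) t-SNE implemented in the
package (no lighter implementation was available in the target
environment), with perplexity `min(30, (n-1)/3)`, a seeded layout, and
min-max normalization of each axis to [0, 1]. It is used for
visualization only; no downstream quantity depends on it.

# Agreement and cluster-validation statistics

Observed agreement is the Fleiss-style pairwise statistic: the mean over
subjects of the fraction of agreeing rater pairs. Chance correction uses
the free-marginal (Randolph) multirater kappa, $(P_o - 1/c)/(1 - 1/c)$
with $c = 3$ categories; this pairing is internally consistent with a
panel of 53 subjects, 41 unanimous and 12 split 2:1, which yields
$P_o = 45/53 \approx 0.849$ and $\kappa = 0.77$ — and that consistency
only holds if the three negative-scored dogs were rated unanimously,
which is therefore assumed in the worked panel.

Cluster differences in each C-BARQ category use the Mann-Whitney U test
with midranks for ties, the min-side U, and a tie-corrected normal
approximation *with* continuity correction. The continuity correction is
a deliberate deviation from reproducing the uncorrected reporting style:
exhaustively enumerating every tie-free arrangement at $n_1 = n_2 = 6$
shows the uncorrected normal tail strays up to 0.069 from the exact null
mid-range, while the corrected one stays within 0.016 — and the package's
own contract demands agreement within 0.02. For $n_1 + n_2 \le 12$ the
exact two-sided p-value is also computed by complete enumeration and used
as the oracle in tests. Raw p-values are reported across the 8 categories
(raw p-values stay primary for this small fixed panel); a
Holm-adjusted column is emitted alongside, clearly
labeled as an extension. Three-way vote ties are flagged and excluded,
never imputed; '-'-labeled trials are excluded from the supervised stages
by default (`include_negative` re-includes them).

# Supervised models

The automated-ML step is a budgeted evolutionary search in the spirit of
TPOT (population 20, tournament selection, uniform crossover, per-gene
mutation 0.3, steady-state replacement, elitism by construction) over
pipelines of the form optional z-scaler, optional variance or univariate
feature selector (top 8/16/32/64 features), and an estimator from
elastic-net GLM, random forest, k-NN, or RBF-kernel SVM with small
hyperparameter ranges. The budget caps *distinct* pipelines evaluated
(default cap 10,000; the analyses here use 200); duplicates hit a cache.
Fitness is the stratified 5-fold cross-validated score — accuracy for
classification, negative MSE for regression; regression folds stratify on
response-ordered bins. Reported metrics (accuracy / macro precision /
macro recall / macro F1; MAE / MSE / R²) come from the winner's pooled
out-of-fold predictions. Macro averaging is the package's choice for the
two-class problem (micro would duplicate accuracy). Features default to
the flattened movement embeddings; any row-aligned matrix (e.g. the raw
standardized trajectories) can be passed instead. Cluster assignment is deliberately not
used as a feature, keeping the supervised task independent of the
unsupervised one.

# Problem sizes and numerical choices

Cohort-scale computations use the full-scale default (46 trials of ~40 s
at 24 fps; embedding dimension `floor(m/2) * n_filters` ≈ 3,650).
Property suites that repeat the full generate-embed-cluster chain over 20
seeds run on reduced cohorts (20 dogs, 15 s trials) — chosen so that a
single misassigned dog cannot push the adjusted Rand index below the 0.6
recovery bound the property asserts, which at very small n it
artifactually can. Elbow selection is validated over 5 full-scale seeds.
Degenerate inputs are handled explicitly: empty clusters re-seed, an
all-tied Mann-Whitney returns z = 0 and p = 1, zero-variance targets
report R² as missing with a warning, and a constant embedding cloud
yields no outliers.

# Known limitations

* The generator's effect sizes are calibrated, not estimated; absolute
  classifier/regressor performance on synthetic cohorts is therefore an
  upper bound scenario relative to real video, where style separation is
  weaker and detection failure is not frame-independent.
* The autoencoder is trained full-cohort (train/validation split by
  trial); embeddings of validation trials are
  still produced by a model that saw the other trials, so the supervised
  cross-validation is conditional on the learned representation.
* The elbow detector, outlier rule, and agreement definition each admit
  several common variants; the package's choices are documented above
  and are the ones under test.
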