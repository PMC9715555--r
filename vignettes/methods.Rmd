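---
title: "Methods: behavioral coupling, population manifolds, and cross-subject decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral coupling, population manifolds, and cross-subject decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`crossdecode` analyses chronic multi-electrode recordings from freely moving
animals whose behavior has been labeled into six classes (step, turn, drink,
groom, rear, rest) in 500 ms snippets, together with paw velocity traces on a
10 ms grid. The pipeline has four stages: single-unit behavioral coupling
(STAPSSS), non-linear low-dimensional embedding of binarized population
activity (Laplacian eigenmaps, with landmark Isomap and PCA alternatives),
cross-session polytope similarity statistics, and cross-session /
cross-subject decoding via Procrustes alignment of the embedded manifolds.
A synthetic multi-subject session generator with known ground truth drives
calibration and validation of every stage.

# Single-unit coupling (STAPSSS)

For a unit and a paw, the spike-triggered average paw swing–stance status is
the mean of the paw's binary swing/stance trace in windows of ±1 s (201 bins
of 10 ms) around every spike, normalized by the waveform mean. Swing is a
horizontal speed strictly above 0.3 mm per 10 ms; values equal to the
threshold count as stance. Spikes are binned at 10 ms and a bin with k
spikes contributes k windows; windows clipped by the recording edges are
excluded, because zero-padding them would bias the waveform mean.

Significance uses a shift bootstrap: the spike train is rotated circularly
by 1000 uniform offsets at least 1 s away from zero, the waveform standard
deviation is recomputed for each rotation, and the observed standard
deviation is compared with the empirical 0.99 quantile (type-7 convention,
so the threshold is exactly reproducible) of the null standard deviations.
Rotation preserves both marginals and the autocorrelation of the series, so
autocorrelated paw movement alone cannot create spurious coupling. The
coupling ratio is `c = sd(waveform) / q99(null sds)`; `c > 1` flags a
significant unit. Numerically, the null is computed from one circular
cross-correlation of the full spike and status series (FFT), of which every
rotated waveform is a 201-sample slice; for the rotated surrogates the
series is therefore treated as circular (windows wrap at the recording
edge). The discrepancy with the edge-excluding observed waveform is at most
200 bins out of a session's ~10^5 and the 1% type-I level is verified by
simulation in the test suite.

The contralateral bias of a unit is `b = c_right / c_left` for
left-hemisphere units and `b = c_left / c_right` for right-hemisphere
units, computed separately for front and hind paw pairs; the peak offset is
the signed lag (ties toward zero) of the waveform's largest deviation from
1, negative when the movement peak precedes the spike.

Behavioral selectivity per unit uses one-sided Wilcoxon rank-sum tests of
the 500 ms spike counts in each class against the remainder of the session,
Benjamini–Hochberg corrected across the six classes. The balanced
Kruskal–Wallis analysis subsamples every class to the smallest class size,
repeats the test 100 times, and counts significant pairwise post-hoc
comparisons (two-sided rank-sum at the same 0.05 level, uncorrected) only
when the main effect is significant, so class imbalance cannot drive the
post-hoc counts.

# Population embedding

Spike counts of all units (single and multi) are binned at 100 ms and
binarized; only time points with at least 15 active units are retained
(sessions with fewer than 5000 retained points are flagged and can still be
processed at reduced scale). An unweighted mutual k-nearest-neighbor graph
is built on the binary population vectors with the Hamming distance and
k equal to 0.5% of the time points (round-half-away-from-zero, floor 1):
an edge exists iff each point is among the other's k nearest. Binary data
make exact distance ties ubiquitous; ties are broken by a fixed
multiplicative-hash ordering of the indices, which is deterministic and
platform-independent but avoids the systematic bias toward temporally early
neighbors that breaking ties by ascending index would create (we measured
61% of neighbors falling in the first half of a session under index
tie-breaking).

The embedding solves the generalized eigenvalue problem `L v = λ D v`
(random-walk normalized Laplacian) restricted to the graph's largest
connected component — mutual kNN graphs can disconnect, and dropped time
points are recorded and excluded from all downstream label joins. For
solver stability the problem is transformed to the symmetric matrix
`D^{-1/2} W D^{-1/2}`, whose top eigenpairs are found with ARPACK (dense
eigendecomposition below 400 nodes; the ARPACK starting vector is seeded so
identical graphs give bit-identical results). Eigenvectors are
back-transformed, unit-normalized, ordered by ascending eigenvalue, and the
constant zero-eigenvalue mode is discarded. The sign of each eigenvector is
fixed by making its largest-magnitude entry positive.

Two iterations are performed: the first with the Hamming metric and 0.5%
neighbors reduces to 20 dimensions; the second rebuilds a mutual kNN graph
on the iteration-1 coordinates with the Euclidean metric and 7.5%
neighbors and embeds again. The second-iteration metric is a configurable
default: the first iteration's metric is tied to binary data, the second
operates on real-valued coordinates where Euclidean distance is the natural
choice. Whether "two iterations" should instead re-weight the original
graph is genuinely open; rebuilding the graph from iteration-1 coordinates
is implemented because it is the variant that makes the second neighbor
fraction meaningful.

Controls: `time_shuffle` permutes time points globally, `neuron_shuffle`
permutes each unit's time series independently, `time_shift` rotates each
unit circularly by an independent offset. All three destroy the
behavior-locked population structure while preserving the documented
marginals, and embeddings of control-transformed matrices must decode at
chance — this is tested.

Intrinsic dimensionality is estimated from neighborhood growth: the mean
number of neighbors within log-spaced radii, the local slope of
log(neighbors) versus log(radius) over sliding 5-point windows, and the
maximum slope. The search is restricted to the small-radius growth regime
(mean neighbor counts between 2 and n/20): beyond it, closure and
saturation of the manifold distort the slope (on a flat 2-torus the
unrestricted maximum overshoots to ≈2.7; restricted, the estimator recovers
2.0). Known 1-D and 2-D manifolds embedded in 20 dimensions are recovered
within ±0.5 in the test suite.

Landmark Isomap (10% landmarks, 0.5% neighbors, union-symmetrized weighted
kNN graph, geodesics via shortest paths, landmark MDS with Nyström
triangulation) and PCA on the non-binarized counts (same time-point filter)
provide the comparison embeddings.

# Polytope similarity across sessions

The polytope of a session is the set of six class-mean population vectors
(in recording space or an embedded space). Two statistics compare sessions:

* **Rank concordance.** For each class i, the other classes are ranked by
  distance from i in each session; `s_i` counts classes occupying equal
  ranks (0–5). The exhaustive null enumerates all 5! = 120 permutations of
  the non-reference ranks and all 7260 unordered permutation pairs
  (including self-pairs); observed and null distributions are compared with
  a two-sample, two-sided Kolmogorov–Smirnov test. Distance-rank ties are
  broken by the canonical class order for determinism.
* **Jeffries–Matusita.** Session w's class means are Procrustes-rescaled
  onto session v's (translation, scaling, rotation, reflection), and
  `d_JM = sqrt(Σ_ij (sqrt(D^v_ij) − sqrt(D^w_ij))²)` over all ordered class
  pairs compares the distance matrices; the square root damps outlying
  distances. The null recomputes `d_JM` (including the Procrustes refit)
  under every permutation of w's class labels — 720 for six classes, 120
  with rest excluded — and the one-sided p-value is the fraction of null
  values at or below the observed one. The identity permutation is
  included, so the smallest attainable p is 1/720 and the null p-values are
  exactly uniform on the 1/720 grid (tested). Because Procrustes maps the
  second session onto the first, the statistic is directional; this is
  deliberate and tested.

The somatotopy control rebuilds each session's class-mean vectors with unit
identities shuffled within somatotopic regions, independently per class:
region-level mean activity per class survives, unit-level coding does not.
The analysis is repeated for many shuffles (default 500) and the average
p-value reported. Single-unit regions make the shuffle the identity there
and are logged.

# Decoding

**Swing–stance (within session).** Features are every unit's
Gaussian-smoothed (σ = 20 ms) 10 ms spike counts in ±400 ms windows — 81
bins per unit. The classifier is a fully connected feed-forward network
(ReLU, softmax, class-weighted cross-entropy with weights inverse to class
frequency, inverted dropout, L2 weight decay, Adam with batch 64, early
stopping on validation balanced accuracy with patience 10) implemented in
the package: no installed R package offers multi-layer networks with
dropout and per-class loss weights. A ridge logistic regression with
three-fold cross-validation of the regularization strength (glmnet) on the
concatenated training and validation sets is the linear baseline. Splits
are stratified 70/15/15.

**Six classes (within session).** Inputs are the first 10 embedding
dimensions in seven consecutive 100 ms bins centered on each labeled
snippet (the snippet's five bins plus one flank on each side; the centering
is a package choice). Bins removed by the activity filter are imputed from
the nearest retained bin inside the window, and snippets with fewer than
three retained bins are dropped — without imputation, low-activity classes
(rest above all) would be silently excluded. Features are min–max
normalized with statistics from the training folds only. The data is split
into four equal parts; four runs rotate 2 train / 1 validation / 1 test,
and the mean over the four test folds is reported. All reported accuracies
are mean per-class (balanced) accuracies: the unweighted mean of the
per-class recalls.

**Cross-session / cross-subject.** The six classes are split into disjoint
alignment and decoding sets (15 splits with four alignment classes, 20 with
three). Both embeddings are min–max normalized to [0, 1] per dimension and
restricted to four dimensions to avoid an underdetermined fit; a
least-squares Procrustes transform (vegan; translation, scaling, orthogonal
matrix including reflection) maps the test session's alignment-class means
onto the training session's. Decoding-set samples are never touched while
fitting the transform — the result carries an audit of the index sets, and
a test asserts their disjointness. An RBF-kernel SVM (kernel scale 1 on the
normalized coordinates, one-vs-one) is trained on class-balanced
decoding-set samples of the training session and tested on the aligned
decoding-set samples of the test session; 20 Monte-Carlo repetitions
resample the balanced training subsets (the alignment means are not
resampled). The generalization accuracy of a session is its row mean in the
train × test matrix; variants including and excluding the diagonal are both
reported. Ablation harnesses re-embed sessions after removing k random
units (dimension 20 for k ≤ 40, else 10) or all units of one area plus
random padding so each condition removes `max(#M2, #M1, #S1)` units
(dimension 10).

# The synthetic generator

Real recordings provide no generative model, so every distributional choice
below is a synthetic stand-in, chosen once to emulate the statistical
structure the analysis assumes and then frozen. The generator's role is
calibration (do nulls hold?) and planted-signal recovery (is real structure
found?), not biological realism.

* **Behavior track.** A semi-Markov chain on the 500 ms snippet grid with
  geometric dwell times (defaults 1.5–4 s per class) and transition
  probabilities constructed so the stationary distribution equals the
  configured class weights exactly (defaults give the strong imbalance of
  spontaneous behavior: rest 30%, step 25%, turn 15%, drink/groom/rear
  10% each).
* **Gait.** Each paw swings once per gait cycle (1.22 cycles/s, the
  observed mean step rate) with class-specific swing duty (0.35 for
  stepping front paws, 0 at rest). Paw phases advance with independent,
  slowly drifting speeds so limbs desynchronize over seconds — with
  deterministic anti-phase gaits, a unit driven by one paw would be equally
  coupled to every paw and contralateral bias could not exist.
* **Class archetypes.** The six class archetypes form a regular simplex
  with geometrically decaying axis weights (ratio 0.7) after a seeded
  rotation — a conserved, anisotropic class geometry in which some class
  pairs are near and others far, as in real repertoires — normalized so the
  mean pairwise distance equals `archetype_separation` (default 3.5). The
  simplex is embedded orthogonally to the all-ones latent direction:
  because unit mixing vectors sum to one, archetypes are then pure activity
  *contrasts* and class identity is carried by which units co-activate, not
  by the population rate. Without this, the shared mean-mixing direction
  creates a class-level rate signature that survives the somatotopy
  shuffle and defeats that control.
* **Units.** Each unit gets a non-negative mixing vector over the latent
  space (normalized |N(0,1)|), a baseline rate uniform on 2–12 Hz, an SNR
  tag, and a swing gain drawn around its area's mean (M2 1.3, M1 1.8,
  S1 2.5 — the anterior-to-posterior coupling gradient) acting on the
  contralateral paw of its somatotopic limb.
* **Rates.** The class predictor `mixing · archetype` is clipped to ±3 and
  centered per unit by log-mean-exp so the baseline is the unit's mean rate
  over classes. A class-shared movement-activation axis
  (`exp(movement_gain · m_c)`, `movement_gain = 2`, `m_c` the centered
  movement level of class c) loads all units equally, reproducing the
  global rest-versus-movement activity gradient that anchors the leading
  embedding dimensions across subjects while carrying no unit-identity
  information. The swing term `(1 + (g−1)·swing)` is normalized to unit
  mean within each class, so paw-locked firing does not change class-mean
  rates. A smooth vigor latent (AR(1), ~2 s timescale, sd 0.35) scales the
  archetype deviation over time — behavior is expressed with varying
  intensity, making population states a continuum rather than isolated
  islands. A session-level log-normal gain per class (sd 0.1) emulates
  session-to-session differences in engagement. Rates are clipped at 50 Hz
  (Poisson overflow guard) and spikes drawn as inhomogeneous Poisson counts
  in 10 ms bins.
* **Latency.** A positive `swing_latency_s` makes the rate modulation lag
  the swing: spikes follow movement (sensory-like), and the STAPSSS peak
  offset is negative, near `−1000 · latency` ms.

What the generator does **not** emulate: bursting and refractory structure,
electrode drift and unit splitting, LFP, biomechanics of the paw
trajectories, label noise, and any non-stationarity beyond the vigor
process. Passing tests therefore show that the pipeline recovers the kinds
of structure it assumes and that its null calibrations hold under
realistic autocorrelation and imbalance — not that real cortical data
contain such structure.

# Numerical choices and problem sizes

Half-open bins `[t, t + Δ)` with a 0-based time origin are used everywhere;
the 500 ms snippet i covers 10 ms bins `50(i−1)+1 … 50i` and 100 ms bins
`5(i−1)+1 … 5i`. Quantiles use the inclusive type-7 convention. All
stochastic operations take explicit seeds and restore the caller's RNG
state; sessions, embeddings, and decoders are bit-reproducible given their
seeds.

The test and acceptance runs use deliberately reduced problem sizes chosen
to keep each stage's statistical question answerable: calibration sessions
of 600–900 s with 36–80 units, decoding sessions of 1200 s with 60 units
(≈12,000 retained 100 ms time points), 1000 synthetic null units for the
STAPSSS type-I check, 40 planted units for power, three planted session
pairs (median p) for the polytope calibration, and decoder networks of two
64-unit hidden layers with learning rate 10^-3 (the larger paper-style
3×500 / 3×200 architectures and 10^-4 learning rate remain the defaults of
`mlp_fit()` for full-scale use). Known-manifold checks use 1200–1500
points.

# Limitations

The polytope similarity test in recording space compares sessions with
equal dimensionality; sessions with different unit counts can be compared
in an embedded space of common dimension. The JM permutation test is
directional. Landmark Isomap coordinates are defined up to a rigid
transform of full Isomap's. The somatotopy control, by construction,
cannot rule out conserved *class-level* activity profiles as a similarity
source — the generator is calibrated so class identity lives in unit-level
co-activation, and with strong session-level engagement noise the
unshuffled test loses power. No out-of-sample (Nyström) extension is
provided for embedding new time points.
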