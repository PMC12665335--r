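---
title: "Methods: quantifying gesture-vocal co-structuring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gesture-vocal co-structuring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costruct)
```

## The question and the model

In improvised vocal traditions, singers gesture continuously while they
sing. Beyond direct, time-locked coupling (a hand rising with a pitch
glide), one can ask a *second-order* question: do motifs that **sound**
alike co-occur with gestures that **move** alike? `costruct` operationalises
this as a correlation between two pairwise-similarity structures.

Given a set of segmented vocal motifs with synchronized audio and
motion-capture signals:

1. Each motif is described by four sonic time series — fundamental
   frequency $f_0$, its estimated derivative $\Delta f_0$, loudness, and
   spectral centroid — and six kinematic time series — 3D position,
   velocity and acceleration of the dominant hand and of the head, in a
   body-centric frame.
2. For every unordered pair of motifs and every feature, a dependent
   dynamic time warping (DTW) distance is computed, giving a table with
   $\binom{n}{2}$ rows and 10 distance columns (for $n = 595$ motifs,
   176{,}715 rows).
3. **Analysis 1** computes, for each of the $4 \times 6 = 24$
   sonic-kinematic column pairs, the Spearman rank correlation over motif
   pairs — the *co-structuring profile* — for the pooled performer set and
   per performer, against a Bonferroni threshold $\alpha / m$
   ($\alpha = 10^{-4}$, $m = 96$ for the canonical four-set family), with a
   shuffle-null control.
4. **Analysis 2** asks how predictable sonic distances are from kinematic
   distances, using gradient-boosted regression trees under a fixed
   model-selection protocol, reporting holdout $R^2$ for hand-only,
   head-only, combined, and randomized predictor sets.

## The DTW distance

The local cost between frames $a_i$ and $b_j$ is the Euclidean norm of the
frame difference, summed jointly over a feature's dimensions — *dependent*
DTW: the three axes of a kinematic feature share one warping path. Three
structural constraints, with $L$ the length of the longer series in the
pair:

* **Sakoe–Chiba band.** Cell $(i, j)$ is admissible iff
  $|i \cdot \mathrm{len}_b/\mathrm{len}_a - j| \le \lceil 0.1 L \rceil$.
  Anchoring the band to the matrix diagonal (slope correction) keeps
  unequal-length pairs feasible; with a naive band a short-vs-long pair can
  have no admissible path at all.
* **Open endpoints.** The path may start at any admissible cell with
  $i \le \lceil 0.1L \rceil + 1$ and $j \le \lceil 0.1L \rceil + 1$, and end
  within the mirrored margin. This absorbs segmentation jitter: two
  renditions of the same phrase cut a few frames differently should not pay
  an alignment penalty at the cuts. At margin 0 the textbook fixed-endpoint
  recurrence is recovered exactly.
* **Path normalization.** Motif durations vary severalfold; un-normalised
  accumulated cost grows with path length, so distances are divided by the
  optimal path's step count by default (`normalize_by_path`, exposed as a
  flag). No z-normalization is applied to the series themselves: loudness
  is already on a common dB-re-maximum scale and positions share the
  body-centric metre scale.

The band test is not symmetric in its operands when lengths differ, so the
implementation always evaluates a pair with the longer series first;
$d(a,b) = d(b,a)$ holds exactly. Because all local costs are nonnegative,
the minimum-cost path *ending* anywhere in the start region is the fresh
length-1 path — a useful identity that the dynamic program exploits and
that the brute-force enumeration oracle in the test suite verifies
independently (all admissible paths for series of length 4–6, compared to
1e-9).

Ties in the accumulated cost are broken deterministically (fresh start
over continuation; diagonal over vertical over horizontal predecessor);
with continuous-valued inputs ties have probability zero, but determinism
keeps reruns byte-identical.

## Sonic conditioning

The chain is fixed: pitch tracking → gap bridging → Gaussian smoothing →
derivative estimation.

* **Pitch.** The reference analysis used a style-specific learned
  extractor, which is out of scope here; `estimate_f0()` is a standard
  frame-based autocorrelation tracker (Hann window, normalised
  autocorrelation, parabolic peak refinement, voicing threshold 0.5),
  adequate for clean monophonic voice and for the synthetic fixtures.
  Precomputed pitch tracks can be ingested instead.
* **Gap bridging.** Interior unvoiced runs of at most 350 ms are filled by
  linear interpolation — short pitch breaks occur inside ornaments and are
  not perceived as phrase breaks, and DTW cannot align series with holes.
  Longer interior gaps mark the motif `ok = FALSE`, and such motifs are
  excluded from the distance table (never silently included).
* **Smoothing.** A truncated discrete Gaussian, $\sigma = 2.5$ samples,
  radius $4\sigma$, reflective edges. The kernel is a convex combination,
  so constants are preserved and no new extrema beyond round-off are
  created. All four sonic series are smoothed with the same $\sigma$.
* **$\Delta f_0$.** The estimated-derivative transform
  $D_i = ((q_i - q_{i-1}) + (q_{i+1} - q_{i-1})/2)/2$, endpoints
  replicating their nearest interior value.
* **Loudness.** $L_t = 10 \log_{10}(P_t / \mathrm{ref})$ with $P_t$ the
  short-time spectral power and ref the maximum frame power over the
  reference extent, floored at $-80$ dB. "Reference extent" is the parent
  performance when available, else the motif: a performance-level
  reference keeps motifs of one performance mutually comparable.
* **Spectral centroid.** Magnitude-weighted mean frequency per frame. Bins
  below 5% of the frame's peak magnitude are gated out first: the Hann
  window's leakage sidelobes (−31 dB) otherwise drag a pure tone's
  centroid hundreds of Hz toward mid-spectrum. With the gate, a sinusoid's
  centroid sits at its frequency to within a bin, which is the behaviour
  the feature is meant to capture.

Frame settings: 100 Hz frame rate (10 ms hop) and 46 ms analysis windows —
standard melodic-analysis settings; the sonic frame rate is configurable
and 100 Hz resolves fast ornamentation while keeping DTW cheap. $\sigma$ is
interpreted in samples at this rate.

## Kinematic conditioning

Fixed chain: Savitzky–Golay smoothing → body frame → dominant-hand
selection → mirroring.

* **Smoothing.** Second-order Savitzky–Golay, 125 ms window, converted to
  the nearest odd sample count (7 at 60 Hz, favouring detail retention).
  Polynomials up to degree 2 pass through unchanged.
* **Body frame.** One *static* rigid transform per motif, computed from
  time-averaged landmarks: a yaw rotation making the shoulder line
  parallel to the mediolateral $x$ axis and a translation putting the
  pelvis centroid at the origin. A per-frame rotation would contaminate
  velocity and acceleration with the frame's own angular motion, so the
  static per-motif transform is the conservative choice. Velocities and
  accelerations receive the rotation only. Axis convention:
  $x$ mediolateral, $y$ anteroposterior, $z$ vertical; rotation about $z$
  only.
* **Dominant hand.** Per motif, the hand with the larger kinetic energy
  $\sum_t \tfrac12 m \lVert v_t \rVert^2$ (segment mass assumed equal on
  both sides, so $m$ cancels). Exact ties resolve to the left hand — the
  shared space is left-hand space — with a warning.
* **Mirroring.** Right-dominant motifs have the $x$ components of all six
  series negated, mapping every motif into a common "left-hand space" so
  recurrent-but-mirrored gestures compare directly. Head series are
  rotated with the body frame but never mirrored. Mirroring is an
  involution, and speeds and acceleration magnitudes are invariant under
  both the frame change and the mirror (rigid/reflection maps preserve
  norms).

When tracker-native velocity/acceleration channels are absent (synthetic
data, minimal ingests), they are derived from smoothed positions by
central differences, one-sided at the ends.

## Analysis 1: the co-structuring grid

For the pooled ("all") set, motifs are first subsampled without
replacement so each performer contributes equally (the count of the
least-represented performer), and all pairs among retained motifs —
including cross-performer pairs — enter the correlation; post-mirroring,
post-rotation kinematics are cross-performer comparable by construction.
An individual performer's set uses only pairs in which both motifs are
theirs. Spearman is used throughout (ties by average ranks, two-sided
p-values; the directional hypothesis would admit one-sided tests, but
two-sided is conservative).

The family-wide Bonferroni divisor is computed from the run: 24 cells per
performer set, so the canonical all + 3 performers design gives 96 tests
and threshold $10^{-4}/96$.

**Pair non-independence.** Each motif appears in $n-1$ pairs, so the rows
of the distance table are not independent and the asymptotic p-values are
anticonservative — a well-known property of correlating distance matrices.
This matches the reference analysis and is deliberately left uncorrected
in the default path; two controls are provided instead:

* `shuffle_null()` permutes each distance column independently within each
  performer-pair stratum, preserving all marginals while destroying
  pair-level coupling. Under this randomization the usual threshold is
  honest (one column's order is random relative to the other), and on
  strongly coupled synthetic data 100 shuffle replicates yield zero
  significant cells in ≥ 95% of runs.
* `mantel = TRUE` computes label-permutation p-values (permuting motif
  identities, Mantel-style), which respect the dependence. Permutation
  granularity bounds them below by $1/(n_\mathrm{perm}+1)$, so they suit
  moderate thresholds, not $\alpha/96$.

One subtlety the synthetic generator exposed: even at coupling zero, motif
*duration* is a genuine common cause of a motif's sonic and kinematic
distances (both series lengths scale with it), so a weak true association
survives label permutation unless durations are held fixed. The
calibration tests therefore fix durations when the exchangeable null is
the thing being tested.

## Analysis 2: predicting sonic from kinematic distances

Gradient-boosted regression trees (least-squares boosting of
depth-limited trees; the `xgboost` implementation) predict one sonic
distance column from kinematic distance columns: hand triple, head
triple, all six, or all six independently permuted across rows (the
chance baseline — marginals preserved, joint structure destroyed).

Protocol, per report: a stratified 20% holdout is split off first and
never touches selection or fitting; the 48-point grid
($n_\mathrm{estimators} \in \{50,100,150,200\}$,
learning rate $\in \{0.001, 0.01, 0.1\}$, depth $\in \{2,4,8,10\}$) is
searched by stratified 3-fold cross-validation repeated 5 times on the
remaining 80%, scored by mean $R^2$ over the 15 fold fits, ties resolved
to fewest trees then shallowest depth; the winner is refit on the full
training split and holdout $R^2$ reported. "Stratification" balances the
only categorical structure a motif pair has — its unordered performer-pair
category (within-$P_k$ or cross) — in both the holdout split and the CV
folds; the holdout is drawn per performer set.

Because boosting is sequential, the first $k$ trees of a 200-round run
*are* the $k$-round model; the grid search trains once per
(learning rate, depth) pair and scores all four sizes by truncated
prediction — a 4× saving verified tree-for-tree in the test suite. All
fits run single-threaded, which makes reruns byte-identical.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analyses
assume, with known ground truth:

* Each latent melodic class carries a smooth latent curve $z(u)$ (a
  Gaussian random walk smoothed to gestural time scales, roughly 0.5–2 Hz
  at the default durations) with derivative curves $z'$, $z''$.
* Sonic trajectories are fixed affine maps of $(z, z')$: $f_0$ around
  220 Hz ± 60 Hz per latent unit, loudness in dB re the motif maximum,
  centroid around 1500 Hz; $\Delta f_0$ is produced by the package's own
  derivative operator, so the generator exercises the real code path.
* Kinematic trajectories mix a coupled part — a per-(performer, limb)
  random linear map $B_{p\ell}[z; z'; z'']$, hand maps loading the latent
  level and head maps its derivatives, so the limbs carry partly distinct
  information and different pseudo-performers couple through different
  dimensions — with an independent smooth 3D curve, in proportion
  $\lambda : (1-\lambda)$. $\lambda = 1$ with no noise or warp makes
  same-class motifs identical; $\lambda = 0$ decouples sound and movement.
* Per instance: a random monotone time warp of $[0,1]$ with bounded
  derivative (DTW is designed to absorb exactly this), additive noise,
  durations uniform on 1.5–3 s, a nondominant hand that is a spatially
  scaled copy carrying $1/\mathrm{ratio}$ of the dominant hand's kinetic
  energy (default ratio 4), near-static shoulders/pelvis, and a random
  per-performance yaw and offset that the body-frame transform must
  remove. Performers are left-dominant with probability 0.89, the
  proportion reported for concert recordings of this repertoire.
* The whole skeleton passes through the package's own conditioning chain,
  and every random draw is independent of $\lambda$, so runs differing
  only in coupling share their latent and noise draws — which makes the
  coupling-monotonicity property nearly deterministic per seed.

What the generator does **not** emulate: melodic grammar (no scale, no
ornament inventory), articulatory biomechanics, vocal timbre (audio
fixtures are plain harmonic complexes), tracker artefacts (drift,
occlusion), or performer-specific gesture vocabularies beyond the random
coupling maps. Passing tests therefore demonstrate that the pipeline
detects and calibrates second-order coupling of the assumed form — not
that any particular real corpus exhibits it.

## Numerical and design choices

* Band/open margins default to 0.1L; at series lengths of 4–6 used by the
  enumeration oracle, margins and band are exercised across their whole
  admissible range.
* Half-open motif slices $[t_\mathrm{start}, t_\mathrm{end})$ keep
  adjacent motifs frame-disjoint.
* Distance tables persist as plain CSV (full double precision via R's
  default 15 significant digits); at the full 176,715 × 10 scale this
  remains tractable, and `arrow` users can convert externally if desired.
* The 2D embedding export uses classical MDS on the chosen precomputed
  distance column — deterministic, no tuning — and is explicitly
  non-statistical: no inference is performed on reduced coordinates.
* Problem sizes in the validation suite: the canonical synthetic design is
  3 performers × 40 motifs (7,140 pairs); power and monotonicity use 20
  and 10 seeds; regression properties run on 435-pair tables. These sizes
  were chosen so the full suite exercises every claim at desk scale.
* Degenerate inputs: empty series, zero-variance regression targets,
  silent audio, degenerate shoulder geometry and sub-window series all
  raise typed errors rather than propagating NaN; silent spectral frames
  carry the previous defined centroid and are flagged.

## Known limitations

* The autocorrelation pitch tracker is not robust to accompaniment or
  octave errors in dense polyphony; ingest precomputed $f_0$ for real
  concert audio.
* Asymptotic p-values in the grid inherit the pair-dependence liberality
  discussed above; treat the shuffle null (and, at moderate thresholds,
  the Mantel option) as the calibrated reference.
* Holdout $R^2$ on distance pairs shares the same non-independence: rows
  of the holdout overlap motifs with training rows. The randomized
  baseline quantifies what that leakage alone buys (empirically:
  $R^2 \approx 0$).
* The ingest schema (CSV layouts documented in `write_synth_dataset()`)
  is this package's own; adapters are needed for tracker-native formats.
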