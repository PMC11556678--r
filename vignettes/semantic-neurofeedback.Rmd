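---
title: "Methods: building and navigating semantic maps of mental states"
author: "semanticnf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and navigating semantic maps of mental states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semanticnf)
```

## The problem and the model

Univariate fMRI neurofeedback feeds back the mean activity of a region of
interest. That signal reflects engagement intensity but not content: very
different mental states (a happy and a sad recollection, say) produce
strongly overlapping mean activations in emotion-related cortex. The
engine in this package instead treats the *pattern* of activity across the
ROI's voxels as the object of interest and feeds back where that pattern
sits relative to a participant's own previously measured mental states.

The pipeline has four stages:

1. **Anchors.** A localizer stage yields one multi-voxel pattern per
   mental state (`anchor_set`). All later geometry is relative to these.
2. **RDM.** All pairwise dissimilarities between anchors form the
   representational dissimilarity matrix (`build_rdm`). The default metric
   is the correlation distance $d = 1 - r$, which normalizes out each
   pattern's mean and standard deviation and therefore isolates pattern
   *shape*; Euclidean and Mahalanobis metrics are provided for analyses
   where amplitude or voxel noise structure should count.
3. **Map.** Classical (Torgerson) MDS embeds the RDM in 2 or 3 dimensions
   (`embed_rdm`): with $D^{(2)}$ the elementwise-squared RDM and
   $J = I - \tfrac1n \mathbf{1}\mathbf{1}^\top$,
   $B = -\tfrac12 J D^{(2)} J$ is eigendecomposed and the anchor
   coordinates are $X = V_k \Lambda_k^{1/2}$ over the top $k =$ `dims`
   positive eigenpairs.
4. **Online projection.** During feedback the map stays fixed; each
   current-mental-state pattern (CMS) is projected into it by the landmark
   MDS out-of-sample rule (`project_pattern`):
   $x = -\tfrac12\,\Lambda_k^{-1/2} V_k^\top (\delta^{(2)} - \mu)$,
   where $\delta^{(2)}$ holds squared CMS-to-anchor dissimilarities and
   $\mu$ the column means of $D^{(2)}$. Projecting an anchor's own
   dissimilarity vector returns its map row exactly, which the tests
   exercise as the landmark self-consistency property.

Two deliberate conventions are worth stating because the literature leaves
them open. RDM entries are treated as *distances* and squared for double
centering (the standard Torgerson reading), not as already-squared
quantities. And classical MDS was chosen over iterative stress
majorization because it is closed-form and deterministic and because the
landmark projection rule is defined in terms of its eigenbasis; the
trade-off is that it minimizes strain rather than stress, so `map_stress`
(Kruskal stress-1) is reported alongside every map rather than being the
quantity optimized.

## Degenerate spectra and orientation

Correlation-distance RDMs are generally non-Euclidean, so the spectrum of
$B$ usually has negative tail eigenvalues; those axes are unusable and are
truncated, with the retained fraction of positive-eigenvalue variance
recorded on the map. Two edge cases get explicit treatment:

- **Fewer positive eigenvalues than requested axes.** A 2-anchor RDM, for
  instance, spans a single axis. Rather than refusing to build a map (the
  display contract requires 2-D coordinates, and two anchors at $d = 2$
  legitimately embed at $\pm 1$ on one axis), the missing axes are
  zero-padded and a warning names the full eigenvalue spectrum. Only a
  configuration with *no* positive eigenvalue (all anchors coincident) is
  an error.
- **Rotation/reflection ambiguity.** MDS fixes a configuration only up to
  orthogonal transforms. `canonical_orientation` rotates anchor 1 onto
  the nonnegative first axis, puts anchor 2 at nonnegative second
  coordinate (in 3-D, anchor 2 into the first two axes' plane and anchor 3
  at nonnegative third coordinate). This makes maps, serialized maps and
  replays bit-stable; the same transform is stored and applied to every
  projected CMS. Coincident or collinear leading anchors pass through
  untransformed with an explicit `degenerate` orientation tag.

## Similarity versus intensity

Because the correlation metric discards amplitude, a participant who
recreates a target pattern and then engages *more strongly* would see no
change in a similarity-only display. The engine therefore computes, per
feedback step, the target-related pattern strength (`pattern_strength`):
both vectors are mean-centered and the CMS is projected onto the TMS,
giving the scalar coefficient
$\text{strength} = \frac{\mathrm{CMS}\cdot\mathrm{TMS}}{\mathrm{TMS}\cdot\mathrm{TMS}}$.
Centering is applied so that the accompanying similarity (the cosine of
the angle between the centered vectors) coincides with the Pearson $r$
used everywhere else; a raw-vector mode exists behind the `center` flag.
The scale law — $k\,$CMS leaves similarity unchanged and multiplies
strength by exactly $k$ — is asserted to $10^{-10}$ in the tests, at loop
level as well as unit level.

## The two displays

**Map display** (`map_frame`): the CMS point at its projected coordinates,
with marker size affine in strength, clipped to `[0, strength_cap]`.
**Circular display** (`circular_frame`): one thermometer per anchor on a
circle, only the target's filled (fill = clipped strength / `fill_cap`),
plus a central arrow that conveys similarity. Both caps default to 1.5:
strength 1 means localizer-level engagement, so a cap modestly above 1
keeps above-localizer engagement visible without letting outliers saturate
the display; negative strength renders as minimum size / empty
thermometers rather than as an inverted bar, which pilots found ambiguous.

The arrow interpolates between the target thermometer and whichever of its
two layout-adjacent neighbours correlates more with the CMS, at fraction
$\mathit{dist} = 1 - t/(t + nb)$ of the angular gap. The formula
misbehaves for negative correlations (it can push the arrow *past* the
neighbour), so similarities are clamped at zero before evaluation; then
$t \ge nb \ge 0$ guarantees $\mathit{dist} \in [0, 0.5]$. If no anchor
correlates positively the arrow is pinned at the target with a
`degenerate` flag rather than pointing anywhere meaningful. With only two
anchors the single other anchor serves as both neighbours and the arrow
approaches it through the smaller gap.

Thermometer placement (`circular_layout`) is either *generic* — equal
spacing from the top of the circle in declared label order, so callers can
order labels along a valence–arousal circumplex — or *dissimilarity
driven*: all distinct circular orderings (necklaces) are enumerated
(bounded at 8 anchors; $(n-1)!/2$ grows too fast beyond that), each scored
by how far its adjacent dissimilarity shares deviate from equal spacing,
$\sum |1/n - d_{ij}/\sum_{\text{adj}} d|$, and the winner's gaps are made
proportional to its adjacent dissimilarities. Scoring against equal
spacing is the package's resolution of an underdetermined design: scoring
proportional gaps against themselves is vacuously zero for every ordering,
while the equal-spacing reference pushes highly dissimilar pairs to
opposite sides of the circle, which is the display behaviour one wants.
Ties in every argmax (target selection, neighbour choice, necklace search)
break by declared anchor order, first occurrence winning, so replays are
deterministic.

## The closed loop

`run_session` drives either a trial-pattern stream (for testing the
geometry without any haemodynamics) or a volume stream. In volume mode the
CMS estimator (`estimate_cms`) averages a `window_volumes`-long window
shifted back by `hemodynamic_delay_volumes`, converts to percent signal
change against a baseline, and exponentially smooths with weight
`smoothing_alpha`. Defaults — window 4, delay 2 (≈ 4 s at TR 2 s),
α = 0.5 — follow common real-time fMRI practice; an incremental GLM
estimator would be the natural extension but is out of scope. Feedback
cadence is controlled by `feedback_every` (1 = continuous, larger =
intermittent). The loop itself draws no random numbers: identical inputs
give bit-identical trajectories, which the tests assert via
`expect_identical` and which the CLI's manifest files rely on.

Navigation performance (`navigation_metrics`) is scored on the per-frame
correlation distance between the CMS and the *instructed* anchor:
per-block means, within-run least-squares slopes, and the between-run
improvement (run 1 mean minus run 2 mean; positive = better replication in
the second run).

## What the synthetic generator does and does not emulate

The simulator exists so the whole loop is testable without a scanner.

- `make_anchors` draws i.i.d. standard-normal voxel vectors and mixes them
  by a symmetric square root of a prescribed correlation matrix. The
  default 4-state structure (happy/content $r = 0.5$, sad/angry
  $r = 0.4$, weak negative cross-valence correlations) encodes the
  valence-clustered similarity structure emotion localizers typically
  show. Because the *achieved* sample correlations differ from the
  prescription at finite voxel counts, the generator returns them and
  tests compare against achieved values.
- `make_trials` adds amplitude scaling (engagement intensity) and white
  voxel noise scaled relative to each anchor's spatial SD; `noise_sigma =
  0.5` — noise at half the signal's SD — is the default single-trial
  regime, and 20 trials per condition is a realistic localizer length.
- `make_timeseries` convolves block boxcars with a canonical double-gamma
  HRF (peak 6 s, undershoot 16 s, ratio 1/6, fixed for test stability) on
  a baseline of 100, so percent signal change recovers the anchor scale.
- `simulate_agent` abstracts "engaging in an emotion" as movement of a
  convex mixture over anchors: per step
  $w \leftarrow (1-\eta)\,w + \eta\, e_{\text{target}}$, jittered and
  re-projected to the simplex (exact Euclidean projection), then emitted
  as the mixture of anchor patterns plus voxel noise. The neutral starting
  state is the uniform mixture. The agent's state persists across blocks
  and runs, so a positive learning rate produces the within- and
  between-run improvement signature that the navigation metrics are built
  to detect, while $\eta = 0$ yields improvement centred on zero.

None of this models spatially correlated physiological noise, scanner
drift, motion, or the psychology of emotion induction (pictures,
autobiographical recall); the agent is an explicit stand-in for a
participant. Passing tests therefore demonstrate the correctness and
statistical behaviour of the *engine* under controlled conditions, not
decoding performance on real BOLD data.

## Numerical choices and problem sizes

- Eigenvalues are "positive" above $10^{-12}$ times the spectral radius;
  anchor self-projection is asserted at $10^{-8}$, planted-configuration
  recovery (after orthogonal Procrustes alignment) at $10^{-8}$ over 200
  seeded configurations of 4–8 anchors, the strength scale law at
  $10^{-10}$, and rigid-transform distance preservation at $10^{-12}$.
- Serialization keeps full double precision (`%.17g` text columns, JSON
  with unrestricted digits), so write/read round-trips are exact and a
  serialized map projects identically to the in-memory one.
- Statistical contracts run at deliberately modest sizes that keep the
  whole suite around ten seconds on one core while leaving wide margins:
  RDM parameter recovery uses 4 conditions × 500 voxels × 20 trials at
  `noise_sigma = 0.5` over 100 seeds (pass = off-diagonal Pearson
  $r \ge 0.9$ in ≥ 95% of seeds); closed-loop learning detection uses 100
  replicates of two 25-step runs over 120 voxels (pass = positive
  between-run improvement in ≥ 95% of replicates, and a $|t| < 4$
  centred-on-zero check for the non-learning agent).
- Mahalanobis covariance is estimated diagonally with shrinkage toward the
  scaled identity (`estimate_noise_cov`), because residual patterns are
  far fewer than voxels and a full sample covariance would be singular.
- Voxel selection (`select_voxels`) scores each voxel with a one-way F
  statistic across conditions — a deterministic stand-in for
  classifier-weight-based selection, with ties broken by ascending index.

## Known limitations

- The map is frozen after the localizer stage; online re-estimation of
  anchors (drift, habituation) is not modelled.
- Classical MDS minimizes strain; for strongly non-Euclidean RDMs a
  stress-optimized embedding could place anchors differently. Stress is
  reported so users can judge the distortion.
- The dissimilarity-driven circular layout is exact brute force and
  limited to 8 anchors.
- Volume-mode CMS estimation assumes a stationary baseline and no motion;
  real-time preprocessing is upstream of this package.
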