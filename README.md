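# semanticnf

Semantic neurofeedback engine for real-time fMRI pattern navigation.

Conventional fMRI neurofeedback shows a participant how *strongly* a brain
region is active, but not *what* mental content drives that activity: a
patient instructed to engage in a positive emotion could raise the signal
with a negative one and the display would look the same. `semanticnf`
implements the semantic alternative for researchers building closed-loop
fMRI experiments: the *content* of the current mental state is read out from
multi-voxel activity patterns by representational similarity analysis (RSA)
and shown to the participant as a moving point inside a low-dimensional
*semantic map* of their own pre-measured mental states.

## What the engine computes

Given anchor patterns **a**₁ … **a**ₙ (one multi-voxel pattern per mental
state, e.g. *happy*, *content*, *sad*, *angry*, measured in localizer runs):

- **Dissimilarity / RDM** — pairwise pattern dissimilarities, by default the
  correlation distance *d* = 1 − *r* (Pearson), ranging from 0 (identical
  shape) through 1 (unrelated) to 2 (anticorrelated); Euclidean and
  regularized Mahalanobis metrics are available where amplitude matters. The
  n × n matrix of these values is the representational dissimilarity matrix
  (RDM).
- **Semantic map** — classical (Torgerson) MDS of the RDM: the
  double-centered squared-dissimilarity matrix **B** = −½ **J** **D**⁽²⁾ **J**
  is eigendecomposed and the top 2 (or 3) positive eigenpairs give anchor
  coordinates **X** = **V** Λ^{1/2}, canonically oriented so repeated runs
  are bit-stable. Goodness of fit is reported as Kruskal stress-1.
- **Online projection** — each new current-mental-state pattern (CMS) is
  placed into the fixed map by landmark MDS:
  **x** = −½ Λ^{−1/2} **V**ᵀ (δ⁽²⁾ − μ), where δ⁽²⁾ are the squared
  dissimilarities from the CMS to the anchors and μ the column means of the
  anchors' squared distance matrix. No re-embedding happens during feedback.
- **Pattern strength** — the target-related intensity: with mean-centered
  vectors, strength = (CMS·TMS)/(TMS·TMS), the scalar projection of the CMS
  onto the target mental state (TMS). Rescaling the CMS by *k* > 0 leaves
  the Pearson similarity (and the map position under the correlation metric)
  unchanged and multiplies the strength by exactly *k* — similarity carries
  content, strength carries engagement.
- **Feedback displays** — (a) the map display: the CMS point drawn at its
  projected coordinates with marker size affine in clipped strength; (b) the
  circular display: one thermometer per anchor (only the target's is
  filled), plus a central arrow interpolated between the target and its most
  similar layout neighbour by
  *dist* = 1 − *t*/(*t* + *nb*) (similarities clamped at 0, so
  *dist* ∈ [0, 0.5]).
- **Closed loop** — `run_session()` chains CMS estimation (sliding-window
  percent-signal-change averaging with a haemodynamic delay shift and
  exponential smoothing), target selection, strength, projection and both
  displays into a deterministic per-step `trajectory`;
  `navigation_metrics()` scores per-block distance-to-target, within-run
  slopes and between-run improvement.
- **Synthetic loop** — `make_anchors()` (anchor patterns with a prescribed
  correlation structure), `make_trials()`, `make_timeseries()`
  (double-gamma-HRF block designs), and `simulate_agent()` (a participant
  that navigates anchor space as a convex mixture) let you exercise the
  whole pipeline with no scanner.

## Worked example

```r
library(semanticnf)

# localizer stage: 4 emotion anchors over 300 voxels with a prescribed
# valence-structured correlation matrix
loc <- make_anchors(n_cond = 4, voxel_count = 300, seed = 42)
rdm <- build_rdm(loc$anchors, metric = "correlation")
rdm
#> <rdm> 4 x 4 (correlation distance)
#>         happy content   sad angry
#> happy   0.000    0.53 1.228 1.081
#> content 0.530    0.00 1.010 1.270
#> sad     1.228    1.01 0.000 0.599
#> angry   1.081    1.27 0.599 0.000

map <- embed_rdm(rdm, dims = 2)
map
#> <semantic_map> 4 anchors in 2-D (correlation distance; 100.0% of positive-eigenvalue variance)
#>           dim1   dim2
#> happy    0.622  0.000
#> content  0.324  0.522
#> sad     -0.605  0.038
#> angry   -0.340 -0.560
map_stress(map, rdm)
#> <stress_report> Kruskal stress-1 = 0.04203 (2-D)
```

Same-valence states (happy/content, sad/angry) sit close together; the
stress value says the 2-D map distorts the 4-state dissimilarity structure
by about 4%.

```r
# neurofeedback stage: an agent practices navigating to 'happy' in two runs
sim <- simulate_agent(loc$anchors,
                      data.frame(target = "happy", n_steps = 25, run = 1:2),
                      agent_config(learning_rate = 0.2, seed = 43))
traj <- run_session(sim$patterns, loc$anchors, map, session_config(),
                    sim$instructed, run_id = sim$run_id)
m <- navigation_metrics(traj)
m$block_means
#>   run target n_frames mean_distance
#> 1   1  happy       25   0.024044382
#> 2   2  happy       25   0.006298293
round(m$between_run_improvement, 3)
#> [1] 0.018

traj$frames[[50]]
#> <feedback_frame> t=50 target=happy strength=0.977 at (0.618, 0.007)
```

By the last step the CMS point sits essentially on the `happy` anchor
(map row `(0.622, 0.000)`) with a target-related pattern strength near 1
(localizer-level engagement), and run 2's mean correlation distance to the
target is lower than run 1's — the between-run improvement the navigation
metrics are designed to detect.

A command-line wrapper over the same functions is installed at
`cli/snf` (subcommands `simulate`, `rdm`, `map`, `frame`, `session`; every
run writes a `manifest.json` that makes it bit-reproducible).

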