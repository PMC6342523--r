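---
title: "Constrained NMF source extraction for calcium imaging: models and methods"
author: "cnmfr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained NMF source extraction for calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnmfr)
```

## The model

A motion-corrected fluorescence movie is arranged as a matrix $Y \in
\mathbb{R}^{d \times T}$ whose rows are pixels (row-major flattening of the
field of view) and whose columns are frames. `cnmfr` decomposes it as

$$Y = A\,C + B + E,$$

where the columns $a_i \ge 0$ of $A \in \mathbb{R}^{d \times N}$ are
spatially localized footprints (one per neuron), the rows $c_i \ge 0$ of
$C \in \mathbb{R}^{N \times T}$ are the corresponding fluorescence traces,
$B$ is the diffuse neuropil background, and $E$ is noise. For two-photon
data the background is low-rank, $B = b\,f$ with $n_b$ spatial and temporal
modes; for one-photon (microendoscopic) data, where the integration volume
is much larger, `ring_background()` instead models each pixel's neuropil as
a non-negative combination of the *residual* traces of pixels on an annulus
around it, $B = W\,(Y - AC)$, with $W$ sparse and supported on the annulus.

Calcium dynamics are modeled as a first-order autoregressive process:
$c(t) = \gamma\,c(t-1) + s(t)$ with spikes $s(t) \ge 0$ and per-frame decay
$\gamma \in [0, 1)$. `oasis_deconvolve()` solves the resulting sparse
non-negative deconvolution problem

$$\min_{c \ge 0} \tfrac12 \lVert y - c \rVert^2 + \lambda \sum_t s(t)
\quad \text{s.t.}\quad s(t) = c(t) - \gamma c(t-1) \ge 0$$

exactly, by pool-adjacent-violators: pools of frames share a fitted
exponential segment, and adjacent pools are merged left-to-right while the
AR constraint is violated. The solution is the global optimum of this
convex problem; tests verify the Karush-Kuhn-Tucker conditions and compare
against a generic quadratic-programming solver on small instances.

## Batch pipeline

`run_batch()` processes a movie in overlapping spatial patches:

1. **Patch layout** (`construct_patches()`): tiles of `patch_size` (default
   48 × 48 px) with `overlap` (default 8 px) between neighbors; patches are
   truncated at the border.
2. **Initialization** (`greedy_roi()` and variants): components are seeded
   at successive maxima of the variance of the spatially smoothed movie,
   each refined by a local rank-one fit in a window of side
   `4 * gaussian_width + 1`, with the explained activity subtracted before
   the next seed. Two supporting choices matter in practice and were design
   decisions of this package:
   * the movie's top $n_b + 1$ temporal singular modes are projected out
     before variance seeding. The neuropil background is (near) low-rank
     and otherwise dominates the smoothed variance, so seeds would land on
     background structure rather than somata. The extra mode absorbs the
     DC offset. When `background_rank = 0` no projection is applied (the
     leading modes would then be the neurons themselves).
   * each seeded site is excluded from later picks. Without this, a site
     whose residual the local rank-one fit cannot fully explain would be
     re-seeded indefinitely, exhausting the component budget.
   `rolling_greedy_roi` scores variance over a rolling window (default 3 s,
   stride half a window), which favors isolated transients of sparsely
   active cells; `greedy_corr()` seeds at local maxima of the product of
   the correlation image and the peak-to-noise image and needs no preset
   component count; `seeded_initialization()` starts from user masks.
3. **HALS refinement** (`hals_refine()`): alternating block-coordinate
   non-negative updates of background, traces, and footprints. Footprint
   support is confined to the current support dilated by one pixel per
   round, so shapes can grow slowly without losing locality. Every update
   is a coordinate-descent step on $\lVert Y - AC - bf\rVert_F^2$, so the
   objective is non-increasing; an increase beyond $10^{-8}$ relative
   aborts with diagnostics.
4. **Quality filtering** (`evaluate_components()`), run per patch and again
   on the assembled FOV — see below.
5. **Assembly**: footprints are embedded at their patch offsets, divided by
   the per-pixel patch coverage count, and duplicated components along the
   seams are merged: components that overlap spatially and whose traces
   correlate at or above `merge_threshold` (default 0.8) are replaced by
   the non-negative rank-one pair that best reproduces their combined
   activity. Patch backgrounds are compressed to rank `g_b`, embedded, and
   recompressed to rank $n_b$. After the final full-FOV HALS pass the merge
   is applied once more (refined traces expose duplicates the seam merge
   missed) and each footprint is thresholded to the connected core holding
   99% of its energy, which removes low-weight shells accreted by support
   dilation.

### Component quality assessment

Three tests run per component:

* **Spatial consistency**: the movie with all *other* components and the
  background removed is averaged over windows around the strongest trace
  peaks (50 ms before to 300 ms after each of the top `n_peaks` peaks,
  excluding peaks where a spatially overlapping component is active at
  z-score above 2), and correlated with the footprint in a box around its
  centroid. Accept at `space_corr_min` (default 0.5).
* **Trace peak-SNR**: the non-denoised trace $c_i + r_i$ (with $r_i$ the
  residual movie projected through the footprint) is z-scored against its
  baseline and noise level. The noise level is the half-normal scale of
  sub-baseline samples, $\hat\sigma = \mathrm{sd}(\text{sub-baseline}) /
  \sqrt{1 - 2/\pi}$; the baseline for this fit is the trace median, whose
  sampling error is well under 1% (a density-mode baseline was evaluated
  and rejected: its sampling noise of several percent dominates the
  estimator). Each sample's upper-tail probability $\Phi(-z)$ is averaged
  geometrically over windows of one typical transient
  (`transient_seconds`, default 0.4 s), and the SNR is
  $-\Phi^{-1}$ of the most unlikely window, computed in the log domain.
  Accept at `snr_min` (default 2).
* **Footprint shape**: a classifier scores the cropped, max-normalized
  footprint. The default scorer is deterministic and geometric — circular
  fill (mask area over the circumscribed circle) times solidity (mask area
  over convex hull) of the half-maximum mask — and requires no training.
  `train_footprint_classifier()` alternatively fits a single-hidden-layer
  neural network on synthetic soma/non-soma crops. Components scoring
  below `classifier_reject_floor` are rejected outright; the floor is
  disabled during per-patch filtering because patch borders clip
  footprints and the shape score is meaningless there.

An optional fourth test (`spike_snr_test`) deconvolves the detrended trace
and requires at least one spike of `snr_min` times the noise level. Slow
neuropil remnants produce sustained excursions (high windowed SNR) but no
large individual spikes, so this test separates them from transient-driven
somata; it is off by default and enabled in the synthetic benchmark
configuration. Finally, `detect_duplicates()` removes the lower-scoring
member of any pair whose binarized masks overlap asymmetrically above
`overlap_dup` (default 0.7).

## Streaming pipeline

`run_online()` initializes on a movie prefix (default 200 frames; "bare"
mode extracts only `init_components` cells plus the background) and then
processes one frame at a time:

* traces are updated by block coordinate descent over groups of mutually
  non-overlapping components (greedy graph coloring of the overlap graph),
  warm-started from the previous frame;
* sufficient statistics $Y C^\top / t$ and $C C^\top / t$ are maintained
  by rank-one updates, so footprints can be re-estimated without storing
  the movie;
* a rolling buffer of residual frames is searched for new components: the
  energy image of rectified residuals is contrast-enhanced by subtracting
  a Gaussian blur at twice the neuron radius, and local maxima at pairwise
  distance of at least $2r$ become candidates. A candidate must (i) stand
  at least 4 robust standard deviations above the high-passed energy noise
  floor (on the synthetic generator, fresh transients measure 8-50 such
  units while noise-only buffers peak near 3.5), (ii) pass the footprint
  classifier on the mean rectified residual crop, (iii) reach the
  candidate SNR threshold on its buffer trace, and (iv) not duplicate an
  existing component (footprint cosine at most `max_overlap_cos`).
  Accepted candidates enter with zero past trace, which a second epoch
  back-fills;
* footprint updates are distributed across frames by a counter scheme:
  counters start logarithmically spaced in $(1, 2]$, decay by
  $0.5^{1/T_u}$ per frame, and a component is updated when its counter
  falls to 1 (so every footprint is updated at least once every `T_u`
  frames, default 200). No shapes are updated on a frame where components
  were added; instead the counters of overlapping neighbors are zeroed so
  they update on the next frame. Background shapes ride along with every
  scheduled update.

After streaming, traces are re-estimated over the whole movie by
non-negative regression, components that never carried activity are
dropped, and (by default) the same quality battery as in batch screens the
final set. The screen uses a slightly lower spatial-consistency threshold
in the benchmark configuration (0.65 instead of 0.8) because streamed
footprints are rougher than batch-refined ones.

## Multi-session registration

`register_pair()` binarizes footprints at `binarize_threshold` times their
maximum (default 0.2), computes pairwise Jaccard distances $1 - |m_1 \cap
m_2| / |m_1 \cup m_2|$ — with distance 0 when one mask contains the other,
and $\infty$ when the distance exceeds `match_threshold` (default 0.5) —
and solves the assignment problem optimally (Hungarian method via
`clue::solve_LSAP`, padding to square with a large finite cost and
discarding pairs assigned at infinity). Rigid integer-pixel alignment of
templates by cross-correlation is available; non-rigid alignment is out of
scope. `register_multi()` registers sessions chronologically against the
running union of distinct components, replacing matched union members with
the newest footprints and appending unmatched ones, and returns the
per-session matchings into the union. `transitivity_index()` quantifies
whether chained matchings (1→2→3) agree with direct ones (1→3).

## The synthetic generator

`generate_movie()` realizes the model exactly: unit-norm isotropic
Gaussian footprints (scale `gaussian_radius`, truncated at three radii),
centers placed by rejection sampling with a minimum separation of twice
the radius (a retry cap of 1000 makes an overfull FOV a deterministic
error), Bernoulli spikes at `spike_rate` per second driving AR(1) traces,
and a low-rank background of smoothed-noise spatial surfaces (mean pixel
weight 1) times slow non-negative random walks. With the default
`background_amplitude` each pixel carries a DC offset of roughly 0.5
fluorescence units and slow fluctuations on the order of the noise level —
neuropil brighter than the transients in DC terms, fluctuating at the
noise scale, which is the regime of motion-corrected two-photon data. An
optional exponential photobleaching flag supports detrending tests.
Defaults describe the benchmark used throughout the tests: a 64 × 64 px
FOV at 30 Hz, 1000 frames, 20 neurons, $\gamma = 0.95$, spike rate 0.5 Hz,
and transient amplitude ten times the noise level of the projected trace
(unit-norm footprints make the two directly comparable).

What the generator does **not** emulate: motion artifacts, non-Gaussian
and correlated noise, dendrites and axons, overlapping somata beyond what
the separation rule allows, and the full spatial statistics of real
neuropil. Passing the benchmark therefore demonstrates correctness of the
machinery under the stated model, not performance on arbitrary real
recordings.

`generate_sessions()` builds multi-session footprint fixtures from a
master pool with controlled presence probability and per-session rigid
shifts, together with the ground-truth correspondence table.

## Numerical choices and conventions

* Pixel indexing is 1-based with inclusive ranges, row-major flattening
  (`pixel = (row - 1) * cols + col`) — one convention, asserted in tests.
* The `.pmap` on-disk format stores the pixels × time matrix pixel-major
  as little-endian float32 after a 128-byte header, so reading one pixel's
  full time series (and hence a spatial patch) touches contiguous bytes.
  Chunked two-phase writing is bit-identical to single-pass writing.
* Non-negative least-squares subproblems use blockwise coordinate descent
  (HALS), except the ring-background weights, whose annulus regressors are
  too correlated for coordinate descent and are solved by active-set NNLS
  (`pracma::lsqnonneg`) on a temporal subsample.
* Rank-one merge fits run 50 alternating updates from the largest-norm
  group member; ties and tie-breaks are deterministic throughout
  (duplicate removal keeps the lower index on equal scores).
* Baselines are running percentiles over `window_seconds` (default 100 s)
  with stride equal to the window and linear interpolation between block
  centers; traces shorter than a window get a constant global percentile.
  The automatic percentile level matches the mode of a kernel density
  estimate of the trace. ΔF/F uses the baseline of
  $f_i + B^\top a_i / \lVert a_i \rVert$ as denominator, which makes the
  result invariant to the arbitrary scale split between footprint and
  trace.
* AR coefficient estimation uses the lag-2/lag-1 autocovariance ratio
  (guarded against white-noise traces by a significance threshold on the
  lag-1 autocovariance) and noise estimation the mean periodogram power
  over the upper frequency half.

## Problem sizes used in the test-suite

Unit tests run on 16-24 px square movies of a few hundred frames; the
end-to-end batch and streaming checks use the full 64 × 64 × 1000-frame
benchmark (about 15 s and 70 s respectively on a single core). The
acceptance script regenerates the benchmark from its `--seed` argument and
recomputes every reported number at run time.

## Known limitations

* The 1p path provides the ring background model and its refinement
  machinery, but the full 1p patch pipeline (larger overlaps, retaining
  the best variant of overlapping neurons instead of merging) is not
  assembled end-to-end.
* The footprint classifier is trained on synthetic crops only; on real
  data the geometric scorer or a user-supplied model should be preferred.
* AR(2) dynamics, non-rigid motion correction, 3D volumes, and
  probabilistic registration models are out of scope.
* The streaming detector's energy gate assumes roughly stationary noise;
  strongly non-stationary recordings may need a different significance
  threshold.
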