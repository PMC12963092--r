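---
title: "Detecting stone fragmentation in dusting video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stone fragmentation in dusting video: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragtrack)
```

## The problem

During ureteroscopy with laser lithotripsy, surgeons often *dust*
kidney stones: ablate them into particles small enough (roughly
≤ 250 µm) to pass spontaneously. An undesired outcome of dusting is
*fragmentation* — detachment of a piece larger than about 1000 µm that
may later need basketing. Detecting fragmentation in the endoscopic
video stream, in real time, would let the surgeon (or the laser
controller) adjust power settings before more fragments are produced.

`fragtrack` implements a three-stage detection pipeline over a frame
sequence:

1. **Segment** — a per-frame binary mask of the stone (and any
   fragments);
2. **Track** — query points initialized on the stone mask, followed
   frame to frame;
3. **Detect** — the tracked point positions of each frame are
   clustered with a hierarchical density-based clusterer; a
   fragmentation flag fires when the cluster count rises above the
   baseline measured at the last point (re)initialization and the rise
   persists.

The detection rule is deliberately simple: when a fragment breaks off,
the points riding on it move away from the points on the parent stone,
and one spatial cluster becomes two. Clustering uses *positions only*
(Euclidean metric on x, y), never velocities.

## Reference implementations and backend contracts

Clinical video of these procedures is withheld (protected health
information), and so are the learned models used on it. The package
therefore pairs every learned stage with a classical, fully
deterministic reference implementation behind a narrow contract, so
that externally produced artifacts can replace either stage:

* the **segmenter contract** is any function mapping a frame to a
  binary mask of the same shape (`segment_sequence(backend = ...)`,
  or precomputed masks from disk); the reference implementation is
  intensity thresholding (Otsu by default), morphological opening then
  closing with a disc, and a connected-component area filter.
  Opening runs *before* closing so dust speckle is erased before stone
  holes are sealed. A learned text-prompted segmenter thresholded at
  probability 0.5 satisfies the same contract.
* the **tracker contract** is the track-table format
  (`track_id, frame, x, y, visible`) read by `external_tracks()`; the
  reference tracker matches each point's patch from the previous frame
  by zero-normalized cross-correlation within a search radius,
  refined to sub-pixel accuracy by a 1-D parabolic fit in x and y.
  Taking the template from the previous frame (not the first) tolerates
  appearance drift from lighting and turbidity at the cost of slow
  template drift; the detector's re-initialization bounds that drift.

Correlation ties are broken toward the smallest displacement, then
row-major — pure determinism, no preference beyond "do not move
without evidence".

## The clusterer

No hierarchical density-based clustering implementation was available
in the installed R stack, so the package authors one (`cluster_positions()`):

1. *core distances*: distance to the `min_samples`-th nearest
   neighbour, the point itself included;
2. *mutual reachability*: `max(core_i, core_j, d_ij)`;
3. a single-linkage hierarchy over mutual reachability
   (`stats::hclust`);
4. *condensation*: walking the dendrogram top-down, a split is real
   only when both sides hold at least `min_cluster_size` points;
   smaller sides fall out of the current cluster at the split's
   density level λ = 1/height;
5. *excess-of-mass extraction*: a cluster is kept when its stability
   (summed point lifetimes in λ) beats the summed stability of its
   selected descendants.

Two deliberate conventions differ from common defaults and are load
bearing here. First, the **hierarchy root is selectable**: a single
coherent blob must come back as *one* cluster, not as noise, because
the detector compares counts against a measured baseline. Second,
fewer than `min_cluster_size` points in total is all-noise (count 0).
The test suite cross-checks cluster counts against an exhaustive
density-connectivity oracle — an explicit ε-sweep over the
mutual-reachability graph with brute-force connected components —
on hundreds of small point sets.

## The detection rule

Let `B` be the cluster count measured on the frame of the last point
(re)initialization. The per-frame flag is true exactly on maximal runs
of frames with count `> B` of length at least `persistence` (default
3). With `persistence = 1` the rule degenerates to
fire-on-any-increase, which is also the configuration closest to the
published description of the approach; the default debounce exists
because a single-frame cluster-count blip is nearly always clustering
noise, a known major source of false alarms for this family of
pipelines.

`B` is *measured*, not assumed to be 1: a stone behind a partial
occlusion legitimately starts as two clusters, and assuming 1 would
flag it forever.

**Re-initialization.** Points are re-sampled from the current mask
every `reinit_interval` frames (default 60, i.e. 2 s at 30 fps) and
whenever the visible fraction of points drops below
`min_visible_fraction` (default 0.3). Both the interval and the
trigger are design choices of this package — how long a point set was
tracked in the original study is not documented. Re-initialization is
**debounce-aware**: if an above-baseline run is active when a re-init
fires, the run keeps testing against its own baseline until it
resolves. Without this, an event starting a few frames before a
scheduled re-init is swallowed, because the freshly measured baseline
already includes the new fragment's cluster. Only visible points ever
enter clustering; invisible points are frozen at their last position
and would otherwise form phantom clusters.

## Evaluation protocol

Frame level: a ground-truth interval `[s, e]` is matched if any
predicted frame lies within `[s − 30, e + 30]` (±1 s at 30 fps).
A matched interval credits all of its frames as TP once, however many
predictions hit it; an unmatched interval counts all frames as FN;
every predicted frame matching no interval adds one FP. Per-predicted-
frame FP counting is the only unit consistent with per-frame TP/FN
accounting — the FP unit is not otherwise pinned down by the published
tables.

Segment level: the video is tiled into consecutive 90-frame (3 s)
segments. TP counts matched ground-truth *events* — the only reading
under which TP + FN equals the number of labeled events, which the
published counts satisfy (60 + 77 = 137); the more literal
one-TP-per-segment reading is available as
`eval_config(segment_tp_unit = "segment")`. A segment is FP when it
holds at least one predicted frame yet intersects no tolerance-widened
event; without the widening, a correct-but-early prediction would be a
frame-level TP and a segment-level FP simultaneously. Overlapping
ground-truth intervals are rejected rather than merged — per-interval
accounting is ill-defined under overlap.

Metrics are precision, recall and F1 (harmonic mean), each 0 by
convention when its denominator is 0. Multi-case results pool the
counts first and recompute metrics from the pooled counts; metrics are
never averaged across cases.

## The scene simulator

`generate_scene()` emulates the *structure* of a dusting scene, not
its appearance: a bright textured stone (ellipse, intensity contrast
0.35 over a 0.25 background) on a noisy darker background, a
scope-motion jitter random walk (sd 0.4 px/frame), occasional defocus
blur, transient dust discs, and fragments that detach at configured
frames and translate rigidly. Geometry is analytic — the stone is an
ellipse intersected with accumulating half-plane cuts, a fragment is
the complementary side of its cut frozen at detachment — so the split
is an exact pixel partition (area conservation is structural) and
every ground-truth trajectory is closed form. Surface texture is a
smoothed Gaussian random field frozen in stone-local coordinates:
aperiodic (a periodic pattern would hand the correlation tracker false
lock-on points one wavelength away) and rigidly advected, including
sub-pixel motion, via bilinear sampling.

Physical calibration uses `microns_per_pixel` (default 50): dust discs
are capped at 5 px radius and fragments get at least a 20 px diameter,
the two ends of the 250 µm / 1000 µm size convention that separates
dusting from fragmentation. Labeled event intervals default to 15
frames (0.5 s) from the split; real events can be as brief as 3–5
frames at 30 fps, and the simulator supports durations down to 3
frames. All randomness draws from a single stream in a documented
order (texture, jitter and blur, dust, track-point sampling, pixel
noise), making scenes bit-reproducible from their seed.

What the simulator does **not** model: fluid turbidity, bleeding,
specular reflections from the laser fiber, illumination gradients,
rolling-shutter artifacts, or deformation of the stone. Green tests on
synthetic scenes therefore demonstrate the pipeline's mechanics —
masks feed point initialization, detached point groups split into
clusters, the accounting is exact — not clinical performance. On real
surgical video the published experience is that precision, especially
at segment level, is the binding constraint.

## Numerical choices and degenerate inputs

* Otsu thresholding is skipped on constant frames (all-false mask).
* An all-false mask yields a no-points condition; detection is
  suspended (flags stay FALSE, with a warning) until a later
  re-initialization finds points.
* Flat correlation patches (zero variance on both sides) count as
  correlation 1 when their means agree, 0 otherwise; with the
  smallest-displacement tie-break, featureless points stay put instead
  of wandering.
* Sub-pixel offsets are clamped to ±0.5 px and applied only when the
  parabola is concave.
* Cluster labels are deterministic for a fixed input order; λ values
  use `1/max(height, eps)` so zero-height merges cannot divide by
  zero.
* Fragments whose detached region would be under one pixel are
  rejected at configuration time.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run 256×256 scenes of 90–150
frames: 20 fragmentation scenes (one large slow fragment each,
detachment direction and timing varying across scenes) for event
recovery and pooled metrics, 50 no-event scenes with dust and jitter
for the false-alarm guard, and a noise-free rigid-drift scene for
tracker accuracy. These sizes make the whole suite run in minutes on
one CPU while keeping the stone (~100 px across), point grids
(~100 points) and event durations (15 frames) in realistic proportion
to the frame.

## Known limitations

* Fragments faster than `search_radius` px/frame (default 8) outrun
  the correlation search and are lost rather than tracked — the
  documented failure mode for small fast fragments, reproduced in the
  test suite. A pretrained long-range point tracker plugged in through
  the track-table contract is the intended remedy.
* The reference segmenter is intensity-based and will not separate a
  stone from bright instruments or strong reflections; it stands in
  for a learned segmenter, which the backend contract accommodates.
* Clustering on positions only cannot distinguish a detaching fragment
  from a second pre-existing stone drifting apart from the first; both
  raise the cluster count.
* The detector's flags are retroactive by up to `persistence − 1`
  frames (the whole qualifying run is flagged once it qualifies);
  strictly causal consumers should use the frame at which the run
  qualifies as the alarm time.
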