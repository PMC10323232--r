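---
title: "Detecting cell extrusions without segmentation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cell extrusions without segmentation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science and the engineering decisions behind
`epievents`: what is modelled, which parameters matter and why their
defaults are what they are, what the synthetic data generator does and
does not emulate, and where the design was genuinely open.

## The problem

Epithelial cell extrusion — the expulsion of a (usually dying) cell from
the layer by progressive apical constriction — is visible in junction
labelled movies as a cell whose apical outline shrinks over ~20–30 min
until its neighbours seal into a rosette. Counting and localising
thousands of such events across large fields of view is the bottleneck of
quantitative cell-death studies. Segmentation-and-tracking pipelines solve
it indirectly and expensively; `epievents` instead classifies overlapping
spatiotemporal windows directly and aggregates their scores, so no cell
identity is ever needed.

Two other cellular events share the visual signature of a shrinking apex
and act as systematic confusers: sensory organ precursors (SOPs), whose
asymmetric divisions leave a persistently small cell, and cytokinesis,
whose furrow transiently pinches the apical outline. The classifier can
therefore be trained with 2, 3 or 4 classes (`none`, `extrusion`, `sop`,
`division`): giving the confusers their own classes removes them from the
extrusion channel and is the first of three precision levers (the others
being reinforcement and two-network ensembling, below).

## Reference scale

All analysis happens at a fixed reference calibration of 0.275 µm/pixel
and 5 min/frame, at which a typical cell is ~25 px across and an extrusion
spans 4–5 frames. Movies are resampled to this scale on entry
(`rescale_movie_to_reference()`): bilinear interpolation spatially,
nearest-frame resampling temporally. No temporal interpolation is invented
— frames are only repeated or decimated, which matches how training data
are augmented. Output shapes round half away from zero, a deterministic
rule applied to every integer conversion in the package.

For tissues whose cells are simply bigger or slower (e.g. larval abdominal
cells at ~80 px and ~10 frames per extrusion),
`scale_factors_from_cell_features()` derives the factors from those two
observed features instead of the absolute calibration. Factors multiply
movie-scale quantities to give reference-scale quantities, in both
functions.

Because annotations live on integer pixel grids at both scales, a
round-trip through a coarse reference grid cannot always return to the
exact origin: for a spatial factor `f < 0.5` the quantisation step exceeds
one original pixel and the round-trip error can reach 2 px. The matching
tolerances (15 px) dwarf this.

## The window classifier

The unit of classification is a (10, 45, 45) (t, y, x) window — 50 min of
context, two to three cells wide. The temporal crop around an annotated
event covers five frames before the event frame and four after: apical
constriction precedes termination, so the discriminative dynamics lie
before the annotated closure point.

Architecture, per frame: four blocks of 3×3 same-padding convolution
(filters 8, 16, 32, 64), batch normalisation, ReLU; 2×2 max pooling after
the first three blocks shrinks the side 45→22→11→5, and a final global max
pool collapses the remaining 5×5 grid, encoding each frame as a 64-vector.
The printed pooling chain forces the convolutions to be size-preserving,
which is why 3×3 same-padding kernels are used. The 10×64 sequence feeds a
GRU (hidden size 64, matching the feature dimension), dropout 0.5, one
dense layer of 32 ReLU units, and a softmax over the classes. Batch
normalisation precedes activation. GRU size, dense sizes, dropout,
optimiser (Adam, 10^-3, batch 32) and the 3×3 kernel are not dictated by
the architecture contract and are documented package choices, recorded in
each model's sidecar for reproducibility.

Windows are standardised as wholes (mean 0, sd 1 over all voxels of the
10×45×45 crop) before entering the encoder: absolute intensity and overall
illumination cancel, while the relative intensity changes between frames —
the brightening rosette of a closing extrusion, the appearing furrow of a
division — are preserved. (Per-frame standardisation was evaluated and
discarded: it erases exactly that relative temporal structure and
measurably weakened held-out detection.)

All forward and backward passes are implemented in the package (base-R
matrix algebra with compiled kernels for convolution, batch normalisation
and pooling); gradients are validated against central finite differences
to ~10^-7 relative error. Training minimises the categorical
cross-entropy; accuracy is the proportion of correct predictions out of
all predictions; the validation split (25%) is evaluated in inference mode
(running batch-norm statistics, no dropout).

### Training data

Event windows are cropped around annotations with a uniform random jitter
(±5 px, ±1 frame by default) so the event is not always centred. Control
windows are drawn uniformly and rejected if *any* annotation of any class
falls inside their full spatiotemporal extent — the strictest reading of
"no event in the window". Class imbalance is handled by downsampling every
class to the rarest class's count (`balance_classes()`). On-the-fly
augmentation applies content shifts, additive Gaussian noise, bright/dark
squares and illumination changes; each training window contributes
`augmentation_factor` samples per epoch (default 2, the first unaugmented).
With whole-window standardisation the global illumination gain is
absorbed exactly by normalisation; the augmentation is kept because its
single-frame variant still perturbs the relative frame weighting.

High-frame-rate movies can be doubled into even/odd half-rate movies
(`augment_movie_temporal()`) to rebalance their under-representation after
rescaling.

### Precision levers

Three mechanisms trade compute for precision without touching recall
appreciably: (1) training with SOP and division classes so confusers leave
the extrusion channel; (2) **reinforcement** — run detection on training
movies, crop windows at false-positive locations, force-label them `none`,
retrain; repeated `reinforcement_iterations` times (default 5); (3)
**two-network ensembling** — train two networks (training is stochastic:
sampling, initialisation, shuffling) and average their probability maps
voxel-wise, which damps stochastic false positives at twice the inference
cost.

## From windows to point events

Sliding windows (spatial stride 22 px = 50% overlap, temporal stride 2)
are classified and each window's event-class probability is allocated
uniformly to a 5×22×22 voxel patch centred on the window centre; a voxel's
value is the mean over all windows whose patches cover it. Patch
conventions are half-open, `[c-11, c+11)` and `[c-2, c+3)`, and patches of
windows flush with a movie border are extended to that border so that
every voxel is covered by at least one window — otherwise an 11-px rim of
the tissue could never be scored.

Detection then proceeds per event class:

* **Threshold** at `probability_threshold` (default 180 on the 0–255
  display scale): a voxel is positive iff `round(255 p) >= 180`.
* **Connected components** in 3D with 26-connectivity — an extruding blob
  drifts a little between frames, and face-only connectivity would
  fragment it — discarding components below `volume_threshold` (default
  800 voxels ≈ one cell area × 4–5 frames; isolated single-window
  responses are removed mainly by the temporal averaging, sustained ones
  by this filter).
* **Watershed separation** of merged blobs: seeds are regional maxima of
  the Gaussian-smoothed probability (σ = 2 px, 1 frame), suppressed when
  within 12 px (half a cell) *and* 4 frames (about one event duration) of
  a stronger seed — the temporal condition keeps two events at the same
  place but different times separable. Because the averaged map is
  piecewise constant over allocation patches, naive local maxima mark
  whole plateaus and the shoulders of neighbouring tiles; seeds are
  therefore (i) one representative per connected plateau, (ii) required to
  be regional maxima of the relief (the connected level set through the
  seed contains nothing higher), and (iii) required to have relative
  prominence: a seed whose saddle towards a stronger seed lies above 85%
  of its own height is a noise shoulder of the same event and is merged,
  while a genuine second event keeps a deep dip between the peaks. All
  three decisions are computed on a margin-padded box of the full relief,
  not the thresholded component, so they do not depend on where the
  threshold cut the blob. Voxels then flood from the seeds in descending
  probability bands over the 26-neighbourhood; fragments below the volume
  threshold merge into their largest touching neighbour, so the split
  conserves the component's voxel multiset. For degenerate movie-scale
  blobs (> 50× the volume threshold, which only arise from uninformative
  maps) a nearest-seed partition replaces the band flood, whose run time
  would otherwise be quadratic-ish.
* **Centroids** of the surviving components, with the component's peak
  probability attached, are mapped back to original-movie coordinates in a
  single rounding step.

Raising the volume threshold can only remove detections, and raising the
probability threshold can only remove detections while the threshold sits
above the map's background (the regime it is designed for); below the
percolation level the mask becomes one spanning component which the
prominence criterion reports as a single event, and raising the threshold
out of that regime can fragment it. Both properties are tested on
realistic sparse blob maps. The full `detect_events()` composition is
deterministic given the networks and configuration.

## Scoring

A detection and an annotation match when their xy Euclidean distance is at
most 15 px and their frame distance at most 4 (at reference scale: 4.12 µm
and ±20 min); both tolerances scale for other tissues. Matching is
one-to-one and class-aware, accepting candidate pairs in ascending
(spatial, temporal) distance under a maximum-cardinality guarantee: a pair
is skipped when accepting it would reduce the total achievable number of
matches (checked with augmenting paths). Pure greedy acceptance is not
always optimal on dense instances, and the tests require exact agreement
with an exhaustive assignment oracle. Precision, recall and
F1 = TP/(TP+(FP+FN)/2) follow; when a denominator is zero the metric is 0,
except that empty-vs-empty scores 1. Accuracy, which needs true negatives,
is only reported for window-level classification. Distance histograms
(1 px × 1 frame bins) and cumulative event-count curves (10-min bins) give
the spatial and temporal error structure; for unannotated movies a random
detection subset can be exported for manual review and the reviewed
fraction converts to an estimated precision.

## Synthetic epithelia

The generator renders a junction-labelled epithelium as the boundary
skeleton of a scaled Voronoi tessellation: Lloyd-relaxed seed points, one
per cell, each with a per-frame scale factor; pixels join the cell
minimising `d²/s`. Junctions are the blurred label boundaries at a bright
intensity over a dark interior, plus Gaussian sensor noise; seeds drift
slowly so junctions fluctuate. Events are scale trajectories:

* **extrusion** — scale shrinks linearly to 0 over 4–5 frames; the area
  decreases monotonically to zero and the neighbours' junctions converge
  to the closure point (the annotated x, y, t) in a rosette, exactly the
  documented morphology;
* **division** — the seed splits into two separating daughters over 2–3
  frames; the new boundary is the furrow, annotated at onset;
* **SOP** — the scale ramps down once and stays small (persistently small
  apex);
* **confuser** — a transient constriction that relaxes, recurring
  periodically; rendered but never annotated, for reinforcement
  experiments.

Planted events keep at least one window (45 px / 10 frames) of
spatiotemporal separation by default, and ground truth is exact by
construction. Defaults emulate the reference scale: 25 px cells, junction
intensity 0.65 vs background 0.12 (on [0, 1]) with noise σ = 0.03 — a
high-signal regime; difficulty is controlled through that contrast and σ
alone. A nearest-centroid classifier on two handcrafted area-trajectory
features separates planted extrusions from divisions with >90% accuracy,
verifying that the learning task is well-posed before any network is
involved.

What the generator does **not** emulate: real junction texture and
curvature-projection artefacts, photobleaching, tissue flows, mechanical
neighbour deformation beyond the tessellation geometry, and annotation
noise (synthetic ground truth is pixel-exact, manual annotations are not).
Passing the synthetic recovery experiment therefore demonstrates that the
pipeline's machinery — scaling, sampling, training, inference, map
assembly, post-processing, scoring — is correct and well-calibrated, not
that the shipped defaults reach any particular accuracy on real tissue.

## The self-contained benchmark

`run_synthetic_benchmark()` is the package's end-to-end experiment, used
by both the test suite and `scripts/acceptance.R`: three reference-scale
movies of 256×256 px × 60 frames with ~100 cells and 12 extrusions + 8
divisions each; a reduced two-class network (4 base filters → 32 features,
10 epochs, Adam 3·10⁻³, batch 16, best-validation checkpoint) trained on
two movies; the full detection pipeline with the default thresholds on the
held-out movie. The training windows are built to match the population the
classifier faces at inference — this matters far more at this scale than
any hyperparameter:

* positives are drawn around each annotated event with a jitter of half
  the spatial stride (±11 px), so the nearest sliding-window column of
  every event lies inside the supervised displacement range;
* divisions are relabelled `none` (the two-class contract);
* controls are event-free framings drawn from the sliding-window grid
  itself, the exact distribution the detector classifies;
* "temporal-contrast" controls — windows at an event's location but at a
  distant, event-free time — force the classifier to key on constriction
  dynamics rather than static tissue appearance.

With 20 draws per event a fold takes about four minutes on one CPU
(three folds ≈ 12 minutes); `scripts/acceptance.R` computes one fold and
reports its numbers. At this scale the window classifier reliably reaches
≥0.95 held-out window accuracy and the pipeline recovers most planted
events (held-out recall typically ≈0.8–0.9), but precision fluctuates
strongly with the training seed (≈0.5–0.9): with only 24 distinct
training extrusions, the network's responses at recurring static tissue
patterns and in the unsupervised skirt beyond the jitter range are
seed-dependent, producing a handful of false positives that a single
reduced network cannot consistently avoid. The method's designated
remedies for exactly these failure modes — multi-class confuser training,
reinforcement, and two-network ensembling — are deliberately outside this
reduced two-class experiment, which is why the package treats them as
first-class precision levers rather than optional extras. The exact
figures are computed, never quoted, by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Rounding: half away from zero everywhere a size or coordinate becomes an
  integer; thresholding compares `round(255 p)`, matching the exported
  8-bit maps.
* Batch normalisation: ε = 10⁻⁵, running-statistics momentum 0.9;
  training-mode statistics are per batch, inference uses the running
  values, so inference is deterministic and batch-size invariant.
* Softmax rows are shifted by their maximum before exponentiation.
* Empty masks, empty components lists, empty event sets and empty matching
  instances all propagate to empty results rather than errors; a movie
  smaller than one window is an invalid input for detection.
* ROI files are written in the ImageJ binary point-ROI layout (1-based
  stack position on disk, 0-based frames in memory; class in the ROI name
  prefix, since the format has no class field; detection probability only
  survives in CSV exports). ROI-set zips are stored uncompressed with a
  table-driven CRC-32.
* Ties: `max.col(ties.method = "first")` everywhere an argmax is taken;
  pooling argmax prefers the top-left of the 2×2 quad.

## Known limitations

* The classifier is trained from scratch per study; no pretrained weights
  ship with the package.
* Only single-channel 2D+time movies are supported (no z-stacks, no
  anisotropic xy, no drift correction).
* The pure-R/Rcpp network is CPU-bound: fine at the package's study sizes
  (minutes per movie), slow for notum-scale screens (use fewer epochs, the
  reduced width, or fewer reinforcement rounds first).
* At desk scale (tens of annotated events) the detection scores are
  training-seed dependent; stable scores need either more annotated
  events or the precision levers above.
* Reinforcement assumes the annotation set is complete; on sparsely
  annotated movies it would force genuine events into the `none` class.
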