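---
title: "Quantifying vesicle-microcluster dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vesicle-microcluster dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptrack)
```

## The biological setting

Within seconds of a T cell touching an activating surface, signaling
adapters such as LAT and ZAP-70 condense into sub-micron *microclusters* at
the contact plane. A distinct, intracellular pool of LAT rides on
VAMP7-positive vesicles that are delivered to the synapse tens of seconds
later, after microtubule reorientation. Two populations of observations
characterize this two-phase process in time-lapse fluorescence microscopy:

* **kinetics** — clusters appear essentially at time zero, vesicles appear
  in the evanescent (TIRF) field or make first contact with clusters only
  after a lag on the order of 45-60 s;
* **interaction** — once recruited, vesicles travel between microclusters,
  dwell on them, and spend most of their observed lifetime in contact with
  one, occasionally producing transient coincident intensity increases
  ("flares") in both the vesicle and the cluster channel.

`synaptrack` implements the measurement side of this picture: spot/surface
detection, tracking, object-based dynamic colocalization with a
randomization null, distance-transform proximity kinetics, flare detection,
and fixed-cell cluster statistics — plus a synthetic-data generator that
emulates the two-phase dynamics with known ground truth, so that every
stage of the pipeline is testable without access to raw microscopy data.

## Conventions

Images are `T x C x Y x X` (2D+t, "TIRF-like") or `T x C x Z x Y x X`
(3D+t, "light-sheet-like") arrays wrapped in an `image_series` with
physical calibration. All pixel coordinates are 1-based pixel centers in
`(y, x)` / `(z, y, x)` order, following R's indexing; physical quantities
are micrometers and seconds. Time zero is the first acquired frame — which
in real experiments is *not* the instant of cell contact, a caveat that
applies equally to the quantities computed here. Channel roles (cluster
vs. vesicle) are always declared in the configuration, never inferred.

## Detection

Frames are band-pass filtered with a difference of Gaussians (scales
`spot_sigma` and `3 * spot_sigma`), which removes background and flat
gradients and enhances diffraction-limited feature points. Segmentation
thresholds objects from the *enhanced* response: by default Otsu's method
computed once per channel on the pooled enhanced pixels of the whole
series (positive responses only — the clipped zeros carry no class
information). A single per-dataset threshold mirrors how thresholds are
chosen interactively in practice, and has an important side effect: frames
acquired before any real signal exists stay empty instead of being
thresholded against their own noise. The value actually used is recorded
in the detection result and the run log. A manual override is available.

Connected components use 8-connectivity (2D) or 26-connectivity (3D);
components below `min_size` (default 4 px in 2D, 8 voxels in 3D) are
rejected as noise-born. Centroids are intensity-weighted. Touching objects
can be split at local intensity maxima separated by at least
`min_separation` pixels, via a marker-based watershed on the inverted
intensity implemented as ordered flooding; splitting never changes the
union of foreground pixels.

## Tracking

Frame-to-frame linking is greedy nearest-neighbour with gap closing:
candidate links are accepted in order of increasing centroid distance
subject to a search radius `max_disp * (gap + 1)` pixels, and a track is
closed when it has been missed for more than `max_gap` frames (defaults:
5 px, 2 frames). Greedy linking was chosen over global assignment because
it is transparent and, in the regime this package targets — well-separated
spots moving less than the inter-object spacing per frame — provably
coincides with the optimal assignment; the test suite checks identity
agreement against an exhaustive-assignment oracle on small instances. No
merge/split events are modelled (vesicle fusion is visible in real data
but out of quantitative scope). Speeds are physical displacement over
*elapsed* time, so a step across a closed gap is averaged over the whole
interval.

## Object-based colocalization

A vesicle *touches* a microcluster in a frame when its pixel mask, dilated
by `tolerance` pixels (default 1, a Euclidean ball), overlaps any cluster
pixel; the touched cluster is the label with the greatest overlap. The
per-track **lifetime-colocalization fraction** is the fraction of observed
frames in contact; gap frames are excluded from the denominator because an
undetected vesicle cannot be scored. The population statistic is the
percentage of tracks, at least `min_lifetime = 5` frames long, whose
fraction reaches `lifetime_threshold = 0.75`. The minimum-lifetime filter
is a package decision (very short tracks have unstable fractions) and is
exposed as a parameter.

Significance against chance colocalization uses Costes' block
randomization: one channel is cut into `block x block` tiles (default 5 px,
roughly twice the PSF sigma, so tiles are approximately independent
structural units), tile contents are permuted uniformly at random, and the
Pearson coefficient against the unshuffled second channel is recomputed per
iteration. The p value uses the add-one estimator
`(count + 1) / (iterations + 1)`, which cannot return zero.

## Distance kinetics

Cluster label images are turned into Euclidean distance fields (zero on
clusters) with an anisotropic distance transform (Felzenszwalb-
Huttenlocher, exact, implemented in C++), and each track samples the field
at its rounded centroid. Distances are measured cluster-surface to
vesicle-centroid: vesicles are sub-resolution, so their centroid is the
natural reference, while clusters are extended surfaces. First-contact
time is the earliest frame time at which any vesicle's distance falls to
`contact_radius` (default: one xy pixel pitch — the finest sensible cutoff
given that positions are known to about a pixel). A channel's *appearance
time* is the time of the first frame containing an object that persists
for `min_persistence = 3` consecutive frames at tracking defaults;
persistence suppresses noise-born single-frame detections, and because
appearance calls in the literature are typically visual, the persistence
rule is a documented package decision rather than an inference.

## Flares

For each vesicle track, raw intensities of both channels are summed over
the vesicle's mask per frame and normalized by their own track mean,
giving relative fluorescence intensity (RFI) series with mean exactly 1.
Frames exceeding `median + k * MAD` (MAD scaled to the SD equivalent,
`k = 3`) are flagged per channel; a flare is a run of at least `min_frames
= 3` frames flagged in one channel with the other channel also flagged
within `coincidence = 1` frame. The robust baseline is deliberate: the
flares themselves would inflate a mean/SD-based threshold. Requiring
coincidence in *both* channels encodes the defining property of a flare —
vesicle and cluster signal rise together. The package measures flares; it
does not attempt to classify whether the cluster-channel signal originates
from the plasma membrane or the vesicle, which fluorescence imaging at
this resolution cannot distinguish. Per-step speeds are partitioned into
"at flare" (either endpoint frame inside a flare span) and "away".

## Fixed-cell measurements

`cluster_stats` converts labeled clusters into physical area/volume and
integrated/mean intensity (both intensity summaries are emitted, since
either may be wanted); totals are invariant to label renumbering.
`line_scan_profile` samples a segment with bilinear interpolation,
averages across a perpendicular width, subtracts a per-channel background
(an explicit value or ROI mean; fallback, the 1st percentile along the
scan), clips negatives and normalizes each channel to its peak. A channel
without signal above background is returned as all-zero with a warning
record rather than dividing by a meaningless maximum.

## The synthetic-data generator

The generator is a first-class module, not a test fixture: it renders the
two-phase model directly. Clusters are Gaussian spots of scale
`cluster_sigma` present from frame one (optionally decaying with a
half-life); vesicles are PSF-limited Gaussian spots (`psf_sigma`) because
real vesicles (~100 nm) are below the diffraction limit — physical size
enters only through intensity. Recruitment lags are drawn uniformly on
`vesicle_recruitment_window`. In 2D+t mode recruitment is *appearance*
(the spot switches on), emulating entry into the evanescent field; in 3D+t
mode vesicles hover 3 um above the contact plane and descend onto it,
arriving at their recruitment time, emulating what a volumetric microscope
actually sees. Associated vesicles (fraction `assoc_fraction`) travel on
piecewise-linear paths between cluster positions with dwells
(`dwell_prob`, `dwell_duration`) — the simplest motion model that
reproduces dwell/transit statistics of cytoskeleton-guided transport;
non-associated vesicles do a reflected random walk. During a dwell a flare
may fire with probability `flare_prob`, multiplying both channels' signal
within a small disc around the vesicle by `flare_amplitude` for exactly
`flare_duration` frames. Camera noise is Poisson on signal + background
followed by Gaussian read noise, the standard sCMOS/EM-CCD approximation.
All randomness flows from a single seed through a private RNG stream;
identical parameters and seed give bit-identical output.

Ground truth records every planted trajectory, recruitment time, per-frame
contact flag, flare event and cluster position. Contact flags are derived
from a nominal footprint model — the radius a Gaussian object of scale
sigma presents after enhancement and automatic thresholding, calibrated
once on noise-free single-object frames (`r(sigma) = 2.2 sigma - 1.2` px
at the package defaults) — except where a preset plants flags explicitly.

### Presets

The named presets encode documented study conditions:

* `track145` / `track213` — one static cluster, one vesicle, 20 noise-free
  frames; the planted trajectory holds the vesicle in firm contact for
  exactly 15 (resp. 19) of its 20 detected frames, with the contact/no-
  contact positions placed well clear of the touch-tolerance boundary and
  the single transition step below the tracking search radius. These give
  lifetime-colocalization fractions of exactly 0.75 and 0.95.
* `lag50` — 2 s frame interval, cluster present from the first frame, the
  vesicle's centroid first comes within one pixel pitch of the cluster 25
  intervals in, i.e. at 50 s.
* `paper_synapse` — 20 vesicles over 200 frames at moderate noise
  (background 100 photons, read noise 3): 16 vesicles orbit their own
  cluster with one 20-frame excursion (true contact fraction about 0.88),
  4 wander interstitially and never touch, so exactly 80% of vesicles are
  associated for at least 75% of their lifetime.
* `two_phase_tirf` / `two_phase_llsm` — clusters at frame one, vesicle
  recruitment drawn on 45-60 s, 1.5 s interval over more than 200 s, with
  dwells and flares; the volumetric variant uses an 18 x 80 x 80 voxel
  field at 0.25 um z-step.

### What the generator does and does not emulate

It reproduces the features the measurements depend on: two-phase timing,
PSF-limited rendering, directed motion with dwells, coincident flares,
Poisson + read noise. It deliberately omits optical rigor (no vectorial
PSF, no evanescent-decay model), photobleaching, vesicle fusion/fission,
and spatially varying background. Passing tests on synthetic data
therefore demonstrate that the *computational* pipeline recovers planted
structure under realistic noise — not that segmentation choices are
optimal for any particular microscope.

## Numerical choices and degenerate inputs

* Otsu on a constant frame is an error (no separable classes), as is
  automatic thresholding of a series with no enhanced signal.
* Label ordering is by descending size with scan-order tie-break, so
  results are permutation-stable.
* Greedy linking breaks ties by smaller distance, then smaller label.
* An empty cluster channel yields an all-infinite distance field with a
  warning record, not a silent zero.
* Percentages over zero qualifying tracks are errors, never NaN.
* The Costes p value is computed over whole tiles only; fewer than two
  tiles inside the mask is an error.
* TIFF float pages are stored scaled to [0, 1] with the scale factor in
  the JSON sidecar; round-trips are exact to float32 precision.

## Problem sizes

The packaged presets are sized for routine re-analysis on a single CPU:
the worked-example fixtures run in seconds; the 20-vesicle synapse
(200 frames, 160 x 160 px) and the volumetric two-phase preset
(140 frames, 18 x 80 x 80 voxels) each complete in about a minute. These
sizes were chosen so the full validation cycle — simulation, pipeline,
recovery checks — is something a user can run interactively, while
remaining large enough that every stage (stack thresholding, gap-closing,
3D distance fields) is exercised at realistic object densities.

## Known limitations

* The tracker has no motion model; very fast or very dense vesicles will
  fragment or swap. The oracle test quantifies exactly when greedy linking
  is trustworthy.
* Contact is a binary mask-overlap criterion; partial-volume effects near
  the touch tolerance are resolved by whichever side of the threshold the
  discretized masks fall on.
* Appearance times are quantized to the frame interval, so recruitment
  lags carry up to one interval of quantization error.
* The flare detector's robust baseline assumes flares occupy a minority of
  a track's frames; tracks that flare most of the time would inflate the
  MAD and lose sensitivity.
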