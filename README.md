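# synaptrack

Quantitative analysis of vesicle–microcluster dynamics at the
immunological synapse, from multi-channel time-lapse fluorescence
microscopy.

When a T cell engages an activating surface, signaling proteins (LAT,
ZAP-70, Grb2) condense into sub-micron **microclusters** at the contact
plane within seconds, while LAT-carrying, VAMP7-positive **vesicles** are
recruited from inside the cell only after a lag of roughly 45–60 s. Once
recruited, vesicles travel between microclusters, dwell on them, and spend
most of their observed lifetime in contact with one — occasionally
producing transient, coincident intensity increases ("flares") in both
channels. `synaptrack` provides the measurements that establish this
two-phase picture, for anyone analysing cluster/vesicle channels in 2D+t
(TIRF-like) or 3D+t (light-sheet-like) recordings:

* **Detection** — difference-of-Gaussians particle enhancement, per-dataset
  Otsu (or manual) thresholding on the enhanced stack, 8/26-connected
  component labeling, marker-based splitting of touching spots.
* **Tracking** — greedy nearest-neighbour linking with gap closing
  (search radius `max_disp · (gap + 1)`), per-step physical speeds.
* **Interaction** — the object-based contact test (vesicle mask dilated by
  a tolerance overlapping a cluster), the per-track lifetime-colocalization
  fraction

  `f = (# observed frames in contact) / (# observed frames)`,

  the population association percentage
  `% of tracks with f ≥ 0.75 (lifetime ≥ 5 frames)`, a spatiotemporal map,
  and Costes block-randomization for significance of the Pearson
  coefficient, `p = (#{r_null ≥ r_obs} + 1) / (N + 1)`.
* **Distances** — exact anisotropic Euclidean distance fields from cluster
  surfaces (C++), per-vesicle distance-versus-time series, first-contact
  times, channel appearance times and recruitment lags.
* **Flares** — per-vesicle relative fluorescence intensity (RFI) series in
  both channels (mean 1 by construction), robust coincident-increase
  detection (`RFI > median + 3·MAD` in both channels), vesicle speed at
  versus away from flares.
* **Fixed-cell metrics** — per-cluster area/intensity statistics and
  background-subtracted, peak-normalized line-scan profiles.
* **Synthetic data** — a generator for the full two-phase model (Gaussian
  PSF rendering, directed motion with dwells, planted flares,
  Poisson + read noise) with complete ground truth, so the whole pipeline
  is testable end to end.

## A worked example

Simulate a noise-free single-vesicle fixture in which the vesicle is
planted to touch the cluster in exactly 15 of its 20 frames, then run the
full pipeline:

```r
library(synaptrack)

sim <- simulate_timelapse(make_preset("track145"), seed = 0)
res <- run_pipeline(sim$images)
print(res)
#> <pipeline_result>
#>  vesicle tracks:        1
#>  association:           100.0%
#>  first contact:         5s
#>  appearance lag:        0s
#>  flare events:          0
print(res$records[[1]])
#> <interaction_record> track 1: 15/20 frames in contact (75.0%)
```

The single recovered track is in contact for 15 of its 20 observed frames,
a lifetime-colocalization fraction of 75% — the planted value. "First
contact 5 s" is when the approaching vesicle first comes within one pixel
pitch of the cluster surface; the appearance lag is 0 s because both
channels contain persistent objects from the first frame. On the
`paper_synapse` preset (20 vesicles, 16 planted as cluster-associated) the
same pipeline reports a population association of 80%, and on the
`two_phase_*` presets the vesicle channel appears 45–60 s after the
cluster channel with no vesicle–cluster contact before 45 s.

`run_pipeline(series, config, out_dir = "out")` writes tidy CSVs of all
tracks, contacts, distances and flares, a `summary.json`, and a run log
with the thresholds actually used and the configuration hash. A thin CLI
for shell use lives at `inst/scripts/synaptrack-cli.R`
(`simulate` and `run` subcommands).

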