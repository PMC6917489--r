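# synfoci

Quantification of the actin cytoskeleton and membrane-pulling activity at
the B cell immune synapse, from TIRF microscopy time-lapses.

When a B cell spreads on an antigen-presenting surface, its synaptic
F-actin organizes into two distinct structures visible in live (Lifeact) or
fixed (phalloidin) imaging: transient, round, diffraction-limited **actin
foci** (branched, Arp2/3-generated) and short linear **actin fibers**
(formin-generated), interspersed across the synapse. `synfoci` is an R
package for microscopists and quantitative cell biologists that turns such
movies into numbers:

* **Segmentation** — cells by automatic (Otsu) thresholding of actin
  intensity; foci and fibers by competing a matched Gaussian spot filter
  (FWHM 325 nm for primary B cells, 450 nm for Ramos cells) against an
  oriented ridge filter evaluated at 18° increments, with relative
  thresholds expressed as fractions of the cell's mean actin intensity.
  Foci and fiber masks are disjoint by construction.
* **Tracking and dynamics** — optimal frame-to-frame linking of foci
  centroids within a distance gate, a two-frame persistence filter,
  per-cell densities (foci per 10 µm²), lifetimes, displacements, and a
  survivorship-corrected exponential lifetime estimator.
* **Enrichment and colocalization** — mean-intensity enrichment of any
  channel in foci or fibers, and center-overlap colocalization of foci
  with point structures (e.g. clathrin-coated pits), against a null built
  by randomly re-placing the same structures in the same cell (mean of ten
  seeded randomization runs).
* **Validation** — automated detections vs. manual annotations with a
  5-pixel / 1-frame tolerance, reporting true- and false-positive rates.
* **Membrane pulling** — bright DiI structures on the presenting membrane,
  filtered to those that appeared or moved (excluding preexisting
  blemishes), associated with the actin structure their centers touch, and
  normalized per synapse or per structure area.
* **Synthetic data** — a TIRF-movie generator (`generate_scene()`,
  `render_fixture_suite()`) with planted foci, fibers, DiI events and full
  ground truth, so the entire pipeline is testable without microscope
  data.

## Worked example

Generate a small synthetic movie, segment it, and track the foci:

```r
library(synfoci)

params <- scene_params(image_size_px = 128L, n_frames = 30L,
                       cell_radius_um = 4.5, n_fibers = 6L,
                       fiber_length_um = 2, rng_seed = 11L)
scene <- generate_scene(params)
cfg   <- pipeline_config()

cell <- segment_cells(scene$actin, cfg$min_cell_area_um2)[[1]]
seg  <- segment_stack(scene$actin, cell, cfg)
tracks <- prune_tracks(
  link_foci(seg$foci_by_frame, cfg$link_max_dist_nm,
            scene$actin$pixel_size_nm),
  cfg$min_track_frames)

summarize_cell(tracks, cell, n_frames(scene$actin),
               scene$actin$frame_interval_s, scene$actin$pixel_size_nm)
#> # A tibble: 1 × 5
#>   cell_id foci_per_10um2 mean_lifetime_s mean_displacement_nm n_tracks
#>     <int>          <dbl>           <dbl>                <dbl>    <int>
#> 1       1           1.49             1.5                 142.       19
```

Read: this cell carries ~1.5 tracked foci per 10 µm² of synapse at any
moment (planted truth for this seed: 1.31), and a tracked focus ends up
~140 nm from where it started. The raw 1.5 s mean lifetime is heavily
censored by this deliberately short 3 s movie — `estimate_lifetime_mean()`
corrects for the persistence filter and censoring, and on the full-length
default movie (200 frames) it recovers the planted 3 s exponential mean to
within a few percent, which is what the recovery tests assert.

The same analysis runs end-to-end from a YAML config:

```sh
Rscript inst/cli/synfoci run analysis.yaml
```

with stages `simulate | segment | track | coloc | validate | pulling`,
tabular CSV outputs and a JSON run manifest for provenance.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model behind
each stage, every tunable parameter with its default and units, what the
synthetic scenes do and do not emulate, and the package's numerical
conventions.
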