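---
title: "Quantifying actin foci, fibers and membrane pulling at the B cell synapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying actin foci, fibers and membrane pulling at the B cell synapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

B cells spreading on an antigen-presenting surface build an immune synapse
whose F-actin organizes into two visually and mechanistically distinct
structures: **foci** — transient, roughly round, diffraction-limited
condensates of branched (Arp2/3-generated) actin — and **fibers** — short
linear filaments or bundles attributed to formins, interspersed between the
foci. TIRF time-lapses of a live-actin reporter (Lifeact) show both at once,
on top of a diffuse lamellipodial background, and the biological questions
hinge on quantities none of which can be read off by eye at scale: how many
foci per unit synapse area, how long each lives, how far it travels, how
strongly other molecules (Arp2/3, formins, clathrin-coated pits) enrich in
either structure, and which structure drives the membrane-pulling events
that a DiI-labeled presenting membrane reports as local brightenings.

`synfoci` implements that measurement chain as composable functions plus an
orchestrating pipeline, and — because no public raw imaging accompanies this
class of experiment — ships a synthetic TIRF-movie generator with complete
planted ground truth, so that every stage is validated by parameter
recovery rather than by inspection.

## Separating foci from fibers

Both structure classes are enhanced by matched linear filters and then
compete pixel by pixel:

* **Spot response.** Convolution with a unit-sum isotropic Gaussian whose
  FWHM is the expected focus size: 325 nm for primary B cells, 450 nm for
  the larger Ramos-cell structures (`foci_scale_nm`). Kernel sigma is
  `scale / 2.355` converted to pixels; boundaries are mirror-reflected.
* **Ridge response.** The pixelwise maximum of convolutions with unit-sum
  anisotropic Gaussian line kernels rotated in 18-degree increments — ten
  orientations spanning 180 degrees — so filaments of any orientation are
  captured. The transverse scale matches the spot scale; the long axis
  extends 3 sigma-equivalents of the spot filter (`long_factor = 3`).

The long-axis factor deserves a note, because the choice was genuinely
open. With a short long-axis (2x), the ridge filter responds to an
*isolated round spot* at 80% of the matched spot filter's response, so the
spot-vs-ridge competition (below) classifies only a ~1.7 px core of each
focus as "more spot than ridge". Camera noise then intermittently pushes
true foci below the minimum-area filter, and every such dropout severs a
track — in recovery experiments this biased mean lifetimes about 20% low
even in sparse fields. At 3x the ridge filter averages far enough along its
axis that round structures lose to the spot filter by a factor ~1.8, the
classified core grows to ~2.3 px radius, and planted-truth recovery becomes
near-exact. The factor remains a parameter of `enhance_fibers()`.

Thresholding is **relative**: a pixel survives if its response reaches
`fraction x mean(raw actin intensity over the cell mask)`. The reference is
deliberately the raw frame, not the response map (the two coincide on
uniform images because all kernels sum to one). There is no universal
threshold fraction — in practice it is calibrated per experiment and held
fixed across conditions within it — so the defaults (foci 1.3, fibers 1.1)
are starting points, recorded in every run's provenance.

Candidate foci are pixels of the thresholded spot mask where the spot
response **strictly** exceeds the ridge response (ties count as fiber).
8-connected components smaller than `min_focus_area_px` (default 4) or with
second-moment-ellipse axis ratio above `max_elongation` (default 3) are
removed; component moments carry a 1/12 px pixel-extent correction so a
single pixel is round by definition and a 1-px line of length L has ratio
~L. Fibers are the thresholded ridge response minus all focus pixels, so
the two masks are disjoint by construction and both live inside the cell
mask.

Cells themselves are segmented once, on a median-smoothed first frame, by
Otsu's threshold plus hole filling; every connected region above
`min_cell_area_um2` becomes a cell, with no further exclusion. The mask is
held fixed across the movie — cells at the analysis stage are spread and
stationary — which also keeps per-cell normalizations stable.

## Tracking and dynamics

Foci centroids (spot-response-weighted) are linked frame to frame by an
optimal one-to-one assignment (Jonker–Volgenant shortest augmenting path):
among matchings that use only pairs within the gate (`link_max_dist_nm`,
default 500 nm/frame), the linker maximizes the number of links and, among
those, minimizes total displacement. A greedy nearest-neighbour pass was
considered and rejected: on crossing configurations it fails to minimize
total displacement, which is the defining property of the linking step and
the one the test suite verifies against exhaustive enumeration. There is no
gap closing — a focus undetected for one frame ends its track — consistent
with the strict persistence filter: tracks shorter than two frames
(`min_track_frames`) are discarded before any statistic.

Per track, lifetime is `n_frames x frame_interval_s`, displacement is the
start-to-end centroid distance, and speed their ratio. Foci density is the
mean number of tracked foci per time point per 10 um^2 of cell area.

Because the persistence filter and the finite movie bias lifetimes, the
package provides a survivorship-corrected estimator
(`estimate_lifetime_mean()`): for an exponential lifetime with mean tau the
frame count is geometric with `p = 1 - exp(-dt/tau)`; conditioning on
surviving the filter shifts the distribution (memorylessly), and tracks
still present in the final frame are right-censored. The closed-form MLE
`p_hat = deaths / (deaths + sum(excess frames))` then gives
`tau_hat = -dt / log(1 - p_hat)`. On simulated geometric data with
realistic censoring the estimator is accurate to a few percent where the
naive mean is biased by tens of percent.

## Enrichment and colocalization

Enrichment of any channel in a structure is the mean intensity over the
structure mask divided by the mean over the whole synapse mask, so 1 means
indifference. The definition obeys an exact mixture identity — summing
`area_fraction x enrichment` over any partition of the cell gives 1 — which
the tests assert to 1e-9 as an internal-consistency check.

Object colocalization is center-overlap: the fraction of regions (foci or
fiber components) whose footprint contains at least one point-structure
center, and reciprocally the fraction of centers lying on region pixels.
Its null is built by re-placing the same number of structures, as discs of
the same equivalent radius, uniformly at random inside the same cell
without pairwise overlap (rejection sampling, 10,000-attempt budget), and
averaging the recomputed fractions over ten randomization runs (seeded,
bit-reproducible). Only the non-overlap constraint uses the disc footprint;
the overlap test itself uses centers, so the disc approximation to each
structure's true shape is immaterial to the measured fraction. Under
uniform placement the point-in-region fraction converges to the region's
area fraction of the cell, which the tests verify against the analytic
expectation at 1000 runs.

## Validating the segmentation like a human would

Automated detections are compared to manual annotations by greedy
one-to-one matching in ascending distance order, accepting a pair when
centers fall within 5 px and 1 frame (both inclusive; the tie-break is
lexicographic, so the report is deterministic). The true positive rate is
the percentage of reference (human) foci matched; the false positive rate
is the percentage of test (computer) foci unmatched. One-to-one matching is
the stricter reading of such a comparison and the one implemented; rates
are monotone in both tolerances, which the tests assert.

## Membrane pulling

DiI structures are local maxima of a difference-of-Gaussians band-pass
(core FWHM 325 nm, surround 2x) inside the cell, thresholded at 5 robust
SDs of the in-cell response, and excluded within a rim near the cell edge
(the edge itself is a strong band-pass feature). They are linked with the
same tracker as foci. To exclude preexisting membrane features that the
cell did not create, only *dynamic* structures count: a track that begins
after the first movie frame ("appeared") or whose net start-to-end motion
reaches `motion_threshold_px` (default 3 px — the quantitative cutoff for
"moved" is a package choice, exposed in the config). Each dynamic event is
associated with foci if its center ever lies on a detected focus pixel
during its lifetime, likewise with fibers; events touching both are
labelled `both` and counted in each category, with the `both` share also
reported separately. Summaries report events per um^2 of synapse per frame
and, for the efficiency comparison between the two structures, events per
um^2 of *structure* area.

## The synthetic scene generator

`generate_scene()` renders what the analysis assumes the microscope
delivers: a disc-shaped spread cell of uniform cytoplasmic background over
a dim exterior; static fiber segments as anisotropic Gaussian ridges; foci
born by a Poisson process at an areal rate (plus a steady-state initial
population), living exponential lifetimes discretized to frames, diffusing
with a small coefficient, and rendered as isotropic Gaussians of 325 nm
FWHM; a DiI channel with appearing bright events and preexisting static
blemishes; and camera noise as Poisson shot noise plus Gaussian read noise,
quantized to 16-bit integer digital numbers. Every structure is recorded in
ground-truth tables, and identical parameters (including the mandatory
seed) reproduce identical pixel arrays.

Default conditions, used by the tests and the acceptance script: 256 x 256
px at 100 nm/px, 200 frames at 100 ms, cell radius 8 um, mean focus
lifetime 3 s, diffusion 0.002 um^2/s, amplitudes giving peak SNR ~8, and a
birth rate of 0.05 /um^2/s giving a steady-state density of ~0.15 foci/um^2
(~30 concurrent foci). The density choice is deliberate: at the 325 nm /
100 nm px optical scale, spots closer than ~4 px merge into a single
detection, so fields several-fold denser (as inhibitor-free synapses can
be) are partially uncountable *by any detector at this resolution* — an
inherent property of the measurement, not of the implementation. Planted
ground truth is only a meaningful benchmark where planted structures are
individually resolvable, so the default sits below the crowding regime;
denser fields are one parameter away, with the expectation that recovery
degrades by the geometry just described.

Ground-truth placement of DiI events follows the same logic: events are
planted in the cell core (outside the detector's edge rim), at least 10 px
from co-occurring planted structures, and fiber-associated events sit on
isolated stretches of a single fiber, away from crossings — at a crossing,
two overlapping ridges genuinely look like a spot, and the "correct" label
would be ambiguous even for a human.

What the generator does **not** emulate: TIRF evanescent-field decay,
realistic PSF side lobes, photobleaching, flat-field error, fiber turnover
or bending, and focus intensity fluctuation. Passing recovery tests on
these scenes therefore demonstrates the correctness of the measurement
chain under its stated model, not robustness to every artifact of real
data — pre-corrected input is assumed throughout.

## Numerical choices and degenerate inputs

* Kernel radii are 3 sigma (4 sigma for rendered spots); kernels are
  unit-sum and odd-sized; convolution is FFT-based with mirror-reflected
  boundaries, matching a direct-sum oracle to better than 1e-9 relative.
* All coordinates are 1-based `[row, col]`; frame indices are 1-based.
  (Tabular interfaces and CSVs use these conventions throughout.)
* Response-map ties in the spot-vs-ridge competition go to fiber; threshold
  comparisons are inclusive (`>=`).
* Empty inputs degrade explicitly: constant images segment to zero cells;
  empty structure masks give `NaN` enrichment with a warning; empty
  reference or test sets give `NaN` rates; infeasible randomized placement
  errors, naming the cell.
* Filter scales below one pixel warn and degenerate toward identity.
* TIFF output is 16-bit unsigned integer (camera digital numbers) so
  round-trips are bit-exact; float TIFFs from other software are read with
  native values.

## Problem sizes

The test suite and the acceptance script run the full chain on a 256 x 256,
200-frame movie (~30 concurrent foci; about a minute of computation) plus a
set of 128 x 128, 16-30-frame fixture scenes; oracle-equivalence checks use
64 x 64 frames, and the tracking oracle enumerates matchings exhaustively
at up to 4 foci over 5 frames for 100 random instances. These sizes were
chosen so the whole validation runs comfortably on a laptop while leaving
every statistical check enough events to be sharp.

## Known limitations

* Foci denser than the crowding limit are undercounted by construction;
  the package reports what the filters can resolve.
* Sub-pixel localization is deliberately out of scope — centroids are
  response-weighted but no PSF fitting is performed.
* Fibers are quantified as mask area only; no filament tracing or per-
  filament statistics.
* The lifetime correction assumes an exponential (memoryless) lifetime; a
  strongly non-exponential turnover process would need a different
  survivorship model.
* The DiI detector is a generic band-pass blob finder; tubular membrane
  structures are detected by their bright core, not reconstructed.
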