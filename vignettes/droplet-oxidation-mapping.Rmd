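---
title: "Per-droplet spatiotemporal mapping of lipid and protein oxidation"
author: "dropOx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-droplet spatiotemporal mapping of lipid and protein oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement

Oil-in-water emulsions such as mayonnaise oxidize heterogeneously: lipid
radicals accumulate inside dispersed oil droplets while proteins oxidize
at the oil-water interface and in the continuous aqueous phase.
Confocal time-lapse imaging resolves this spatially with three channels
per field and day:

* **red** (ex 640 nm) — the non-oxidized form of a radical-sensitive
  lipophilic dye (BODIPY 665/676) inside droplets;
* **green** (ex 561 nm) — the oxidized, emission-shifted form of the same
  dye;
* **blue** (ex 488 nm) — intrinsic autofluorescence of oxidized proteins.

The per-droplet degree of lipid oxidation on a given day is the
ratiometric statistic

$$R = \frac{\bar I_G}{\bar I_G + \bar I_R},$$

the green mean over the droplet's pixels divided by the summed green and
red means. Because the dye converts red into green, $R$ runs from 0
(non-oxidized) to 1 (fully shifted) and is invariant to a common gain on
both channels. Protein oxidation is read as the mean blue intensity over
the droplet mask (interface) and over the mask complement (aqueous
phase), in photons per pixel.

Each droplet's time series is fitted with the Gompertz growth curve

$$f(t) = a\,e^{-b\,e^{-ct}},$$

with asymptote $a$, displacement $b$, and growth rate $c$ (day^-1^). The
rate $c$ is the *local oxidation rate*: $c_\mathrm{lip}$ from the lipid
ratio, $c_\mathrm{prot}$ from the interface blue signal. Formulation and
droplet-size effects are then tested with an ANCOVA,

$$c = \mu + \alpha_\mathrm{formulation} + \beta\,(1/r) + \varepsilon,$$

with the formulation as a categorical factor (reference coding,
homogeneous slopes) and the inverse droplet radius as a continuous
covariate, at $\alpha = 0.05$. The factor is tested by the
extra-sum-of-squares F against the covariate-only model; within-group
simple regressions of $c$ on $1/r$ give the per-formulation size effect.
The $1/r$ covariate encodes the surface-to-volume argument: smaller
droplets expose relatively more interface.

# Pipeline stages

`runPipeline()` executes, per field: segmentation, spot detection and
tracking, label assignment, quantification, kinetics, then pools fields
for statistics.

**Segmentation** (`segmentDroplets`). The red channel is
percentile-normalized (1 / 99.8 by default) to `[0, 1]`, smoothed with a
1 px Gaussian, thresholded at 0.5, hole-filled, and split into touching
droplets by a watershed on the distance transform (seed separation 5 px).
Regions with equivalent radius outside `[2, 40]` px and droplets touching
the field border are removed; labels are renumbered by decreasing area.
This is a deterministic classical replacement for a pretrained
star-convex segmentation network with the same contract (an integer label
mask): droplets are bright, near-circular, high-contrast objects, and a
reproducible segmenter needs no trained weights. The 0.5 threshold echoes
such networks' probability threshold and is configurable.

**Tracking** (`detectSpots`, `linkTracks`, `filterTracks`,
`assignLabels`). Spots are maxima of a negated Laplacian-of-Gaussian
response at scale $\sigma = d/(2\sqrt2)$ for blob diameter $d = 14$ px
(the scale that maximizes the response of a disk of diameter $d$), after
an optional 3x3 median filter, with quadratic sub-pixel refinement and
non-maximum suppression at radius $d/2$. All positive-response maxima
above an adaptive floor — 2% of the frame's maximum response — are kept;
the floor removes the near-zero side-lobe maxima a sharp-rimmed disk
produces under the LoG and is not an absolute intensity threshold.
Frames are linked by a linear assignment problem with
squared-displacement costs; links beyond 15 px are inadmissible, and
birth/death alternatives are priced at 1.05 x the *maximum* admissible
cost. (Pricing at a lower quantile, e.g. the 90th percentile, severs any
genuine link costing more than 2.1 x that quantile — with squared costs
this cuts the jitter tail of real displacements, so the maximum-cost
convention of the established LAP trackers is used; both knobs are in
`trackingParams()`.) A second assignment joins track ends to later
starts within 2 skipped frames and 15 px (gap closing). Tracks with
fewer than 10 spots (i.e. "above 9.9") are then discarded, which on a
10-day grid keeps droplets present every day; gap-closed tracks are
inspected before this filter. Finally each spot inherits the
segmentation label under its rounded position; when two trajectories
claim one label on a day, the spot nearer the label centroid wins and
the loser records a gap.

**Quantification** (`assembleTimeSeries`). Channel means are taken over
exactly the labeled pixels; the aqueous mean over the exact mask
complement, one number per field and day. Intensities are reported raw
(photons per pixel) by default. A constant-background subtraction is
exposed (`subtractBackground`) and is used for the *rate fits*: the
three-parameter Gompertz curve has no offset term, so fitting a series
sitting on a nonzero baseline biases $c$ downward, most visibly for
weak protein signals. Reported intensities stay raw; only the fitted
series are baseline-corrected when the background is known.

**Kinetics** (`fitGompertz`). Bounded Levenberg-Marquardt least squares
with an explicit, reproducible initialization: $a_0 = 1.05\max y$;
$c_0$ from the slope of $\log(-\log(y/a_0))$ against $t$ over the rising
part of the curve ($0 < y < 0.9\,a_0$; the inflated $a_0$ distorts the
saturated tail, so the tail is excluded), fallback 0.5 day^-1^; $b_0$
from the earliest rising point. If the solver rejects the start
(near-singular gradient for curves whose rise is barely sampled), a
small grid of alternative rates (0.25, 0.75, 1.5, 3 day^-1^) is tried
and the best residual kept. The rate is bounded to `[1e-4, 10]` day^-1^;
fits pinned at a bound or not converged are excluded from statistics,
per signal, and counted in the exclusion log. Fits need at least 4
points by default (3 parameters + 1; `minPoints` is exposed down to 3,
where the fit is exactly determined).

# The synthetic-data generator

`generateField()` renders ground-truthed acquisitions: hard,
non-overlapping disk droplets (rejection-sampled with a 2 px edge gap;
placement aborts with the achieved count if the field is too crowded),
radii uniform in 1.5-2.5 um by default — the tracked population of the
emulsions being emulated (mean ~2 um with ~0.3-0.5 um spread; the full
detection range extends to 4 um, but droplets much larger than the 14 px
blob diameter are not what the tracker is tuned for). Rims are
anti-aliased by 4x supersampled area coverage, since 7-10 px radii need
sub-pixel rims for realistic segmentation tests.

Per droplet and day $t$: the lipid dye pool `lipidTotalIntensity`
(150 photons/px) is split red/green by the droplet's own Gompertz
fraction $g(t)$, so red + green is conserved over time by construction;
the blue channel is the droplet's interface-protein Gompertz curve
inside the mask (painted over the whole disk, matching a whole-mask
readout; a ring-only mode exists for sensitivity studies) and a separate
continuous-phase kinetic outside. Per-channel constant backgrounds
(2 / 2 / 1.5 photons/px) are added everywhere, and every pixel is a
Poisson draw around its expectation — all channels are photon counts,
matching counting statistics. Droplet centers random-walk by at most
`driftPxPerDay` between days (clamped inside the field), and droplets
can be undetectable on interior days with probability `dropoutProb`
(capped by `dropoutMaxDays`; first and last days are spared so that a
trajectory's identity stays observable end-to-end — transient detection
failure, not coalescence, is what this emulates). Identical seeds give
identical stacks.

**Formulation presets.** `scenarioPreset("I" | "II" | "III")` encode the
three analyzed formulations, calibrated so the noise-free medians land on
the study's printed endpoints: day-10 lipid ratios of 0.39 / 0.32 / 0.85
for I / II / III, and interface-protein trajectories that are near-flat
around 2 photons/px (I), rise early from 2.5 to ~5.8 (II), or stay at
1.8-1.9 through day 4 and reach 7.5 by day 10 (III) — all raw values
including the 1.5 photons/px blue background. Protein rates carry a
size-coupling slope of 0.5 day^-1^ um in every preset; lipid rates are
size-coupled only in preset II (0.12 day^-1^ um), following the result
that only that formulation showed a significant lipid size dependence.
The day grid is 1..10. Preset runs use 240 droplets per 512 px field and
two fields per formulation (~480 tracked droplets per group, the order of
the tracked populations in the study); a 512 px field cannot hold the
study's full per-field droplet count without overlap, so numbers per
field are desk-scale and fields are replicated instead.

What the generator does **not** emulate: optics (no PSF, no 3-D
sectioning), droplet coalescence or breakage (dropout is the only
disappearance mechanism), dye exchange between droplets, bleaching, and
segmentation-level shape irregularity — droplets are ideal disks.
Passing tests therefore demonstrate correctness of the algorithms under
the stated image model, not robustness to every property of real
micrographs.

# Numerical choices and degenerate inputs

* Coordinates are 1-based `(row, col)` with pixel centers at integer
  coordinates, consistently across generator, segmentation and tracking.
* Percentile normalization errors on constant images ("degenerate
  contrast") rather than guessing a scale; an empty label mask is a
  valid segmentation result.
* The LAP solver is an exact $O(n^3)$ Jonker-Volgenant implementation
  (no assignment-solver dependency); forbidden entries use a large
  finite cost, and dummy-dummy blocks cost zero.
* `oxidationRatio` is `NA` when both channels are zero; negative
  intensities are rejected.
* Gompertz fits flag all-equal series as non-converged; convergence uses
  the solver's relative tolerances (`ftol 1e-15`, `ptol 1e-12`,
  <= 500 iterations).
* ANCOVA refuses single-group or constant-covariate designs with
  explicit diagnostics; results are invariant to group relabeling by
  construction of the F-test.
* Ties in detection (plateau maxima) are resolved by the d/2 suppression
  radius, keeping the stronger response.

# Known limitations

* **Global threshold vs heterogeneous brightness.** Late in oxidation
  the red channel dims per droplet at different rates; with a global
  percentile anchor, the dimmest droplet can fall below the fixed 0.5
  threshold (about 1 droplet-day in 200 at the default kinetic spread).
  Fidelity fixtures therefore use homogeneous kinetics; in
  heterogeneous runs an occasional missed day is absorbed by gap
  closing.
* **Rim re-discretization under drift.** The mask's rim pixel set
  changes as centers move, modulating per-mask means by a few percent
  for 100-200 px droplets; conversion-conservation checks use zero-drift
  scenes (the generator-level pixel-sum conservation holds regardless).
* **LoG scale mismatch.** Droplets much larger than the configured blob
  diameter yield ring-shaped response maxima offset from center; the
  default radius range keeps droplets near the 14 px scale.
* Protein curves with tiny amplitude relative to photon noise produce
  noisy $\hat c$; such fits are retained unless non-converged, and
  medians/regressions over hundreds of droplets are the intended
  estimands.
* No multiple-testing correction is applied; the report labels each test
  so users can adjust downstream.

# Problem sizes used in checks

Parameter-recovery and calibration checks run at deliberately chosen
desk scales: 100 noiseless parameter draws; two 200-droplet fields for
noisy rate recovery; a 20-droplet field for segmentation fidelity; 50
droplets with 5 px/day drift and 5% single-day dropouts for tracking
identity; 200 replicates for the type-I calibration; and the three
presets at two 240-droplet fields each for the end-to-end formulation
study. These sizes are stated here as the package's reference
conditions; all are reproducible from `scripts/acceptance.R`.
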