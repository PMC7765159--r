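# dropOx

Per-droplet spatiotemporal analysis of lipid and protein oxidation in
oil-in-water emulsions, from multi-day three-channel confocal image
series.

Emulsified foods (the motivating system is mayonnaise) oxidize
heterogeneously: a radical-sensitive lipophilic dye (BODIPY 665/676)
reports lipid oxidation inside each oil droplet by shifting its emission
from the red channel (ex 640 nm, non-oxidized) to the green channel
(ex 561 nm, oxidized), while oxidized proteins autofluoresce in the blue
channel (ex 488 nm) at the droplet interface and in the continuous
aqueous phase. dropOx turns such image series into per-droplet oxidation
kinetics and formulation statistics:

1. **Segmentation** — percentile normalization (1 / 99.8), fixed 0.5
   threshold, distance-transform watershed; per-day integer label masks
   with sub-pixel centroids and equivalent radii.
2. **Tracking** — Laplacian-of-Gaussian spot detection (blob diameter
   14 px, sub-pixel), linear-assignment linking (15 px max displacement)
   with gap closing (≤ 2 skipped frames), and a ≥ 10-spots track filter;
   trajectory identities are re-assigned onto segmentation labels.
3. **Quantification** — per droplet and day, the lipid oxidation ratio
   `R = I_G / (I_G + I_R)` (0 = non-oxidized, 1 = fully shifted) and the
   mean blue intensity over the droplet mask; per field and day, the
   aqueous blue mean over the inverted mask (photons/pixel).
4. **Kinetics** — each droplet's series is fitted with the Gompertz
   curve `f(t) = a exp(-b exp(-c t))`; the growth rate `c` (day⁻¹) is
   the local oxidation rate (`c_lip`, `c_prot`).
5. **Statistics** — ANCOVA of rate on formulation (categorical) plus
   inverse droplet radius `1/r` (continuous covariate, day⁻¹·µm), with
   extra-sum-of-squares F for the formulation and within-group
   regressions of rate on `1/r` (α = 0.05).

A first-class synthetic-data module (`scenarioConfig`, `scenarioPreset`,
`generateField`) renders ground-truthed acquisitions — non-overlapping
anti-aliased disk droplets, conserving red+green conversion, Poisson
photon noise, inter-day drift, optional dropouts — so every stage is
verifiable without real microscopy data. Presets `"I"`, `"II"`, `"III"`
emulate the three studied formulations (soybean oil; soybean oil +
ascorbic acid; stripped soybean oil).

## Worked example

```r
library(dropOx)

sc  <- scenarioPreset("III", fieldPx = 256L, fieldUm = 61.5,
                      nDroplets = 25L, seed = 7L)
sim <- generateField(sc)
sim$field
#> FieldSeries: 10 day(s) x 3 channels, 256 x 256 px (0.2402 um/px)
#>   day times: 1, 2, 3, 4, 5, 6, 7, 8, 9, 10

res <- analyzeField(sim$field, group = "III",
                    subtractBackground = c(red = 2, green = 2, blue = 1.5))
d <- res$timeseries$droplets
length(unique(d$trajectory))
#> [1] 25
median(d$ratio[d$day == 10])
#> [1] 0.853
head(res$rates[, c("trajectory", "radius_um", "c_lip", "c_prot")], 4)
#>   trajectory radius_um c_lip c_prot
#> 1          1      2.06 0.482  0.617
#> 2          2      1.39 0.505  0.667
#> 3          3      1.62 0.460  0.648
#> 4          4      1.80 0.477  0.652

withinGroupRegression(res$rates, "c_prot", "III")
#> Group III, c_prot ~ 1/r: slope = 0.3377 /day/um (se 0.102), t = 3.31, p = 0.00307, n = 25
```

All 25 droplets are tracked over the 10 days. The median day-10 lipid
ratio of 0.85 says the stripped-oil droplets are almost fully oxidized
by day 10. The fitted local rates sit near the preset's true values
(`c_lip` ≈ 0.5 day⁻¹), and even at this small scale the protein rate
shows its positive dependence on the inverse radius (slope ≈ 0.34
day⁻¹·µm at n = 25; the full two-field runs at ~480 droplets per
formulation resolve it at p < 1e-4).

`runPipeline()` accepts several fields/scenarios with group labels,
pools the rates, runs the ANCOVA and regressions, and optionally writes
all tables (droplet and field time series, rates, statistics report,
exclusion log) as CSV. `writeFieldSeries()` / `readFieldSeries()`
round-trip image series as multi-page TIFF (day-major, channel-minor,
16-bit) with a YAML sidecar. A command-line wrapper for simulated runs
is in `inst/scripts/run_pipeline.R`.

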