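# puncta

Quantification toolkit for the imaging and screening readouts of
biomolecular condensate biology. It targets labs studying phase-separating
proteins (the motivating system is an oncogenic transcription-factor fusion
forming nuclear condensates in renal cell carcinoma) who need the
bespoke measurements of that field as tested, scriptable code rather than
ad-hoc ImageJ macros:

* **LacO/LacI tethering assay** — a LacI-GFP bait is tethered at a LacO
  array, producing one bright punctum; recruitment of an mCherry-tagged
  partner is scored by the enrichment ratio
  `Ipeak / Iperiphery`, where `Ipeak` is the mean of the four neighbors of
  the smoothed-mCherry maximum inside the punctum disk and `Iperiphery` the
  mean of the smoothed-mCherry radial profile at the two annuli just
  outside the punctum radius. The radius itself comes from the GFP radial
  profile: the first distance at which the derivative of intensity with
  respect to distance is no longer negative. A ratio above 1 indicates
  recruitment.
* **Droplet quantification** — Otsu thresholding, 8-connected labeling,
  per-droplet areas and morphometrics, bilinear line profiles, and
  object-based co-condensation efficiency (fraction of reference droplets
  with ≥50 % area overlapping the partner channel).
* **FRAP** — percent-recovery normalization
  `100·(I − Imin)/(I0 − Imin)` (background-subtracted; `I0` = pre-bleach
  mean, `Imin` = intensity at the bleach frame) and a single-exponential
  fit `R(t) = 100·M·(1 − e^{−kt})` giving the mobile fraction `M` and
  half-time `t½ = ln2/k`.
* **Pooled CRISPR screens** — depth normalization to reads per 100,000,
  per-sgRNA `log2((Tlate+1)/(T0+1))`, median gene scores, and partition of
  depleted genes into shared vs. cell-line-specific candidates.
* **Synthetic-data generators** with exact ground truth for all of the
  above (Gaussian puncta in two-channel z-stacks, disk droplet fields,
  exponential FRAP traces, negative-binomial screen counts), used to
  validate every estimator.

## Worked example

```r
library(puncta)

# a synthetic tethering scene with true mCherry co-enrichment
scene <- make_laco_scene(punctum_spec(amplitude_mch = 60, seed = 42))
measure_enrichment(scene, r_max = 12)
#> Punctum measurement: slice 5, center (48, 48), radius 12 px (truncated)
#>   Ipeak = 66.6252, Iperiphery = 20.0203, ratio = 3.3279 -> interacting (ratio > 1)
```

The pipeline picked the punctum slice (z = 5), localized the center,
estimated the punctum radius from the GFP profile derivative (truncated at
`r_max` here, as expected for a noisy Gaussian spot), and measured a 3.3-fold
mCherry enrichment over the periphery — correctly calling the simulated
interaction (the scene was built with partner amplitude 60 over background
20).

```r
# FRAP: recover mobility parameters from a noisy trace
tr <- make_frap_trace(frap_spec(mobile_fraction = 0.6, rate_k = 0.1,
                                noise_sd = 2, seed = 1))
fit_recovery(normalize_frap(tr))
#> FRAP fit: mobile fraction 0.608, k = 0.1046 /s, t1/2 = 6.63 s

# droplets: object-based co-condensation against generator truth
fld <- make_droplet_field(droplet_field_spec(overlap_fraction = 0.6, seed = 3))
cc <- co_condensation_efficiency(segment_droplets(fld$channel_a),
                                 segment_droplets(fld$channel_b))
cc$efficiency
#> [1] 0.5833333   # exactly the fraction of droplets painted in both channels
```

Both estimates sit on top of the generating truth: the fitted mobile
fraction 0.608 and rate 0.105 /s versus true 0.6 and 0.1 /s, and the
co-condensation efficiency equals the painted overlap fraction (7/12).

A command-line front end wraps the same functions:

```sh
inst/cli/puncta simulate laco --out-dir scenes --seed 7 --n 10
inst/cli/puncta laco --gfp scenes/scene_001_gfp.tif \
                     --mch scenes/scene_001_mch.tif --out enrichment.csv
inst/cli/puncta tumor-volume --length 10 --width 8   # -> 332.8 mm^3
```

Every stage writes its resolved configuration and a timestamp-free log next
to its outputs, so re-running with the same seed reproduces results byte
for byte.

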