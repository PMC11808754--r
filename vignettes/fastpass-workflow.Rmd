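---
title: "Single-raster DESI-MSI line-scan screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-raster DESI-MSI line-scan screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastpass)
```

## The measurement model

Desorption electrospray ionization mass spectrometry imaging (DESI-MSI)
normally rasters a surface row by row to build a 2-D ion image.  For
screening applications the spatial information that matters is much
smaller: when samples are deposited at known positions along a linear
spot array, a *single* raster line over the array already resolves every
sample.  The line-scan is then projected like a liquid-chromatography
run, with the retention-time axis replaced by physical distance: each
pixel (acquisition frame) pairs a distance coordinate with a full mass
spectrum, total and extracted ion traces (TIC/XIC) are drawn against
distance, and integrating a trace across a spot's declared interval
gives that sample's signal.

`fastpass` implements this pipeline: reading and writing line-scan data
(processed-mode imzML, optionally mzML), lock-mass correction and
spatial normalization, spot integration, the spot-to-blank signal-ratio
statistic used to optimize the raster rate, formula-driven annotation,
and the downstream screening statistics (replicate %CV, PCA, volcano).
A seeded synthetic line-scan generator stands in for instrument data so
every stage is testable end to end.

### Coordinates and spot intervals

Distances are 0-based physical positions in µm measured at the pixel
start; a spot covers the half-open interval
`[center - width/2, center + width/2)`.  Half-open intervals make
integration windows a partition: no pixel can be counted in two
adjacent regions.  The transverse pixel dimension (1 mm on the
instrument this design mirrors) has no effect in a 1-D model and is
carried as metadata only.  `default_layout()` reproduces the standard
slide: 11 spots of 3 mm diameter spanning 50 mm edge-to-edge, which
leaves 1.7 mm gaps between adjacent spot edges.

## The synthetic line-scan generator

The simulator emulates the features of real line-scan acquisitions that
the downstream methods are sensitive to; it is not a physical model of
droplet drying or the DESI plume.

**Intra-spot distributions.**  Dried droplets are heterogeneous:
peptides enrich at the spot margins (the familiar coffee-ring effect),
carbohydrates concentrate at the center, small exogenous molecules
spread roughly evenly.  Three profile shapes encode this:
`ring` (a symmetric pair of truncated Gaussians at |u| = 0.85, sigma
0.1, on the normalized intra-spot coordinate u in [-1, 1]), `center`
(truncated Gaussian at u = 0, sigma 0.35) and `uniform`.  The source
descriptions are qualitative; the Gaussian parameterizations are this
package's concrete choice.  Each profile is normalized to integrate to
1 over the spot, so an analyte's total deposited intensity depends only
on its base intensity and the pixel count, not on its shape — the
conservation property the tests assert.

**Rate response.**  DESI is continuously ablative, so the signal
collected in a pixel scales with the dwell time `pixel_size / rate`:
`signal_factor = (reference_rate / rate)^signal_exponent`, with
exponent 1 by default.  Delocalized signal — analyte smeared outside
its spot by the moving ablation plume — behaves differently: its
*dwell-normalized* intensity drops by `delocalization_drop` (default
60%) linearly between the slowest rate (50 µm/s) and a knee rate
(125 µm/s), and is flat beyond the knee.  The raw delocalized intensity
deposited per out-of-spot pixel is therefore
`base * delocalization_level * signal_factor * delocalization_factor`:
the dwell-time factor applies to everything the spray collects, and the
knee-shaped factor multiplies it.  The spread is spatially uniform over
all non-sample pixels (gaps and blank spots).  Whether carryover is
symmetric or trails the scan direction is not established by the
measurements this mirrors; uniformity is the simplest defensible
choice and is isolated behind `rate_response_model()`.

**Noise.**  Every recorded m/z channel of every pixel receives additive
Gaussian noise `N(baseline_level, baseline_dispersion)` with the total
clipped at zero (defaults 20 ± 5 counts against analyte deposits of
10^3–10^5).  Optional mass jitter perturbs each recorded m/z by a
ppm-scale Gaussian.  No distributional form is claimed by the source
material; clipped Gaussian channel noise is the simplest model that
exercises the XIC, blank-subtraction and %CV code paths.  The RNG is
seeded once per run and draws occur in pixel order, making runs
bit-for-bit reproducible — a property the suite asserts.

**What the simulator does not emulate** (and hence what passing tests
do not show about real data): chemical background with structured m/z,
ionization suppression between co-deposited analytes, detector
saturation, profile-mode peak shapes, spray instability beyond the
smooth drift that spatial normalization removes, and 2-D effects.

## Raster-rate optimization

The optimization statistic is the signal ratio: per-pixel mean analyte
intensity inside a sample spot divided by the per-pixel mean in a
reference region.  Per-pixel means are used rather than raw sums so
regions of different lengths are comparable.  Two reference definitions
are implemented — solvent-blank spot intervals (default) and inter-spot
gaps — because the operational descriptions of the "noise" region in
the source material differ between the two; the choice is a
configuration flag rather than a resolved question.

Under the default rate-response model the closed-form expected ratio is

```
ratio(r) = (B * s(r) * w + c) / (B * L * s(r) * d(r) + c)
```

with `s` the signal factor, `d` the knee-shaped delocalization factor,
`w` the mean profile weight (0.5), `L` the delocalization level, `B`
the base intensity and `c` the noise baseline.  Up to the knee the
denominator falls faster than the numerator (both carry `s`, and `d`
drops 60%), so the ratio rises; past the knee `d` is constant and the
noise floor's relative weight grows, so the ratio decays.  The optimum
therefore sits exactly at the knee — an interior maximum at 125 µm/s on
the default 50–225 µm/s, 25 µm/s-step, eight-rate grid.  Remove the
knee (`delocalization_drop = 0`) and the optimum collapses to the
slowest rate; `signal_ratio_theory()` evaluates this closed form so the
stochastic sweep is always cross-checked against it.  Exact ties are
broken toward the faster rate, throughput being the secondary
objective.  At 125 µm/s the timing arithmetic gives 440 s for a 55 mm
line and 40 s per sample for 11 samples (`acquisition_time()`,
`per_sample_time()`).

The sweep grid itself (50–225 in steps of 25) is a reconstruction: the
endpoints follow from the printed acquisition-time range (16.67 min at
50 µm/s and 3.70 min at 225 µm/s over 50 mm) and the count of eight
evaluated rates; it remains configurable.

## Processing choices

**Lock-mass correction** uses the leucine enkephalin species present in
the spray (reference m/z computed from C28H37N5O7 per polarity, never
hard-coded).  The correction is a single multiplicative factor per
pixel — adequate for the few-ppm drift regime; no polynomial
recalibration is attempted.  Pixels with no detectable lock peak
inherit the nearest pixel's factor, and a run is rejected when coverage
falls below 90%.

**Spatial normalization** divides each pixel by the lock trace scaled
to unit mean, after a 5-pixel moving median that prevents single-pixel
dropouts from being amplified.  Per-pixel normalization is the
implemented default; the arithmetic is idempotent and preserves
spot-to-spot ratios whenever the lock channel is flat.

**Feature detection** pools all recorded peaks, clusters m/z by
single-linkage along the sorted axis at 10 ppm, and ranks features by
total integrated intensity across sample spots, retaining the top 500
by default ("most abundant" is defined as the integrated total, not the
maximum pixel).  **Blank subtraction** removes the media-blank row
column-wise with a floor at zero; **analyte normalization** scales each
feature column by its own maximum.

**Annotation** applies the dual threshold of 5 ppm mass error and 0.8
isotopic-envelope similarity.  The similarity metric behind the "80%"
criterion is not specified by the source material; cosine similarity
over the first three matched isotopologues is used for its scale
invariance, and the matching tolerance is configurable.  Envelopes are
computed by convolving elemental isotope distributions (aggregated by
nominal mass shift), and adduct m/z arithmetic includes the electron
mass — a sub-ppm effect, but material within a 5 ppm budget.

**Statistics.**  Replicate reproducibility is the mean per-feature %CV
(sample standard deviation over mean) within replicate groups, computed
on raw integrated signals — blank subtraction would cancel channels
shared with the blank (the spiked internal standard foremost) and leave
only noise there — and restricted to features actually detected in the
group (group mean at least 5% of the feature's maximum group mean).
The volcano analysis uses Welch's t-test on log2-transformed
intensities with the joint rule p ≤ 0.05 and |fold change| ≥ 2 on raw
p-values; the source thresholds are raw, so no multiple-testing
correction is applied by default (Benjamini–Hochberg by flag).  Fold
changes are computed on blank-subtracted, pre-normalization intensities
with a pseudocount guarding zero means.  PCA is mean-centered (scaling
optional) on sample-role rows.

## Validation design and problem sizes

All empirical claims in the test suite are computed by the suite
itself, on simulated data:

* oracle equivalence of spot integration and signal ratio against
  explicit brute-force loops on 1000+ random traces, and of top-N
  prioritization against a brute-force sort;
* planted-truth recovery: annotation recall of five planted fatty
  acids against a 50-compound decoy panel at 2 ppm mass jitter;
  volcano recovery of ten planted 4-fold features at 3-vs-3 replicates
  and 5% multiplicative noise; PCA separation of three planted strain
  profiles with positive silhouette;
* a planted 10 ppm calibration shift recovered to below 0.1 ppm;
* localization and conservation of deposited signal, and replicate %CV
  below 10% at 5% multiplicative noise.

The bundled strain-screen fixture uses a 10-spot, 50 mm array (three
strains × three replicates plus a media blank) at 50 µm pixels — 1000
pixels per run; the sweep uses the 11-spot, 55 mm array (1100 pixels)
with six sample-spot replicates; the feature-prioritization check
plants 600 species (1800 isotopologue channels) in one run.  These
sizes keep the full suite under a minute on a laptop while leaving
every code path exercised at realistic channel counts.

## Known limitations

* The delocalization amplitude (`delocalization_level = 0.05`) is a
  modeling constant chosen to sit well above the noise floor at the
  fastest simulated rate; real delocalization varies by analyte class
  and surface.
* Profile-mode data are handled only via local-maximum-style windowed
  summation in XICs; there is no centroiding algorithm or m/z-domain
  baseline subtraction.
* Titers are relative; no calibration curves or absolute quantitation.
* Annotation is mass-plus-envelope only — no MS/MS scoring, and no
  online database search; the compound panel is local and explicit.
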