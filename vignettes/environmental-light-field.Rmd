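---
title: "Measuring environmental light fields: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring environmental light fields: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elfr)
```

## Why photon radiance by elevation angle

Eyes measure radiance — light arriving at the observer from each
direction — not the illuminance that falls on surfaces, and biological
photoreceptors count photons rather than integrate energy (across the
visible band, 400 to 700 nm, the energy per photon differs by 75%, so
the distinction matters). `elfr` therefore works in photon radiance,
photons s⁻¹ m⁻² sr⁻¹ nm⁻¹, and reports its log₁₀ as the unit **lit**.
Typical values: sunlit outdoor scenes 16–18 lit, overcast 15–16 lit,
indoor lighting 13–16 lit, moonlight about 11 lit, starlight about
9 lit. Two decimal places suffice, since 0.01 lit is a 2.3% linear
change, near the threshold of perceptible contrast.

Light environments are strongly structured by elevation (sky above,
ground below, light sources overhead) and comparatively random in
azimuth. The pipeline therefore reduces each scene to statistics per
elevation bin, with azimuth serving as the sample over which those
statistics are taken. The descriptive unit is the *median* radiance
per bin — robust to bright sources covering few pixels — together
with *contrast-spans*: the widths, in lit, of the intervals containing
50% and 95% of a bin's pixel radiances.

## The camera model

`counts_to_radiance()` inverts a standard radiometric model,

\[ L = \frac{(\mathrm{counts} - \mathrm{black})\,K_{ch}}
            {t \cdot g_{ISO} \cdot g_{N}}, \]

with per-channel scale constants \(K_{ch}\), exposure time \(t\) and
relative gain tables for ISO and aperture. Choices a physical
calibration leaves open are fixed as follows:

* **Dark-noise floor.** After black-level subtraction, values ≤ 0 are
  clamped to 10⁻³ × the smallest positive radiance in the image, so log
  statistics stay finite; this mimics the noise floor of a real sensor
  and only affects pixels that carry no usable signal anyway.
* **Saturation.** Counts at or above 99% of the white level are flagged
  saturated. The threshold is conservative: real sensors go nonlinear
  slightly below full scale.
* **Gain tables.** ISO and aperture gains are exact-match lookups with
  a nearest-key fallback (with a warning), since cameras expose only
  discrete settings.
* **Vignetting.** Off-axis transmission \(V(\theta)\) is tabulated at
  10° steps per calibrated aperture and interpolated linearly in
  \(\theta\); correction happens in fisheye space, where \(\theta\) is
  native, before remapping. The apply-then-correct round trip recovers
  a flat field to well under 1% for smooth fall-offs.
* **EV.** One exposure value step is a factor 2 of exposure
  (3 EV = ×8), the photographic convention.
* Physical constants \(h\) and \(c\) are the CODATA 2018 exact values.

## Geometry

The supported projection is the equisolid fisheye law
\(r = 2f\sin(\theta/2)\), normalised so the 180° image circle rim is
\(\theta = 90°\). With the camera horizontal, the image equator is the
horizontal plane; elevation \(\varepsilon = \arcsin(\sin\theta\cos\psi)\)
and azimuth \(\varphi = \operatorname{atan2}(\sin\theta\sin\psi,
\cos\theta)\), where \(\psi\) is the position angle from image-up.

`remap_to_equirect()` inverts this mapping per output cell
(nearest-neighbour at the real-valued preimage of each cell centre), so
the remap is deterministic, hole-free, and never invents pixel values.
The output is square; row 1 is +90° (zenith), the central rows straddle
the horizon, and the default side length equals the image-circle
diameter, which preserves equatorial sampling density. Cell \((i,j)\)
covers a half-open angular interval with angles evaluated at cell
centres; the top bin is closed at +90°. Each scene covers the front
hemisphere (azimuth −90°…+90°), which is treated as the scene's full
azimuth sample.

Equirectangular rows near the poles stretch a small solid angle across
the full row — deliberately not solid-angle-corrected, since the
method's weighting is *by elevation angle*, not by solid angle. The
practical consequence is that pole bins repeat few distinct sensor
pixels many times, which matters for validation (below).

## HDR bracketing and merging

A bracket of three exposures 3 EV apart extends dynamic range by 2⁶ =
64. Merging is a two-step rule. First, `normalize_bracket()` removes
random inter-exposure differences by scaling each radiance-converted
exposure so its median (over pixels unsaturated in *every* exposure —
this restriction prevents saturation bias) matches the bracket average.
The average is the geometric mean of the per-exposure medians, chosen
because every downstream statistic lives in log space; an arithmetic
option exists (`reference = "arithmetic"`) and differs by under 1% for
well-calibrated brackets. Second, `merge_hdr()` assigns each pixel its
value from the highest-EV exposure in which it is unsaturated — hard
selection, not weighted blending. Pixels saturated everywhere keep the
lowest-EV value (a lower bound, analogous to saturation in the retina)
and are flagged in a mask that downstream statistics carry along.

## Statistics and aggregation

`bin_statistics()` computes, per 3° bin (60 bins) and per band — white
being the per-nm average \((R+G+B)/3\) formed per pixel before binning
— nine statistics: mean, sd, median, 25th/75th, 2.5th/97.5th
percentiles, min, max. Order statistics are computed on the linear
pixel population and converted to lit afterwards (a monotone transform,
so equivalent to computing on logs); percentiles use the type-7
estimator, fixed for reproducibility. The mean is converted to lit; the
standard deviation stays in linear radiance units because the log-width
of a linear spread is not well defined, and the column is documented as
such. Empty bins yield missing values, never zeros.

`aggregate_scenes()` combines scenes by the log-average
\(\bar{x} = 10^{\frac{1}{n}\sum\log_{10}x_i}\) for medians, percentiles
and means — so a scene that happened to be dimmer still contributes
equally, and scaling one of \(n\) scenes by \(c\) moves the aggregate by
exactly \(c^{1/n}\). Minima and maxima pool across scenes (extremes are
extremes); an aggregated standard deviation is not defined across
scenes and is reported missing. The display image is the per-pixel
geometric mean, tone-mapped only for display.

`simplified_summary()` condenses the table to the upper (+10°…+90°) and
lower (−10°…−90°) fields, ignoring the horizontal ±10° band: per field,
the equal-weight geometric mean of bin medians (in lit), the 95% span
from the geometric-mean bounds, and RGB percentages from the linear
per-field means of the band medians. Bins are assigned to fields by bin
centre, and bins are weighted equally rather than by solid angle,
consistent with the per-elevation weighting above.

## The synthetic-scene generator

`make_truth()` renders a ground truth the pipeline should recover:
per-band piecewise-linear profiles of lit versus elevation, multiplied
by a log-normal azimuthal texture \(10^{N(0,\sigma)}\) whose σ (in lit)
sets the contrast-span — the analytic 95% span is \(2 \times 1.96\sigma\)
lit. The texture field is shared across bands (scene texture is largely
achromatic), which keeps band and white spans identical and the ground
truth closed-form. Optional point sources apply
\(\max(\mathrm{scene}, \mathrm{source})\) within an angular radius.
Presets (`synth_preset()`) place a common sky/dark-horizon/ground shape
at the regimes listed above; "overcast" uses σ = 0.10 against 0.25–0.35
elsewhere, reproducing the collapse of contrast-span under overcast
skies. Rendering through the camera (`render_bracket()`) forward-maps
truth into the fisheye raster, applies vignetting, exposure scaling,
black level, clipping and integer quantisation; auto-exposure places
the scene median at 5% of the usable count range for the 0 EV frame.
All randomness is seeded from the scene spec, so fixtures are
bit-reproducible.

What the generator does *not* emulate: photon shot noise and read noise
(off by default so tests are deterministic), chromatic lens effects,
demosaicing artefacts, and physically based sky gradients in azimuth.
Passing tests therefore demonstrate the correctness of the calibration,
geometry, merging and statistics chain — not robustness to sensor noise
or to departures from the ideal equisolid law.

## Validation design and problem sizes

Every operation is tested against an independent oracle: closed-form
values for the unit conversions and the equisolid law, a brute-force
sort-based implementation for the bin statistics (exact agreement on
64 × 64 images), a Monte-Carlo population for the log-normal span
(≥ 10⁵ samples per bin), and end-to-end recovery of analytic truth
through the full render–analyse cycle.

Recovery accuracy depends on the sensor size through the pole bins:
near ±90° an equirectangular row resamples only the small fisheye cap
around the zenith/nadir, so the effective sample behind those bins
grows with the square of the image-circle radius. Quick unit tests use
a 100–200 px radius and check interior bins tightly; the acceptance
checks run a 1200 px radius (2400 × 2400 remap, matching a consumer
full-frame sensor's ~1600 px circle in spirit), where bin medians
recover analytic truth to better than 0.05 lit and 95% spans to better
than 10% at the widest supported texture, σ = 0.5, across *all* bins
including the poles. The constant-offset identity (two scenes differing
only by a uniform lit offset recover parallel curves) is tested with a
shared texture seed, isolating the pipeline's linearity from sampling
noise.

## Output conventions

Results serialise as a 60-row × 37-column table (bin-centre elevation,
then nine statistics × four bands in white/red/green/blue order) to CSV
(6 decimals, missing bins as empty cells) and to an XLSX workbook
written by a minimal built-in OOXML writer; environment workbooks add a
metadata sheet with the scene count. Radiance images are stored as
uncompressed 32-bit float TIFFs encoding lit/30 (so the natural 0–30
lit range fits the unit-interval float payload losslessly at this
precision) with small PNG previews. The standard chart —
laterally compressed image, main radiance-vs-elevation diagram with
50%/95% white-light envelopes, and normalised colour and contrast-span
panels — is drawn entirely from the results table (never recomputed
from pixels) and saved as editable PDF plus PNG, landscape, sized two
to an A4 page. The dashed guide levels (starlight 9, moonlight 11,
twilight 13, overcast 15.5, sunlight 17 lit) are arbitrary orientation
marks and configurable.

## Known limitations

* Only the equisolid projection is implemented; other fisheye laws
  would need their own radius–angle mapping.
* The calibration data model is provided, but performing a physical
  calibration (integrating sphere, spectroradiometers) is out of scope.
* Colour-science quantities (colour temperature, CRI) are deliberately
  not computed: the method characterises light reaching the eye, not
  the illuminant.
* Raw camera formats are expected as linear 16-bit TIFF plus a JSON
  metadata sidecar; decoding proprietary raw files is left to external
  converters.
* Pole-bin statistics at small sensor sizes are sampling-limited, as
  quantified above.
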