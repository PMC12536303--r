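---
title: "Inter-frame Doppler variance OCT angiography and epithelial morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-frame Doppler variance OCT angiography and epithelial morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octamorph)
```

## Scope

`octamorph` implements an OCT-angiography (OCTA) analysis chain for layered
skin and mucosa — vulvar tissue being the motivating application. From
repeated B-scans it computes intensity-based Doppler variance (IBDV) flow
contrast, projects en-face angiograms, and quantifies two kinds of
morphometry: microvascular (vessel density and diameter) and structural
(epithelial thickness between the tissue surface and the dermal–epidermal
junction, DEJ). Because clinical OCT volumes of this kind are not publicly
available, the package ships a synthetic speckle phantom with exact ground
truth; every processing stage is validated against it.

## The flow statistic

In the inter-frame protocol, J B-scans (default J = 6) are acquired at the
same slow-axis position, separated by ΔT (default 5 ms, the slow-scan
flyback time). Static tissue produces nearly identical speckle in
consecutive repeats; moving blood decorrelates it. Per voxel,

$$\sigma^2 \;=\; 1 \;-\;
\frac{\sum_{j=1}^{J-1} |A_j|\,|A_{j+1}|}
     {\sum_{j=1}^{J-1} \tfrac12\left(|A_j|^2 + |A_{j+1}|^2\right)}$$

where $|A_j|$ is the amplitude in repeat $j$. The denominator is the mean
power of each consecutive pair: this is the only normalization under which
identical frames give exactly $\sigma^2 = 0$ and the statistic is confined
to $[0, 1]$ (by the AM–GM inequality), and it makes $\sigma^2$ invariant
under global amplitude rescaling — so storage normalization, detector gain
and display scaling have no effect. Only amplitudes enter; complex input is
accepted and its modulus taken.

Two kinds of averaging are deliberately kept apart: **J counts repeated
frames** (the temporal dimension that carries flow information), while
spatial smoothing of the estimator is exposed separately as `window`
(lateral half-width, default 2, i.e. 5 A-lines) and `depth_window`
(default 1 inside `assemble_volume()`, 0 in the bare `compute_ibdv()`).
Numerator and denominator are each box-summed over that neighbourhood
*before* the ratio, which is the variance-reducing order of operations.
Voxels with zero denominator (no signal at all) are defined as
$\sigma^2 = 0$: no signal is treated as no measurable flow, and such voxels
are in any case removed by the intensity mask.

Decorrelation of the noise floor would otherwise read as flow, so
`assemble_volume()` masks voxels whose mean amplitude over the J repeats
falls at or below a volume-wide quantile (`threshold_quantile`, default
0.25 — close to the air fraction above the tissue surface in a typical
scan). Masked voxels become `NaN` and are ignored by the projection;
`threshold_quantile = 0` keeps everything. The en-face angiogram is a
per-(x, y) maximum-intensity projection over a depth range, by default the
full depth below the shallowest detected surface.

## The synthetic phantom

`generate_speckle_frames()` emulates exactly the statistical structure the
IBDV estimator assumes, nothing more:

* **Fully developed speckle.** Each voxel carries a circular complex
  Gaussian field; its modulus is Rayleigh distributed (verified by a
  Kolmogorov–Smirnov test in the suite).
* **Temporal dynamics.** Consecutive frames mix as an AR(1) process on the
  complex field, $E_{j+1} = \rho E_j + \sqrt{1-\rho^2}\,E_\text{fresh}$,
  with $\rho$ = `static_correlation` (default 0.99) in tissue and the
  per-vessel `flow_correlation` inside vessels. The endpoints are exact
  ($\rho = 1$ freezes the speckle, $\rho = 0$ decorrelates it fully); at
  intermediate values the induced *amplitude* correlation is approximately
  $\rho^2$, which is monotone in $\rho$ — the property the validation
  relies on. $\rho$ is therefore documented as a mixing coefficient, not a
  calibrated amplitude correlation.
* **Geometry.** A two-layer medium (epithelium over dermis, reflectivities
  0.45 and 1.0) under a sinusoidally undulating surface; vessels are tubes
  of given radius around 3-D polylines, a voxel belonging to a vessel iff
  its centre lies within the radius (no anti-aliasing, so ground-truth
  pixel counting is exact). `dej_contrast` scales the reflectivity step at
  the DEJ; 0 reproduces the sclerosis-like case in which the boundary is
  physically absent.
* **Depth attenuation** is exponential in optical depth *below the local
  surface* (default 0.002 µm⁻¹), not below z = 0 — which is what makes
  surface undulation visible in the log-intensity slope and testable.
* **Noise floor.** An independent Rayleigh amplitude of scale
  `noise_floor` is added per frame, so air regions decorrelate completely.

The default grid is 128 A-lines × 256 depth pixels × 64 positions × J = 6
(40 µm lateral sampling over a square field, 5 µm axial pixels — the axial
pitch and A-line count are package choices, not measured properties), which
builds in a few seconds. What the phantom does **not** model: the lateral
point-spread function (speckle is voxel-independent, so real spatial
speckle correlation and resolution-limited vessel blur are absent), bulk
tissue motion, projection/tail artifacts under vessels, multiple
scattering, and refraction. Consequently, passing the recovery tests shows
the estimator and morphometry chain are correct under the stated model; it
does not certify accuracy on motion-corrupted or resolution-limited
clinical data.

## Vessel morphometry

The angiogram is first resampled to isotropic pixels (linear interpolation
along the coarser slow axis) because skeleton-based calliper measurements
assume square pixels. Enhancement is a multi-scale Mexican hat (negated
Laplacian of Gaussian), scale-normalized so different widths respond
comparably; `scales_um` are target vessel *diameters*, and the Gaussian
sigma for a scale is 0.75 × scale. That factor was chosen by analysing the
filter response to an ideal ridge: with σ ≈ 0.75 × width, the half-maximum
width of the response matches the ridge width, so a threshold near half
maximum reproduces vessel calibre without systematic bias. The defaults
`scales_um = c(160, 240)` were fixed once against drawn ridges and two
phantom geometries (density error within ±1.5 percentage points, Dice
overlap 0.83–0.96) and are configuration, not per-image tuning. Negative
flank responses are clipped and the result rescaled to [0, 1]; the response
to a constant image is identically zero.

Binarization uses Otsu's threshold on the enhanced image by default, with a
`fixed` threshold as an escape hatch; a degenerate constant image yields an
all-background mask with a warning rather than an error. Components below
`min_area_px` (default 5) are discarded. Vessel density is the percentage
of region pixels that are vessel — a plain count, checked in the suite
against a brute-force oracle.

Diameters automate a multi-point manual calliper: the mask is thinned to a
centerline (Zhang–Suen), and at every `sample_step_px`-th skeleton pixel
(default 10) the local diameter is twice the Euclidean distance-transform
value times the pixel pitch. Skeleton pixels closer to a skeleton endpoint
than their own radius are excluded so tapering ends do not bias the mean.
The 2 × EDT convention reads even widths exactly and odd widths one pixel
high — within the stated ±1 px accuracy of the method across widths
3–15 px.

## Epithelial thickness

`detect_surface()` takes the mean over the J repeats, estimates a noise
threshold from the shallowest `bg_rows` pixels (mean + k·SD, k = 4),
reports the first crossing of a trailing running mean per A-scan, and
median-filters across A-scans. Errors stay within 2 px on a strongly
undulating speckled surface.

`detect_dej()` is built for uneven tissue: A-scan log-amplitude profiles
are *aligned to the detected surface* before lateral averaging (13 A-scans
by default), so averaging sharpens rather than smears the boundary no
matter how the surface undulates. The attenuation slope is estimated by
least squares on a clean stretch *below* the search range (any DEJ must lie
within `max_offset_px` of the surface) and removed; a candidate depth is
scored by the difference of mean detrended log-amplitude over `step_w`
pixels below versus above it, with a guard gap of the smoothing half-width
so the smeared transition does not dilute the step. The winning candidate
is refined to the gradient-weighted centroid of the edge, and the per-scan
trace is median-filtered laterally. A detection is accepted only if its
step exceeds `min_contrast` (default 0.4 log-amplitude units): the full
epithelium/dermis step at the default reflectivities is
$\log(1/0.45) \approx 0.8$, while the largest spurious step produced by
pure speckle in contrast-free phantoms measures about 0.33 — the default
sits between the two with margin on both sides. Where no boundary is
detectable the DEJ is reported *missing*, a value rather than an error;
`dej_found_fraction` makes the failure mode quantitative, and with
`dej_contrast = 0` phantoms it is exactly 0 while full contrast gives
exactly 1.

Thickness per A-scan is `(dej_z − surface_z) × axial_spacing_um /
group_index`. The default `group_index = 1` reports raw optical thickness —
deliberately, so values are comparable with measurements taken directly on
B-scan images; set 1.4 (a typical epithelial group index) for geometric
thickness. The summary statistic is the **median** across A-scans, robust
to residual boundary outliers; A-scans whose DEJ does not lie below the
surface are set missing with a warning.

## Pipeline, report and conventions

`run_pipeline()` chains the stages per anatomical site (labia majora,
interlabial sulci, labia minora), producing one report row per site:
epithelial thickness everywhere, vessel density/diameter for the sites
configured in `vessels$sites` (default the labia minora). One master seed
drives everything; per-site phantom seeds are derived by fixed offsets, so
identical configurations produce byte-identical CSV reports. Any stage
failure leaves that row's cells missing and is recorded in the YAML
parameter log, which captures every effective setting for provenance.
Missing cells serialize as empty CSV fields and render as an em-dash.

The packaged reference table (`vulvar_morphometry()`) holds per-subject,
per-site published pilot measurements (8 subjects, 5 with vulvar lichen
sclerosus) verbatim, including its missing cells; `summarize_report()`
computes all ranges and counts from the stored cells by exact arithmetic
rather than copying any previously quoted aggregate, so its output is
internally consistent with the table by construction.

Conventions and numerical choices, in one place: indices are 1-based and
ranges inclusive (R convention) — the first index is the fast axis x,
then depth z, then repeat j, then slow axis y; thresholds are
strictly-above (with `threshold_quantile = 0` special-cased to keep all);
$\sigma^2$ is clamped to [0, 1] against floating-point excursions; volume
and angiogram I/O uses 32-bit multi-page TIFF with a YAML sidecar for scan
metadata and amplitude scale (the IBDV statistic is scale-invariant, so
the normalization required by the TIFF range is harmless).

## Validation problem sizes

The test suite and the acceptance script regenerate everything from code:
a 96 × 160 × 96 isotropic phantom with five tubes of radii 60–140 µm for
density/Dice/diameter recovery; drawn bars of widths 3–15 px for the
calliper sweep; 20 single-position phantoms with thickness drawn from
80–350 µm and undulation amplitude 0–60 µm for thickness recovery;
20 000-voxel Monte-Carlo draws for the IBDV mean; and two full pipeline
runs for determinism. These sizes keep a complete run in the order of a
minute or two while leaving every tolerance comfortably resolved by the
Monte-Carlo error.

## Known limitations

Vessels at the lateral sampling limit (diameter ≲ 2 px) are below what the
skeleton/EDT calliper can resolve; the phantom defaults use vessels a few
pixels wide accordingly. Density is reported over the full en-face region
(no artifact exclusion). The DEJ detector assumes a single dominant
boundary below the surface; stacked layers or strong dermal texture could
distract the step statistic. None of the motion- or PSF-related effects
listed above are simulated, and no inter-group statistical testing is
provided — the package quantifies; inference is left to the analyst.
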