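# octamorph

OCT angiography and epithelial morphometry for layered skin and mucosa.

Vulvar lichen sclerosus (VLS) is a chronic inflammatory skin disease whose
monitoring today relies on repeated biopsies. OCT angiography offers a
non-invasive alternative: repeated B-scans at the same position reveal
flowing blood through speckle decorrelation, and structural B-scans expose
the epithelial layer whose thickness and vascular bed change with disease.
`octamorph` provides the full computational chain for that kind of study —
for imaging scientists building OCTA pipelines and for analysts who need
reproducible vessel and thickness morphometry — together with a synthetic
speckle phantom with exact ground truth, used to validate every stage.

## The core statistic

With J repeated B-scans per slow-axis position (J = 6, ΔT = 5 ms in the
motivating protocol), flow contrast per voxel is the intensity-based
Doppler variance

```
              Σ_{j=1}^{J-1} |A_j| |A_{j+1}|
σ² = 1 − ───────────────────────────────────────
          Σ_{j=1}^{J-1} ( |A_j|² + |A_{j+1}|² )/2
```

σ² is 0 for static tissue, approaches 1 for fully decorrelated (flowing)
voxels, is confined to [0, 1], and is invariant to global amplitude
scaling. Downstream: en-face maximum-intensity projection → Mexican-hat
(multi-scale Laplacian-of-Gaussian) vessel enhancement → binarization →
vessel density (% of region) and skeleton/distance-transform diameters;
in parallel, surface and dermal–epidermal junction (DEJ) detection on
B-scans gives per-site epithelial thickness, with the DEJ allowed to be
*missing* where dermal contrast vanishes (the sclerotic failure mode).

## Worked example

Simulate a three-site "subject" and run the whole pipeline (about half a
minute at this grid size):

```r
library(octamorph)
cfg <- list(seed = 5,
            phantom = list(n_lateral = 64, n_depth = 160, n_positions = 32))
rep <- run_pipeline(cfg)
print(rep)
#> Morphometry report (3 rows)
#>      subject    group   site              density (%) diameter (um)
#> [1,] phantom-01 control labia_majora      —           —
#> [2,] phantom-01 control interlabial_sulci —           —
#> [3,] phantom-01 control labia_minora      27.40575    165.7143 ± 43.15592
#>      VuET (um)
#> [1,] 297.7415
#> [2,] 177.7791
#> [3,] 117.1724
```

The three sites were simulated with true epithelial thickness 300, 180 and
120 µm, recovered here as 297.7, 177.8 and 117.2 µm (errors under half an
axial pixel). Vessel metrics are computed for the labia minora, the site
the motivating protocol quantifies: the binarized angiogram covers 27.4 %
of the en-face region (the phantom's true vessel footprint at this grid is
within two percentage points), with vessel diameters 166 ± 43 µm against
true tube diameters of 120–200 µm. Missing cells print as an em-dash, as
in the packaged clinical reference table.

That reference table — per-subject published pilot measurements of eight
subjects (five VLS, three controls) — ships with the package:

```r
print(summarize_report(vulvar_morphometry()))
#> Report summary (24 rows)
#>            column   min    max n_nonmissing
#>       density_pct 29.21  45.80            8
#>  diameter_mean_um 31.44  58.27            8
#>    diameter_sd_um  7.39  18.10            8
#>           vuet_um 63.00 317.00           21
#> Epithelial thickness by site:
#>               site min max n_nonmissing
#>       labia_majora 121 317            7
#>  interlabial_sulci  63 192            6
#>       labia_minora  89 181            8
```

A thin command-line wrapper with `simulate`, `angio`, `quantify`, `run`
and `summarize` subcommands is installed at
`system.file("cli", "octamorph.R", package = "octamorph")`.

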