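Package: octamorph
Title: OCT Angiography and Epithelial Morphometry via Intensity-Based
    Doppler Variance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optical coherence tomography angiography (OCTA) of
    layered skin and mucosa. Computes inter-frame intensity-based Doppler
    variance (IBDV) flow contrast from repeated B-scans, assembles Doppler
    variance volumes, and generates en-face angiograms by maximum intensity
    projection. Quantifies microvasculature (vessel density and diameter via
    Mexican-hat enhancement, binarization, skeletonization and distance
    transform) and epithelial thickness (surface and dermal-epidermal
    junction detection on B-scans). Includes a seedable synthetic OCT
    speckle phantom with layered tissue, uneven surface topography,
    embedded decorrelating vessels and known ground truth, and an
    end-to-end pipeline producing per-subject, per-site morphometry
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
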