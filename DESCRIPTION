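Package: omnicyte
Title: Time-Lapse Microcolony Cytometry for Rod-Shaped Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular pipeline for quantitative analysis of time-lapse
    microscopy of bacterial microcolonies: dataset discovery and input/output
    (TIFF frames, editable 16-bit PNG cell masks), sub-pixel image
    registration by upsampled cross-correlation, classical baseline
    segmentation with contact-tolerant instance masks and external-mask
    import, overlap-based frame linking with division detection and
    temporal-consistency correction, single-cell cytometry (medial-axis
    geometry, fluorescence, diffraction-limited focus detection) assembled
    into a per-cell summary table with spreadsheet export, evaluation metrics
    (cell width inferred from cell contact, cumulative fatal-error curves),
    and visualizations (frame mosaics with vector outlines, kymographs, cell
    towers, lineage trees). Includes an agent-based growing rod-colony
    simulator that produces ground-truth masks, lineages and multi-modality
    renders so that the whole pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
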