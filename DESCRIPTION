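Package: silitrace
Title: Quantitative Time-Lapse Analysis of Silica Deposition Vesicle
    Membrane Protein Trafficking in Diatoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the trafficking of GFP-tagged silica
    deposition vesicle (SDV) membrane proteins from dual-channel confocal
    time-lapse recordings of dividing diatoms. Implements the full
    region-based quantification procedure (z-plane summation, outside-cell
    background correction, sub-pixel cross-correlation drift correction,
    keyframed rectangular regions with linear size interpolation,
    normalization of the pre-cytokinesis total to 1.0, silica-tracer peak
    synchronization, and multi-cell averaging), a membrane-fate classifier
    that discriminates the four proposed fates of the SDV membrane after
    biosilica exocytosis, and a synthetic time-lapse generator with explicit
    molecule-pool kinetics and machine-readable ground truth for validating
    the pipeline. Auxiliary calculators cover silicanin domain-architecture
    annotation, homolog screening of BLAST tabular output, mean residue
    ellipticity, standard-curve assay quantification, and silica-formation
    synergy folds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
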