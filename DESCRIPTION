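Package: rogfp2
Title: Ratiometric roGFP2 Redox Imaging and Seedling Phenotype Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for ratiometric redox biosensor imaging and
    seedling phenotyping. Converts two-channel (405/488 nm excitation) roGFP2
    fluorescence ratios to the degree of sensor oxidation and the glutathione
    redox potential (E_GSH) via the Nernst equation, with DTT/H2O2 calibration
    endpoints; quantifies fluorescent-dye (DHE, H2DCFDA, FDA) intensities in
    circular regions of interest on grayscale TIFF images with background
    subtraction and percent-of-control normalization; computes root architecture
    metrics (lateral root density); and provides the statistics layer used in
    plant stress phenotyping: one-way ANOVA, Duncan's multiple range test with
    compact letter display, and per-genotype Pearson correlation matrices. A
    seeded synthetic-data generator produces two-channel biosensor image stacks
    with known ground-truth oxidation maps, matched calibration stacks, and
    multi-genotype phenotype tables with a specified correlation structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
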