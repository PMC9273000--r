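Package: nanostoich
Title: Subcellular Ligand-to-Metal Stoichiometry from NanoSIMS Ion Count Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative evaluation of multi-channel NanoSIMS secondary-ion
    count images of cells exposed to isotopically labeled platinum drugs.
    Provides region-of-interest ion-count extraction with Poisson counting
    errors, 15N isotope-abundance and two-endpoint label-fraction computation,
    a 12C2-referenced Pt/N concentration index, per-compartment stoichiometry
    curves across exposure concentrations with slope fitting and
    sensitivity-factor calibration, phase-correlation registration of
    sequentially acquired runs, treated-versus-control comparisons and
    channel-pair colocalisation metrics, and a synthetic phantom generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
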