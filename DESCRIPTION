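Package: fastpass
Title: Single-Raster DESI-MSI Line-Scan Processing for High-Throughput
    Metabolic Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for desorption electrospray ionization
    mass spectrometry imaging (DESI-MSI) acquisitions taken as a single
    raster line over a linear array of sample spots.  Line-scan runs are
    projected as distance-domain chromatograms (TIC/XIC), lock-mass
    corrected, spatially normalized to an internal-standard channel, and
    integrated over declared spot intervals to give per-sample molecular
    profiles.  Includes the spot-to-blank signal-ratio statistic for
    raster-rate optimization, formula-based adduct and isotopic-envelope
    annotation, untargeted feature detection with top-N prioritization,
    PCA phenotyping and volcano differential screening, and a seeded
    synthetic line-scan generator for end-to-end validation without
    instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    yaml
Suggests:
    cluster,
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
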