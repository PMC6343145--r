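Package: dilongqc
Title: Chromatographic Fingerprinting and Nucleoside Quantitation for
    Guang Dilong Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric toolkit for single-wavelength liquid-chromatography
    quality control of Guang Dilong (the dried earthworm Pheretima
    aspergillum) and its adulterant species. Provides seeded simulation of
    diode-array chromatograms with the nucleoside composition structure of
    authentic and adulterated material, baseline correction and peak
    detection, chromatographic fingerprinting with correlation-based
    similarity against a mean fusion chromatogram, calibration fitting with
    LOD/LOQ estimation, six-nucleoside quantitation, analytical validation
    statistics (precision, repeatability, stability, recovery), and
    adenosine-marker adulterant classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
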