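Package: brmspheroid
Title: Correlative Brillouin-Raman Analysis of Tumor Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the joint mechano-chemical analysis of multicellular
    tumor spheroids by Brillouin and Raman microspectroscopy. Implements
    damped-harmonic-oscillator (DHO) fitting of Brillouin spectra with
    Stokes/anti-Stokes symmetry calibration, high-wavenumber Raman
    processing (spline fluorescence removal, reference-spectrum
    subtraction, CH/OH band-area ratio), a biphasic cell/ECM composition
    model that decomposes the measured Brillouin shift into cellular and
    extracellular components, confocal-image morphometry (nuclear aspect
    ratios by zone, marker-positive fractions, invasion areas), and a
    seeded synthetic-data generator so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    multcomp,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
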