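Package: crocodiel
Title: Diel Cell-Flux Simulation of Carbon, Nitrogen, Oxygen, and Iron in a
    Unicellular Marine Diazotroph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained simulator of the diel metabolic cycle of the
    unicellular nitrogen-fixing cyanobacterium Crocosphaera watsonii. The model
    couples carbon storage, nitrogen storage, population growth, intracellular
    oxygen (a diffusion-respiration balance over a spherical cell), and the
    daily translocation of iron between photosystems, an intracellular buffer,
    and nitrogenase. It resolves light/dark metabolic switching, respiratory
    protection of nitrogenase, Arrhenius temperature factors, light saturation
    with photoinhibition, and oxygen-management sensitivity scenarios, and
    provides temperature and irradiance scans of daily-integrated fluxes.
    Measurement-side utilities compute photosystem-II electron transfer rates
    from fast-repetition-rate fluorometry quantities, fit Eilers-Peeters
    light-response curves, convert acetylene-reduction rates to nitrogen
    fixation, generate synthetic diel observations, and calibrate model
    parameters against observed time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
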