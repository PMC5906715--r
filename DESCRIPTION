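Package: condsize
Title: Injection-Less Conductance Sizing of Blood Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates blood-vessel lumen diameter from tetrapolar guidewire
    impedance measurements without saline injection. Extracts the ohmic system
    resistance from voltage magnitudes at two (or more) excitation frequencies
    under a series resistance-capacitance electrode-polarization model,
    decomposes the measured conductance into lumen, vessel-wall and
    surrounding-medium pathways with an annular field model, and inverts the
    decomposition for the lumen diameter by a bracketed iterative scheme.
    Includes saline-phantom and ex-vivo tissue-conductivity calibration, a
    packaged saline conductivity lookup table, Bland-Altman agreement and
    repeatability statistics, and a seeded synthetic spectrum simulator for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
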