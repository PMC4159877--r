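Package: anfisqsar
Title: Neuro-Fuzzy QSAR Models for Anthocyanin Radical Scavenging Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) modelling of
    DPPH radical scavenging activity of anthocyanins and anthocyanidins from
    conceptual-DFT reactivity descriptors. Computes ionization potential,
    electron affinity, hardness, softness, electronegativity, chemical
    potential, electrophilicity and phenolic O-H bond dissociation energies
    from supplied semi-empirical molecular energies; screens descriptors by
    Pearson correlation with collinearity elimination; fits a first-order
    Takagi-Sugeno adaptive neuro-fuzzy inference system (ANFIS) with grid
    partition and hybrid least-squares/backpropagation learning; and
    validates predictions by pair-resampling bootstrap estimates of the mean
    absolute error and Q-squared. Ships a compound registry for the
    flavylium-cation tautomer system, a synthetic descriptor/activity
    generator for testing, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
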