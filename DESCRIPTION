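Package: pahsoiltox
Title: Soil Microbial Indices, Enzyme Resistance and Phytotoxicity under
    Polycyclic Aromatic Hydrocarbons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the response of soil microbial communities to
    polycyclic aromatic hydrocarbon (PAH) contamination: colony-forming-unit
    calculations from dilution plate counts, colony development (CD) and
    ecophysiological diversity (EP) indices from daily colony-appearance
    series, the Orwin-Wardle soil resistance index from enzyme activities,
    Phytotoxkit seed-germination and root-growth inhibition scores,
    dose-response summaries (treatment means, fold changes, Pearson dose
    correlations), and balanced two-way analysis of variance with
    eta-squared variance partitioning and Tukey-based compact letter
    displays. Includes a seeded synthetic-data generator that emulates the
    4 hydrocarbons x 4 doses x 3 replicates design so every pipeline stage
    is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
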