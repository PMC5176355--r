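Package: dosetox
Title: Mass-Action Sequestration and Gene-Dosage Toxicity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of gene-dosage toxicity caused by
    mass-action sequestration of weak protein-protein interaction partners
    under enzyme overexpression. Provides a closed-form and bisection solver
    for one-hub / N-partner binding equilibria, surface plasmon resonance
    isotherm and dissociation fitting, Michaelis-Menten, IC50 and ligand
    saturation fitting, Gompertz growth-curve and abundance-fitness curve
    analysis, co-immunoprecipitation spectral-count hit calling, metabolite
    fold-change and significance annotation, and seeded synthetic-data
    generators with recorded ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
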