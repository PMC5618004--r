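Package: pentaweb
Title: Steady-State Pentagon Food-Web Analysis Linking Ciliates to
    Bacterial Carbon Demand
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how the predator chain of the marine
    microbial food web sets the growth-limitation regime of heterotrophic
    prokaryotes. Implements closed-form steady states of the pentagon food
    web (free phosphate, autotrophic flagellates, heterotrophic
    prokaryotes, heterotrophic nanoflagellates, ciliates), the quadratic
    law linking ciliate biomass to bacterial carbon demand with its switch
    between mineral-nutrient-limited and organic-carbon-limited growth, a
    Lotka-Volterra dynamic counterpart constrained to those steady states,
    ordination statistics for binary community fingerprints (Jaccard
    distances, nonmetric multidimensional scaling, Procrustes
    superimposition with permutation-test ensembles, PERMANOVA,
    virus-to-prokaryote ratios), and synthetic mesocosm data generators
    that make the whole pipeline testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'pentaweb-package.R'
    'AllGenerics.R'
    'BandMatrix.R'
    'FoodWebParameters.R'
    'foodwebCore.R'
    'dynamicSimulator.R'
    'fingerprintBasics.R'
    'nmds.R'
    'procrustes.R'
    'ensemble.R'
    'fitBcd.R'
    'permanova.R'
    'syntheticData.R'
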