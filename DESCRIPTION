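Package: gasdive
Title: Compartmental Blood and Tissue Gas Dynamics in Diving Sea Turtles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Perfusion-limited compartmental model of inert and metabolic gas
    exchange in breath-hold diving sea turtles. Estimates nitrogen, oxygen and
    carbon dioxide tensions in arterial blood, mixed venous blood and four body
    compartments (brain, fat/bone, central circulation, muscle) of loggerhead,
    leatherback and green turtles over arbitrary time-depth profiles. Includes
    time-depth-recorder regularization and dive segmentation, lung compression
    and pulmonary shunt mechanics with depth-dependent faveolar collapse,
    body-condition and cardiac-output model variants, end-dive nitrogen
    supersaturation metrics, and a seeded synthetic dive-bout generator so the
    full pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, tools, utils, Rcpp, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'constants.R'
    'AllClasses.R'
    'RcppExports.R'
    'dive-records.R'
    'parameters.R'
    'lung-mechanics.R'
    'gas-dynamics.R'
    'experiments.R'
    'gasdive-package.R'
    'manifest.R'
    'methods.R'
    'synthetic-data.R'
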