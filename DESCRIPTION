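Package: eqspec
Title: Equilibrium Speciation, Rank Annihilation Factor Analysis, and
    Formation-Constant Refinement for Metal-Ligand Competition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying competitive metal-ligand complexation
    equilibria, built around the Al(III)-ciprofloxacin-NADP system. Solves
    multicomponent chemical equilibria (including metal hydrolysis and water
    autoprotolysis) from cumulative formation constants by damped Newton
    iteration in log concentration space; estimates 1:1 conditional stability
    constants from spectral titration matrices by rank annihilation factor
    analysis with an eigenvalue-based RSD statistic; simulates and refines
    pH-potentiometric titrations by Gauss-Newton least squares on the
    cumulative log beta values, including a stepwise model-building loop; and
    generates synthetic spectra and titration curves with the bilinear
    Beer-Lambert structure the analyses assume.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
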