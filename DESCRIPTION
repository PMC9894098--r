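Package: cellforge
Title: Design of Custom Therapeutic Cells for Failing Human Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("cellforge", "developers", email = "cellforge@example.org",
           role = c("aut", "cre"))
Description: Simulates electrotonic (gap-junctional) coupling between human
    ventricular cardiomyocyte models (healthy, heart-failure remodeled, and
    fibrotic heart-failure variants of the O'Hara-Rudy endocardial model) and
    composable non-excitable "custom" therapeutic cells assembled from ion
    channels of c-kit+ cardiac interstitial cells, mesenchymal stem cells,
    cardiac fibroblasts, and cardiomyocytes. A genetic algorithm searches
    channel conductance scalings, gap-junction conductance, and coupled-cell
    count for candidate cells that restore healthy action-potential and
    calcium-transient waveforms, scored by normalized root-mean-square error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
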