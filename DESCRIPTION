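Package: skywis
Title: Importance-Sampling Skyline Estimation of Effective Population Size
    Through Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the demographic history of a population from a sample
    of homologous DNA sequences by importance sampling over coalescent
    genealogies. Genealogies are proposed backward in time under the
    Stephens-Donnelly conditional-sampling construction for a finite-sites
    Jukes-Cantor model; importance weights correct each genealogy to the
    constant-size coalescent likelihood; per-genealogy skyline estimates on
    logarithmically growing epochs are combined into a weighted
    piecewise-constant curve of effective population size through time.
    Supports serially sampled (heterochronous) sequences and includes a
    variable-population-size coalescent sequence simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
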