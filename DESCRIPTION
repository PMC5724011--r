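Package: hdxdiff
Title: Differential Hydrogen-Deuterium Exchange Mass Spectrometry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differential analysis of hydrogen-deuterium exchange
    mass spectrometry (HDX-MS) peptide-level uptake data, built around the
    study design used to probe conformational dynamics of peptide-loaded
    versus peptide-receptive MHC class I molecules. Provides per-peptide
    replicate statistics and relative fractional uptake, between-state
    differential uptake, residue-level consolidation of overlapping peptides
    into difference heat maps (shortest-peptide rule with C-terminal
    tie-break), coverage and redundancy metrics, normalized uptake-increase
    statistics with paired and Welch t tests, a forward simulator of
    Linderstrom-Lang EX2 exchange kinetics with replicate noise, binomial
    isotopic-envelope simulation with unimodal/bimodal classification, and
    fluorescence-polarization receptivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
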