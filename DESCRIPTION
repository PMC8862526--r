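Package: inbredpanel
Title: Homozygosity, Relatedness and Introgression Analysis for Inbred Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genomic characterization of panels of near-isogenic
    lines derived from wild populations by repeated full-sibling-pair inbreeding.
    Calls homozygous blocks from windowed heterozygous-SNP counts with a
    jointly-trained Poisson-emission hidden Markov model (Baum-Welch fitting,
    Viterbi and posterior decoding), refines obligate-heterozygous regions such
    as a sex-determining segment, computes windowed population-genetic
    statistics (Hudson's F_ST, nucleotide diversity, linkage-disequilibrium
    decay, moment inbreeding coefficients, ANOVA-based broad-sense
    heritability), scans for introgression with the ABBA-BABA D and f_d
    statistics, clusters lines by identity-by-state, and ships a full-sib
    inbreeding genome simulator with exact founder-ancestry ground truth so
    that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    vcfR,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
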