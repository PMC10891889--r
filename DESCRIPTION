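Package: baculoscribe
Title: Annotation and Comparative Characterization of Baculovirus Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational characterization of large circular
    double-stranded DNA virus genomes, in particular baculoviruses.
    Implements circular-genome open reading frame prediction with the
    annotation conventions used for baculovirus genomes (50 amino-acid
    minimum, 75 bp overlap rule, masking of ORFs inside homologous
    regions), classification of early/late promoter motifs in upstream
    windows, de novo detection of homologous regions (hrs) as tandem
    repeat arrays with an imperfect palindromic core, Kimura 2-parameter
    distances with the 0.05 substitutions/site species-demarcation rule,
    reciprocal-best-hit comparative genomics with gene parity plots and
    whole-genome identity, and a seeded synthetic-genome simulator with
    recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
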