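Package: thetascan
Title: Discovery and Validation Toolkit for tRNA-Associated HDV-Like
    Theta Ribozymes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Descriptor-driven secondary-structure motif search for
    minimal HDV-like (delta) self-cleaving ribozymes in phage genomes,
    with catalytic-position false-positive control motifs, tRNA
    association and genomic-context classification, alternative genetic
    code (stop-codon reassignment) detection by coding-density
    comparison, and self-scission kinetics fitting (mono/biexponential,
    Hill-type Mg2+ dependence, and two-pKa pH-rate profiles). Includes a
    synthetic phage-genome generator with a ground-truth manifest so the
    whole pipeline is testable without external databases, and a small
    command-line interface tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
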