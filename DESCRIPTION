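Package: editClust
Title: Cluster Structure, Co-Editing and Directionality of A-to-I mRNA Editing Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for characterizing adenosine-to-inosine
    (A-to-I) mRNA editing sites along transcripts: read-level co-editing
    correlation (the phi coefficient r) and the cooperativity ratio r',
    detection of dense clusters of consecutive edited adenines with
    context-preserving randomized controls, medium-range cluster windows from
    neighbor editing probabilities, long-range cluster detection by
    Kolmogorov-Smirnov comparison of inter-site distance distributions,
    an editing-driven variance decomposition of transcriptome and proteome
    diversity, base-pairing-probability profiles around editing sites, and
    inference of the 3'-to-5' directionality of editing from read-level
    intermediate states. Includes a fully seeded synthetic-data generator
    (nested Neyman-Scott site placement, Gaussian-copula correlated reads,
    structure-profile emulation) so that every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
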