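Package: effectorscan
Title: Comparative Screening of Candidate Effector Repertoires from
    Head-Body Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to predict and compare candidate effector repertoires of
    plant-feeding insects from head-versus-body RNA-seq experiments.
    Transcripts upregulated in head tissue that carry a signal peptide and
    no transmembrane domain are called putative effectors; all-vs-all
    protein similarity graphs are clustered with an implemented Markov
    Cluster (MCL) algorithm to find core (shared across datasets) and
    pioneer (lineage-specific, annotation-less) effector clusters;
    reciprocal best BLAST hit (RBBH) analysis builds 1:1 orthologue groups,
    which are screened for positive selection with pairwise Nei-Gojobori
    dN/dS after codon-aware back-translation and alignment trimming. A
    synthetic multi-species repertoire generator with full ground truth
    (codon evolution at specified omega, negative-binomial head/body
    counts, secretion labels) makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    edgeR,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
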