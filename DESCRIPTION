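Package: virsig
Title: Virus Genome Signatures for Family-Level Taxonomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-only classification of eukaryotic viruses at the family
    and order level. Genomes are annotated against databases of clustered
    protein-family profiles and per-family genome-organisation models; the
    relatedness of two viruses is summarised by a composite generalised
    Jaccard index over their protein-profile and genome-organisation
    signatures. The package builds profile databases (all-vs-all protein
    search, Markov clustering, per-cluster alignment, profile construction),
    constructs bootstrapped UPGMA dendrograms with clade support, assigns
    taxonomic candidates with a thresholded 1-nearest-neighbour classifier
    followed by a topological evaluation of the candidate's placement, and
    scores the taxonomic information content of individual profiles by
    mutual information. External engines (BLAST+, MAFFT, HMMER) are used
    when available, with native fallbacks for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
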