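Package: ervkit
Title: Annotation, Dating and Polymorphism Analysis of Endogenous Retrovirus Insertions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the desk-scale study of young long-terminal-repeat (LTR)
    retroelement families in genome assemblies. Provides a synthetic-genome
    generator that plants full proviruses (with target-site duplications),
    solo LTRs, truncated fragments and nested insertions and derives strain
    genomes differing by presence/absence events; a k-mer-anchored scanner and
    defragmenter that reconstructs insertion calls and classifies them as
    provirus, solo LTR or truncated; Gag open-reading-frame assessment against
    a family consensus; recency statistics from Jukes-Cantor-corrected
    divergence and neighbor-joining terminal branch lengths, including
    LTR-LTR divergence dating; an automated presence/absence polymorphism
    caller across assemblies with target-site-duplication evidence at empty
    sites; and enumeration of antisense-oligonucleotide target copies with a
    gene/insertion proximity report. All stages are exercisable end to end on
    simulated genomes with planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Annotation, SequenceAnalysis, Phylogenetics, Transposon
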