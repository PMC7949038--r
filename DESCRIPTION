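Package: dmrscape
Title: Differential Methylation Landscapes from Per-CpG Bisulfite Calls
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls differentially methylated cytosines and regions (DMCs/DMRs)
    from per-CpG whole-genome bisulfite sequencing calls using an all-sample
    coverage filter, a group-mean difference threshold, same-direction
    chaining within a base-pair gap limit and a Mann-Whitney U regional test.
    Annotates DMRs to promoters, exons, introns, CpG islands, enhancers and
    repeats by a fractional-overlap rule; classifies DMRs across tumor
    genotypes into transformation-associated regions and putative targets of
    a DNA methyltransferase's catalytic versus accessory function; integrates
    promoter hypomethylation with differential expression into gene response
    groups; and aggregates histone/accessibility signal over region sets as
    length-scaled or TSS-centered metagene profiles. A beta-binomial
    methylome simulator with planted regions of known category drives
    recovery testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics, Sequencing
RoxygenNote: 7.3.3
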