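Package: ovIgSeq
Title: Immunoglobulin Locus Annotation and Repertoire Analysis for Sheep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating germline immunoglobulin heavy- and
    light-chain loci (template-guided segment search combined with
    recombination-signal-sequence scanning under the 12/23 rule,
    IMGT-style functionality classification and subgroup clustering)
    and for analysing rearranged B-cell receptor amplicon reads:
    read filtering, V(D)J gene assignment, junction decomposition
    into exonucleolytic deletions and P/N additions, CDR3 extraction
    and length profiling, somatic hypermutation spectra with AID
    hotspot (WRCY/RGYW) quantification, and per-sample repertoire
    statistics. A fully seeded synthetic repertoire generator with
    per-read ground truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'rss.R'
    'germline.R'
    'filter.R'
    'assign.R'
    'junction.R'
    'shm.R'
    'stats.R'
    'simulate.R'
    'pipeline.R'
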