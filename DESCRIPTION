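Package: orgRecomb
Title: Organellar Genome Recombination and Rearrangement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of recombination-driven instability
    in plant organellar genomes from paired-end short reads. Provides exact
    repeat-pair discovery on circular genomes, prediction of repeat-mediated
    recombination products (loop-out subgenomic circles, inverted-segment
    isomers), a seeded paired-end read simulator with full ground truth, a
    deterministic seed-and-extend micro-aligner with SAM import/export,
    per-kilobase coverage stoichiometry scanning, soft-clip based
    rearrangement junction detection with chloroplast inverted-repeat
    isomerization filtering, and read-pair quantification of parental versus
    crossover configurations across repeat pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Coverage, StructuralVariation
RoxygenNote: 7.3.3
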