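Package: asmforge
Title: Genetic-Map-Guided Scaffolding, Gap Filling and Quality Control
    for Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for curating draft genome assemblies into chromosome-scale
    references: linkage-map-guided misassembly detection, scaffold breaking,
    ordering and orientation; gap closing with independent patch assemblies
    under explicit flank/distance spanning rules, including cross-assembly
    confirmation of collapses (negative gaps); and an assembly evaluation
    suite covering N50/NGx contiguity, Phred-scaled consensus quality (QV)
    estimated from small-variant calls, centromere/telomere chromosome-end
    classification, repeat-region statistics, gap-to-gene proximity and
    transcript alignment classes.  A deterministic synthetic-genome simulator
    plants misjoins, inversions, gaps and collapses with known truth so every
    stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
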