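Package: svduplex
Title: Error-Minimized Structural Variant Junction Detection in Capture Sequencing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects rare structural variant (SV) junctions in targeted
    capture sequencing libraries with molecule-level error correction.
    Read pairs are collated into source DNA molecules by their endpoints,
    outer clip lengths and duplex unique molecular identifiers (UMIs);
    strand-aware consensus sequences suppress sequencing errors; split and
    discordant alignments are assembled into SV calls across molecules and
    samples; artifact-specific filters (duplex confirmation, strand family
    size, shared endpoints) separate true junctions from intermolecular
    ligation and chimeric PCR artifacts; junction microhomology and de novo
    insertions are characterized at base resolution and de novo SNVs/indels
    near junctions are tested for junction proximity by permutation. A
    bundled synthetic capture-library simulator with per-fragment ground
    truth emulates the relevant artifact classes so every stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
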