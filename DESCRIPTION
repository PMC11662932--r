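Package: mmejscan
Title: Alignment-Free Detection of Microhomology-Mediated End-Joining
    Deletions in Short Reads
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects medium-sized (6-100 bp) deletions arising from
    microhomology-mediated end joining (MMEJ) without relying on read
    alignment around the breakpoint. The package discovers all homolog
    pairs (maximal exact repeats) in a reference genome, precompiles the
    post-deletion junction sequence predicted for each pair (perfect and
    one-base imperfect variants), and searches sequencing reads for exact
    occurrences of those junctions to obtain supporting-read counts and
    variant allele frequencies. Additional components classify paired
    tumor/normal calls as somatic or germline, characterise repair
    mechanism from junction homology and flank signatures, detect
    minisatellites and G-quadruplex motifs around deletions, and provide a
    self-contained spike-in read simulator with sensitivity/specificity
    benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
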