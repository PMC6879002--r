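Package: lrkit
Title: Linked-Read Library Simulation, Molecule Inference, and Diploid
    Assembly Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and assessing barcoded Linked-Read
    sequencing experiments. Simulates Linked-Read libraries from a diploid
    template genome (exponential molecule shearing, Poisson allocation of
    molecules to barcoded partitions, barcode-prefixed paired-end reads),
    reconstructs long DNA molecules from barcode-grouped read placements
    with the standard proximity filters, estimates library design
    parameters (physical coverage, per-molecule read coverage, molecules
    per partition, unweighted and length-weighted molecule length), and
    evaluates haplotype-resolved assemblies (N50/NA50 with alignment-based
    misassembly breaking, windowed diploid/haploid genome-fraction
    classification, chance-overlap expectations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
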