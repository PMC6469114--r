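Package: hgtscan
Title: Detection of Endosymbiont-to-Host Horizontal Gene Transfer in
    Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects horizontal gene transfer (HGT) from an intracellular
    endosymbiont (such as Wolbachia) into a host nuclear genome assembly.
    Scaffolds are triaged by taxon-annotated GC/coverage (TAGC) screening,
    symbiont-derived blocks are located with a k-mer anchor-chaining
    aligner, genuine insertions are discriminated from chimeric assembly
    artifacts by read-depth continuity at block junctions, calls are
    corroborated across independent assemblies and annotated with
    transposase proximity, overlapping genes and transcription. Includes
    multi-strain endosymbiont evidence scoring (duplicated and polymorphic
    single-copy genes, duplicated markers), assembly contiguity statistics
    (N50/L50), and a synthetic-data generator with known truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'detect.R'
    'hgtscan-package.R'
    'io.R'
    'kmer-align.R'
    'methods.R'
    'pipeline.R'
    'simulate-experiment.R'
    'stats.R'
    'strain.R'
    'synthetic.R'
    'tagc.R'
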