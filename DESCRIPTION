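Package: BACography
Title: Chromosome-Arm Classification, Annotation and Genome Landscapes for
    Gene-Bearing BAC Sequence Resources
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for turning large gene-bearing BAC (bacterial artificial
    chromosome) sequencing resources into genome-scale knowledge. Provides
    chromosome-arm assignment of BAC assemblies by discriminative k-mer
    classification against flow-sorted arm targets (including centromeric
    overlap pseudo-targets), gene-model annotation with node-length,
    e-value and frequent-model filters, plurality-vote synteny placement on
    a reference genome with two-map anchor joining and inversion detection,
    sliding-window landscapes of gene density and recombination frequency
    with detection of gene-dense low-recombination regions, estimation of
    library screening saturation by permutation accumulation curves with
    asymptote extrapolation, and per-clone and per-arm assembly statistics
    (N50/L50, coverage concordance). A self-contained synthetic-data
    generator emulates the statistical structure of a real BAC resource
    (telomere-biased gene density, centromeric recombination suppression,
    shared repeat families, probe-pool screening noise) so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Sequencing, Annotation, Classification, GenomeAssembly,
    ComparativeGenomics
RoxygenNote: 7.3.3
Collate: 
    'BACography-package.R'
    'AllClasses.R'
    'utils.R'
    'annotation.R'
    'assembly-metrics.R'
    'io.R'
    'kmer-classifier.R'
    'landscape.R'
    'saturation.R'
    'synteny.R'
    'pipeline.R'
    'simulate-genome.R'
    'simulate-library.R'
    'simulate-screening.R'
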