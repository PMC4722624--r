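Package: itdscan
Title: Soft-Clip Based Detection of FLT3 Internal Tandem Duplications from
    Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects FLT3 internal tandem duplications (ITDs) from paired-end
    amplicon next-generation-sequencing alignments by correlating soft-clipping
    points in primary alignments with realignments of the clipped bases to the
    same locus, extrapolating the duplication length from the distance between
    the clip point and the realignment start. Includes an exhaustive,
    deterministic ITD read simulator for amplicon libraries, a grid-evaluation
    harness that maps the detection envelope over all (start, length)
    combinations through an external aligner, and a VCF writer that annotates
    calls with clinical reporting filters (minimum variant allele fraction and
    minimum depth) without suppressing sub-threshold signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    data.table,
    stats,
    stringi,
    tools,
    utils
Suggests:
    BiocGenerics,
    SummarizedExperiment,
    VariantAnnotation,
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: bwa (for alignment-dependent workflows), samtools
Config/testthat/edition: 3
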