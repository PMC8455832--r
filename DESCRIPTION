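Package: sdrkit
Title: Haplotype-Separation Diagnostics and Sex-Determining Region Analysis
    for Diploid Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control and sex-locus analysis of long-read
    diploid genome assemblies in which the two haplotypes are assembled as
    separate contigs. Computes self-alignment coverage multiplicity profiles
    and allele-divergence statistics from tabular BLAST-style hit tables,
    locates the poplar sex-determining region (SDR) on contigs from marker
    alignments and classifies haplotypes as Y or X by the presence of ARR17
    partial repeats, clusters resequencing samples by variant-allele-fraction
    profiles (Ward.D2 hierarchical clustering and classical multidimensional
    scaling), and detects high-copy repeat loci from read-depth tracks with
    locus segmentation, copy counting and six-frame ORF scanning. A synthetic
    data generator produces assemblies, alignment tables, multi-sample VCFs
    and depth tracks with known ground truth so every stage of the pipeline
    can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
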