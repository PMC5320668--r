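Package: methaplo
Title: Epi-Allelic Haplotype Reconstruction from Bisulfite Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters whole-genome bisulfite sequencing (WGBS) and NOMe-seq
    reads into epi-allelic haplotype chains by maximizing a constrained
    posterior over read partitions, strand assignments, and six-state
    epigenotype chains (A, C, G, T, methylated C, and G paired with a
    methylated reverse-strand C).  Each chain is annotated with CpG
    methylation, SNP/SNV genotypes with log fit-ratios, and, for NOMe-seq
    data, GpC chromatin accessibility with inferred inaccessible
    (nucleosome/protein-protected) intervals.  Includes a noise filter for
    minor chains, a bisulfite read simulator with full ground truth for
    validation, readers for SAM/BAM, FASTA, and VCF input, and writers for
    TSV, BED, and bedGraph output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
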