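Package: tajscan
Title: Windowed Tajima's D Genome Scans with Empirically Corrected
    Confidence Limits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sliding-window scans of multi-strain variant data for
    signatures of balancing and directional selection. Computes Watterson's
    theta, nucleotide diversity and Tajima's D per window from unphased
    genotype allele counts, derives both the theoretical beta-approximation
    confidence limits for D and empirically corrected percentile limits from
    the observed genome-wide distribution, maps significant windows onto
    gene models, and contrasts selection classes across species and
    expression classes. Includes a coalescent infinite-sites simulator that
    emits complete synthetic genome bundles (FASTA, VCF, BED mask, GFF3,
    truth tables) for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
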