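Package: embryocomp
Title: Allele-Specific Analysis of Sex-Chromosome Dosage Compensation in Single Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the onset of X-chromosome dosage compensation
    during early embryogenesis from single-embryo RNA-seq, in species carrying
    sex chromosomes of different evolutionary ages (ancestral X, younger XR,
    and a recently formed neo-X/neo-Y pair). Implements autosomal
    normalization of RPKM tables, per-gene maternal/paternal allele
    aggregation over SNP-overlapping reads, zygotic-gene classification under
    allele-specific and transcript-level definitions, female:male bias
    statistics with chi-squared and Wilcoxon comparisons, gene-resampling
    bootstrap detection of the onset of male-X hypertranscription,
    neo-X/neo-Y allele partitioning stratified by neo-Y ORF status, and
    spatial/chromatin association tests (nearest-neighbour clustering against
    a zygotic-gene null, high-affinity-site proximity, and H4K16ac enrichment
    comparisons). A synthetic-data generator with full ground truth emulates
    the embryo timecourse design (eight morphological stages, both sexes,
    replicate embryos) for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
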