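Package: methylomer
Title: Gene-Body Methylation Classification, TE-Island Segmentation and
    Methylome Concordance from CpG Methylation Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of whole-genome CpG methylation call sets,
    as produced by nanopore methylation callers (per-read log-likelihood
    ratios) or bisulfite pipelines (per-cytosine coverage reports).
    Aggregates read-level calls into per-site methylation frequencies,
    merges complementary CpG strands, applies coverage and call-density
    filters, classifies genes as gene-body methylated (GBM) or
    unmethylated (UM) and promoters as methylated (PMG) or unmethylated
    (PUM) with binomial tests against the genome-wide background and
    Benjamini-Hochberg correction, computes metagene methylation profiles
    around gene bodies, segments windowed transposable-element content
    with an exact penalized changepoint solver to call TE islands,
    quantifies cross-technology concordance of site tables, and links
    gene-body methylation to expression via FPKM. A fully seeded
    synthetic-methylome generator with known ground truth makes every
    stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, Sequencing, Coverage
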