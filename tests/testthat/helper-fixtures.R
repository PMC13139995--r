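# Small in-code fixtures shared across test files.

# site table from a frequency vector at fixed coverage
makeSites <- function(freqs, coverage = 10, chrom = "chr1",
                      start_pos = 100, spacing = 100, strand = "*") {
  n <- length(freqs)
  cov <- rep(coverage, length.out = n)
  SiteCalls(chrom = rep(chrom, n),
            pos = start_pos + spacing * (seq_len(n) - 1L),
            strand = strand,
            called_reads = cov,
            methylated_reads = as.integer(round(freqs * cov)))
}

# two-gene fixture: plus-strand gene with 2 exons, minus-strand gene with 2
# exons, on one chromosome
tinyGenes <- function() {
  g <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1001, 7001), c(3000, 9000)),
    strand = c("+", "-"))
  names(g) <- c("gA", "gB")
  ex <- GenomicRanges::GRangesList(
    gA = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(1001, 2501), c(1500, 3000)),
      strand = "+"),
    gB = GenomicRanges::GRanges(  # rank 1 = rightmost exon on minus strand
      "chr1", IRanges::IRanges(c(8501, 7001), c(9000, 7500)),
      strand = "-"))
  GeneSet(g, ex)
}

# write a nanopolish-dialect TSV; rows = list of character vectors
writeNanopolishFixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste("chromosome", "strand", "start", "end", "read_name",
                  "log_lik_ratio", "log_lik_methylated",
                  "log_lik_unmethylated", "num_calling_strands",
                  "num_motifs", "sequence", sep = "\t")
  writeLines(c(header, vapply(rows, paste, "", collapse = "\t")), path)
  path
}

nanopolishRow <- function(chrom = "chr1", strand = "+", start = 100,
                          end = NULL, read = "r1", llr = "3.0",
                          num_motifs = 1, sequence = "AAAAACGAAAAA") {
  if (is.null(end)) end <- start
  c(chrom, strand, start, end, read, llr, "1", "1", "1", num_motifs,
    sequence)
}

# a small simulation config that keeps tests fast; overrides win
fastConfig <- function(...) {
  args <- utils::modifyList(
    list(n_chrom = 1L, chrom_length = 500000L, n_genes = 50L,
         gene_length_mean = 2500, n_te_islands_per_chrom = 1L,
         island_width = 80000L),
    list(...))
  do.call(simulationConfig, args)
}
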