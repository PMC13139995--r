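test_that("nanopolish reader parses, splits motif groups, reports errors", {
  # grouped call: 3 CGs in the motif sequence, one shared LLR
  path <- writeNanopolishFixture(list(
    nanopolishRow(start = 100, llr = "4.5", num_motifs = 3,
                  sequence = "AACGTCGAACGTT"),
    nanopolishRow(start = 500, read = "r2", llr = "-3.2")
  ))
  rec <- readNanopolishCalls(path)
  expect_equal(nrow(rec), 4)
  g <- rec[rec$read_id == "r1", ]
  expect_equal(g$llr, rep(4.5, 3))
  # CGs at string offsets 3, 6, 10 -> positions 101, 104, 108 (1-based)
  expect_equal(g$pos, c(101, 104, 108))
  expect_equal(rec$pos[rec$read_id == "r2"], 501)

  nosplit <- readNanopolishCalls(path, split_groups = FALSE)
  expect_equal(nrow(nosplit), 2)
  expect_equal(nosplit$num_motifs, c(3L, 1L))

  # empty file with valid header -> empty stream
  empty <- writeNanopolishFixture(list())
  expect_equal(nrow(readNanopolishCalls(empty)), 0)

  # malformed LLR -> error naming the line
  bad <- writeNanopolishFixture(list(nanopolishRow(llr = "oops")))
  expect_error(readNanopolishCalls(bad), "log_lik_ratio")

  # missing required column -> error naming it
  tmp <- tempfile()
  writeLines(c("chromosome\tstart", "chr1\t5"), tmp)
  expect_error(readNanopolishCalls(tmp), "strand")
})

test_that("aggregation applies the ambiguity threshold and the definition", {
  calls <- data.frame(chrom = "chr1", pos = 100L,
                      strand = "+", read_id = paste0("r", 1:4),
                      llr = c(3.1, 2.5, -4.0, 0.1))
  tab <- aggregateFrequencies(calls, llr_threshold = 2)
  expect_equal(calledReads(tab), 3L)
  expect_equal(methylatedReads(tab), 2L)
  expect_equal(methFrequency(tab), 2 / 3)

  neg <- calls; neg$llr <- c(-3, -4, -5, -2.5)
  expect_equal(methFrequency(aggregateFrequencies(neg, 2)), 0)

  # permutation invariance in record order
  set.seed(5)
  many <- data.frame(chrom = "chr1",
                     pos = sample(c(100L, 200L, 300L), 60, TRUE),
                     strand = "+", read_id = paste0("r", 1:60),
                     llr = rnorm(60, 0, 4))
  a <- aggregateFrequencies(many, 2)
  b <- aggregateFrequencies(many[sample(60), ], 2)
  expect_identical(calledReads(a), calledReads(b))
  expect_identical(methylatedReads(a), methylatedReads(b))

  expect_equal(length(aggregateFrequencies(many[0, ], 2)), 0)
  expect_error(aggregateFrequencies(many, 0))
})

test_that("aggregated frequency recovers the simulated truth", {
  # 1000 reads at one site, true p = 0.25, LLR mu 5 sd 1: binomial oracle
  set.seed(9)
  meth <- rbinom(1000, 1, 0.25)
  calls <- data.frame(chrom = "chr1", pos = 100L, strand = "+",
                      read_id = paste0("r", 1:1000),
                      llr = rnorm(1000, ifelse(meth == 1, 5, -5), 1))
  f <- methFrequency(aggregateFrequencies(calls, 2))
  expect_lt(abs(f - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))
})

test_that("Bismark coverage reader recomputes frequency from counts", {
  tmp <- tempfile()
  writeLines(c("chr1\t101\t101\t50.0\t5\t5",
               "chr1\t205\t205\t40.0\t5\t5",
               "chr2\t10\t10\t0.0\t0\t0"), tmp)
  expect_warning(expect_warning(tab <- readBismarkCoverage(tmp),
                                "zero counts"), "counts win")
  expect_equal(length(tab), 2)
  expect_equal(GenomicRanges::start(tab), c(101L, 205L))
  expect_equal(calledReads(tab), c(10L, 10L))
  expect_equal(methFrequency(tab), c(0.5, 0.5))  # counts beat the 40.0
})

test_that("complementary CpG strands merge by the pairing rule", {
  tab <- SiteCalls(c("chr1", "chr1", "chr1"), c(100L, 101L, 200L),
                   c("+", "-", "+"), c(10L, 10L, 10L), c(5L, 3L, 2L))
  m <- mergeComplementaryCpg(tab)
  expect_equal(length(m), 2)
  merged <- m[GenomicRanges::start(m) == 100]
  expect_equal(as.character(GenomicRanges::strand(merged)), "*")
  expect_equal(calledReads(merged), 20L)
  expect_equal(methFrequency(merged), 0.4)
  # unpaired plus-strand site passes through unchanged
  lone <- m[GenomicRanges::start(m) == 200]
  expect_equal(calledReads(lone), 10L)
  expect_equal(as.character(GenomicRanges::strand(lone)), "+")
})

test_that("strand split then merge is the identity and conserves reads", {
  set.seed(21)
  orig <- makeSites(runif(50), coverage = 30)
  split <- splitStrandCounts(orig, seed = 4)
  expect_equal(sum(calledReads(split)), sum(calledReads(orig)))
  expect_equal(sum(methylatedReads(split)), sum(methylatedReads(orig)))
  back <- mergeComplementaryCpg(split)
  merged <- back[as.character(GenomicRanges::strand(back)) == "*"]
  expect_equal(sum(calledReads(back)), sum(calledReads(orig)))
  expect_equal(sum(methylatedReads(back)), sum(methylatedReads(orig)))
  # every site with reads on both strands merges back at the original pos
  expect_true(all(GenomicRanges::start(merged) %in%
                    GenomicRanges::start(orig)))
})

test_that("coverage filter applies a strict >= rule and reports removals", {
  tab <- makeSites(c(0.1, 0.2, 0.3), coverage = c(9, 10, 11))
  f <- filterSites(tab, 10)
  expect_equal(calledReads(f), c(10L, 11L))
  expect_equal(S4Vectors::metadata(f)$n_removed, 1)
  expect_equal(length(filterSites(tab, 1)), 3)
  none <- filterSites(tab, 100)
  expect_equal(length(none), 0)
  expect_equal(S4Vectors::metadata(none)$n_removed, 3)
})

test_that("low-call sequences are dropped chromosome-wise", {
  tab <- suppressWarnings(SiteCalls(c(
    makeSites(rep(0.1, 5), chrom = "chr1"),
    makeSites(rep(0.1, 10), chrom = "chr2"))))
  idx <- c(chr1 = 100L, chr2 = 100L, chr3 = 0L)
  f <- filterLowCallSequences(tab, idx, 0.10)
  expect_equal(unique(as.character(GenomeInfoDb::seqnames(f))), "chr2")
  expect_equal(S4Vectors::metadata(f)$dropped_sequences, "chr1")
  # exactly 10% is retained (strict less-than)
  expect_equal(length(filterLowCallSequences(tab, c(chr1 = 50L, chr2 = 100L),
                                             0.10)), 15)
  expect_error(filterLowCallSequences(tab, c(chr1 = 100L)), "chr2")
})

test_that("site TSV round trip is the identity", {
  tab <- makeSites(c(0, 0.3, 1), coverage = c(10, 20, 30))
  path <- tempfile(fileext = ".tsv")
  writeSiteTable(tab, path)
  back <- readSiteTable(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(tab))
  expect_equal(calledReads(back), calledReads(tab))
  expect_equal(methylatedReads(back), methylatedReads(tab))
  expect_equal(methFrequency(back), methFrequency(tab))
})

test_that("SiteCalls validity enforces count and uniqueness invariants", {
  expect_error(SiteCalls("chr1", 100L, "*", 5L, 7L), "methylated_reads")
  expect_error(SiteCalls(c("chr1", "chr1"), c(100L, 100L), "*",
                         c(5L, 5L), c(1L, 1L)), "unique")
  tab <- makeSites(c(0.2, 0.4))
  expect_true(all(abs(methFrequency(tab) * calledReads(tab) -
                        methylatedReads(tab)) <= 1e-9))
})
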