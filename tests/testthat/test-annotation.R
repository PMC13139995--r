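test_that("GFF3 reader assigns strand-aware exon ranks and keeps 1-based", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t101\t400\t.\t-\t.\tID=g1",
    "chr1\ttest\tmRNA\t101\t400\t.\t-\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t101\t200\t.\t-\t.\tID=e1;Parent=t1",
    "chr1\ttest\texon\t301\t400\t.\t-\t.\tID=e2;Parent=t1"
  ), gff)
  gs <- readGff3(gff)
  expect_equal(geneIds(gs), "g1")
  g <- geneRanges(gs)
  expect_equal(GenomicRanges::start(g), 101)
  expect_equal(GenomicRanges::end(g), 400)
  # minus strand: rank-1 exon is the rightmost in plus coordinates
  e1 <- geneExons(gs)[["g1"]][1]
  expect_equal(GenomicRanges::start(e1), 301)
  expect_equal(geneTss(gs), 400)
  expect_equal(geneTts(gs), 101)
})

test_that("GFF3 reader collapses to the longest transcript", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t2000\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1001\t1500\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\tmRNA\t1001\t2000\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\ttest\texon\t1001\t1500\t.\t+\t.\tID=e1;Parent=t1",
    "chr1\ttest\texon\t1001\t1200\t.\t+\t.\tID=e2;Parent=t2",
    "chr1\ttest\texon\t1801\t2000\t.\t+\t.\tID=e3;Parent=t2"
  ), gff)
  gs <- readGff3(gff)
  expect_equal(length(geneExons(gs)[["g1"]]), 2)  # t2 chosen
  # orphan exon errors
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t1\t50\t.\t+\t.\tID=e1;Parent=tX"
  ), gff)
  expect_error(readGff3(gff), "parent")
})

test_that("GFF3 write / read round trip preserves gene models", {
  gs <- tinyGenes()
  path <- tempfile(fileext = ".gff3")
  writeGff3(gs, path)
  back <- readGff3(path)
  expect_equal(sort(geneIds(back)), sort(geneIds(gs)))
  for (id in geneIds(gs)) {
    expect_equal(GenomicRanges::start(geneExons(back)[[id]]),
                 GenomicRanges::start(geneExons(gs)[[id]]))
    expect_equal(GenomicRanges::end(geneExons(back)[[id]]),
                 GenomicRanges::end(geneExons(gs)[[id]]))
  }
})

test_that("region assignment follows the fixed precedence", {
  gs <- tinyGenes()
  reps <- RepeatSet("chr1", c(2501, 5000), c(3000, 5400))  # TE over exon 2
  sites <- makeSites(rep(0.5, 5), coverage = 10, start_pos = 1,
                     spacing = 1)
  # hand-placed single sites
  at <- function(p) makeSites(0.5, coverage = 10, start_pos = p)
  lab <- function(p) {
    r <- assignRegion(at(p), gs, reps, promoter_bp = 200)
    list(label = as.character(r$label), rank = r$exon_rank)
  }
  # inside exon 2 of gA which also overlaps the TE -> exon wins, rank 2
  expect_equal(lab(2600), list(label = "exon", rank = 2L))
  # intron of gA
  expect_equal(lab(2000)$label, "intron")
  # 150 bp upstream of gA's TSS (TSS 1001), outside genes/TEs -> promoter
  expect_equal(lab(851)$label, "promoter")
  # plain TE
  expect_equal(lab(5200)$label, "TE")
  # nothing
  expect_equal(lab(6000)$label, "intergenic")
  # minus-strand promoter sits right of the TSS (gB TSS = 9000)
  expect_equal(lab(9100)$label, "promoter")
})

test_that("every site receives exactly one label", {
  set.seed(31)
  gs <- tinyGenes()
  reps <- RepeatSet("chr1", c(2501, 5000), c(3000, 5400))
  sites <- makeSites(runif(200), coverage = 10, start_pos = 10,
                     spacing = 49)
  reg <- assignRegion(sites, gs, reps)
  expect_equal(nrow(reg), length(sites))
  expect_false(any(is.na(reg$label)))
  expect_equal(sum(table(reg$label)), length(sites))
  summ <- regionMethylationSummary(sites, gs, reps)
  expect_equal(sum(summ$n_sites), length(sites))
})

test_that("region summary computes means and flags empty labels", {
  gs <- tinyGenes()
  reps <- RepeatSet(GenomicRanges::GRanges(), te_class = character(0))
  # two sites in exon 1 of gA, equal coverage
  sites <- SiteCalls(c("chr1", "chr1"), c(1100L, 1200L), "*",
                     c(10L, 10L), c(2L, 4L))
  summ <- regionMethylationSummary(sites, gs, reps)
  expect_equal(summ$mean_frequency[summ$label == "exon"], 0.3)
  expect_equal(summ$weighted_methylation[summ$label == "exon"], 0.3)
  te_row <- summ[summ$label == "TE", ]
  expect_equal(te_row$n_sites, 0)
  expect_true(is.na(te_row$mean_frequency))
})

test_that("exon-rank profile pools high ranks and handles empty buckets", {
  gs <- tinyGenes()
  sites <- SiteCalls(c("chr1", "chr1", "chr1"), c(1100L, 2600L, 8600L),
                     "*", rep(10L, 3), c(1L, 5L, 9L))
  prof <- exonRankProfile(sites, gs, max_rank = 3)
  ex <- prof[prof$feature == "exon", ]
  expect_equal(ex$n_sites[ex$rank == 1], 2)  # gA exon1 + gB exon1 (rightmost)
  expect_equal(ex$n_sites[ex$rank == 2], 1)
  expect_equal(ex$n_sites[ex$rank == 3], 0)
  expect_true(is.na(ex$mean_frequency[ex$rank == 3]))
})

test_that("TE context classification uses majority overlap", {
  gs <- tinyGenes()
  # gA intron is (1501, 2500); upstream2kb of gB is (9001, 11000)
  reps <- RepeatSet("chr1",
                    c(1600, 8900, 6000),
                    c(1900, 9600, 6400),
                    te_class = c("LTR", "DNA", "LINE"))
  ctx <- teContextClassify(reps, gs)$te_context
  ctx <- ctx[order(ctx$start), ]  # RepeatSet sorts its ranges
  expect_equal(ctx$context[ctx$start == 1600], "intronic")
  # 600 of 701 bp inside the 2 kb window past gB's TSS
  expect_equal(ctx$context[ctx$start == 8900], "upstream2kb")
  expect_equal(ctx$context[ctx$start == 6000], "intergenic")
})

test_that("windows, coverage fractions and subtraction behave exactly", {
  win <- makeWindows(c(chrA = 125000), width = 50000)
  expect_equal(GenomicRanges::start(win), c(1, 50001, 100001))
  expect_equal(GenomicRanges::end(win), c(50000, 100000, 125000))

  te <- GenomicRanges::GRanges("chrA", IRanges::IRanges(10001, 35000))
  frac <- intervalCoverageFraction(win, te)
  expect_equal(frac, c(0.5, 0, 0))
  # flattening: splitting an interval into abutting pieces changes nothing
  te2 <- GenomicRanges::GRanges("chrA",
                                IRanges::IRanges(c(10001, 20001),
                                                 c(20000, 35000)))
  expect_equal(intervalCoverageFraction(win, te2), frac)
  expect_true(all(frac >= 0 & frac <= 1))

  a <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 100))
  b <- GenomicRanges::GRanges("chrA", IRanges::IRanges(51, 150))
  d <- intervalSubtract(a, b)
  expect_equal(GenomicRanges::start(d), 1)
  expect_equal(GenomicRanges::end(d), 50)
  # bp conservation: subtract + intersect covers exactly a
  i <- GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  expect_equal(sum(GenomicRanges::width(d)) + sum(GenomicRanges::width(i)),
               sum(GenomicRanges::width(GenomicRanges::reduce(a))))
})
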