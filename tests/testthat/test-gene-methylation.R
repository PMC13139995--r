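test_that("weighted methylation is read-count weighted", {
  sites <- SiteCalls(c("chr1", "chr1"), c(100L, 200L), "*",
                     c(10L, 10L), c(2L, 3L))
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  w <- weightedRegionMethylation(sites, region)
  expect_equal(w$weighted_methylation, 0.25)
  expect_equal(w$n_sites, 2)

  single <- SiteCalls("chr1", 100L, "*", 15L, 0L)
  expect_equal(weightedRegionMethylation(single, region)
               $weighted_methylation, 0)

  # equals the simple mean of frequencies at equal coverage
  set.seed(2)
  eq <- makeSites(round(runif(20), 1), coverage = 10)
  region2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
  expect_equal(weightedRegionMethylation(eq, region2)$weighted_methylation,
               mean(methFrequency(eq)))

  # outside any site -> flagged undefined
  far <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10))
  expect_true(is.na(suppressWarnings(
    weightedRegionMethylation(sites, far))$weighted_methylation))
})

test_that("site binarization: binomial mode and threshold mode", {
  sites <- SiteCalls(c("chr1", "chr1"), c(100L, 200L), "*",
                     c(10L, 10L), c(8L, 0L))
  flags <- binarizeSites(sites, error_rate = 0.05)
  expect_equal(flags, c(TRUE, FALSE))
  # the 8/10 upper tail equals the direct-summation oracle
  expect_equal(binomialUpperTail(8, 10, 0.05),
               bfBinomUpperTail(8, 10, 0.05), tolerance = 1e-15)
  expect_lt(binomialUpperTail(8, 10, 0.05), 1e-8)

  # frequency-threshold boundary: 0.49 < 0.5 not flagged, 0.5 flagged
  ft <- SiteCalls(c("chr1", "chr1"), c(100L, 200L), "*",
                  c(100L, 100L), c(49L, 50L))
  expect_equal(binarizeSites(ft, mode = "frequency-threshold",
                             freq_cutoff = 0.5), c(FALSE, TRUE))
  expect_error(binarizeSites(ft, mode = "nope"))
})

# fixture: two genes whose sites we control exactly through the
# frequency-threshold binarization (cutoff 0.5)
.gbmFixture <- function(k_hot = 30, n = 100) {
  g <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(c(1000, 60000),
                                               c(1000 + n * 100,
                                                 60000 + n * 100)),
                              strand = "+")
  names(g) <- c("hot", "cold")
  ex <- GenomicRanges::GRangesList(
    hot = g["hot"], cold = g["cold"])
  genes <- GeneSet(GenomicRanges::granges(g), ex)
  freqs_hot <- c(rep(1, k_hot), rep(0, n - k_hot))
  freqs_cold <- c(rep(1, 3), rep(0, n - 3))
  sites <- suppressWarnings(SiteCalls(c(
    makeSites(freqs_hot, coverage = 10, start_pos = 1050, spacing = 100),
    makeSites(freqs_cold, coverage = 10, start_pos = 60050,
              spacing = 100))))
  list(genes = genes, sites = sites)
}

test_that("gene-body classification matches the exact binomial tails", {
  fx <- .gbmFixture()
  res <- classifyGeneBodies(fx$genes, fx$sites, background_p = 0.03,
                            site_mode = "frequency-threshold")
  hot <- res[res$gene_id == "hot", ]
  cold <- res[res$gene_id == "cold", ]
  expect_equal(hot$n_sites, 100L)
  expect_equal(hot$n_methylated_sites, 30L)
  # upper-tail p-values equal the direct summation oracle
  expect_equal(hot$p_value, bfBinomUpperTail(30, 100, 0.03),
               tolerance = 1e-12)
  expect_lt(hot$p_value, 1e-6)
  expect_equal(cold$p_value, bfBinomUpperTail(3, 100, 0.03),
               tolerance = 1e-12)
  expect_equal(cold$p_value, 0.58, tolerance = 0.01)
  expect_equal(hot$class, "GBM")
  expect_equal(cold$class, "UM")
})

test_that("genes without covered sites are unclassified, accounting holds", {
  fx <- .gbmFixture()
  # add a third gene with no sites
  g <- c(geneRanges(fx$genes),
         GenomicRanges::GRanges("chr1", IRanges::IRanges(200000, 205000),
                                strand = "+"))
  names(g)[3] <- "empty"
  genes <- GeneSet(g, c(geneExons(fx$genes),
                        GenomicRanges::GRangesList(empty = g[3])))
  res <- classifyGeneBodies(genes, fx$sites, background_p = 0.03,
                            site_mode = "frequency-threshold")
  expect_equal(res$class[res$gene_id == "empty"], "unclassified")
  expect_true(is.na(res$p_value[res$gene_id == "empty"]))
  expect_equal(sum(res$class %in% c("GBM", "UM", "unclassified")),
               nrow(res))
  # BH family excludes the unclassified gene: q of classified genes equals
  # BH over their two p-values alone
  cl <- res[res$class != "unclassified", ]
  expect_equal(cl$q_value, bhAdjust(cl$p_value))
})

test_that("classification is invariant to site order and chromosome split", {
  fx <- .gbmFixture()
  res1 <- classifyGeneBodies(fx$genes, fx$sites, background_p = 0.03,
                             site_mode = "frequency-threshold")
  shuffled <- fx$sites[sample(length(fx$sites))]
  res2 <- classifyGeneBodies(fx$genes, SiteCalls(shuffled),
                             background_p = 0.03,
                             site_mode = "frequency-threshold")
  expect_equal(res1, res2)
})

test_that("raising the background never increases the GBM count", {
  fx <- .gbmFixture(k_hot = 12)
  counts <- vapply(c(0.01, 0.03, 0.06, 0.10, 0.2), function(p0) {
    sum(classifyGeneBodies(fx$genes, fx$sites, background_p = p0,
                           site_mode = "frequency-threshold")
        $class == "GBM")
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("promoter classification applies the 3% floor rule", {
  # promoter window [800, 999] of a gene at 1000; 40 sites at freq 0.025:
  # highly significant against a tiny background, yet below the floor
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 5000),
                              strand = "+")
  names(g) <- "gP"
  genes <- GeneSet(g, GenomicRanges::GRangesList(gP = g))
  prom_sites <- makeSites(rep(1, 8), coverage = 40, start_pos = 805,
                          spacing = 25)
  # 8 of 8 promoter sites flagged; weighted methylation 1.0 -> PMG
  res <- classifyPromoters(genes, prom_sites, background_p = 0.01,
                           site_mode = "frequency-threshold",
                           promoter_bp = 200)
  expect_equal(res$class, "PMG")
  # same significance pattern but weighted methylation 0.025 -> PUM
  low <- SiteCalls(rep("chr1", 8), seq(805, by = 25, length.out = 8),
                   "*", rep(40L, 8), rep(1L, 8))  # freq 0.025 each
  res_low <- classifyPromoters(genes, low, background_p = 0.001,
                               site_mode = "frequency-threshold",
                               site_freq_cutoff = 0.02, promoter_bp = 200)
  expect_equal(res_low$n_methylated_sites, 8L)
  expect_lt(res_low$q_value, 0.05)
  expect_equal(res_low$weighted_methylation, 0.025)
  expect_equal(res_low$class, "PUM")
  # promoter with k = 0 -> PUM
  zero <- SiteCalls("chr1", 900L, "*", 40L, 0L)
  expect_equal(classifyPromoters(genes, zero, background_p = 0.01,
                                 site_mode = "frequency-threshold")$class,
               "PUM")
  # no covered promoter sites -> unclassified
  none <- SiteCalls("chr1", 4000L, "*", 40L, 0L)
  expect_equal(classifyPromoters(genes, none, background_p = 0.01,
                                 site_mode = "frequency-threshold")$class,
               "unclassified")
})

test_that("metagene profile is strand-aware with the declared bin layout", {
  gs <- tinyGenes()
  prof <- metaProfile(gs, makeSites(0.5), upstream_bp = 4000,
                      downstream_bp = 4000, n_body_bins = 40,
                      flank_bin_bp = 200)
  expect_equal(sum(prof$segment == "upstream"), 20)
  expect_equal(sum(prof$segment == "body"), 40)
  expect_equal(sum(prof$segment == "downstream"), 20)

  # gB is minus-strand with TSS 9000: a site 100 bp plus-strand-right of
  # the TSS is 100 bp upstream -> upstream bin 1
  s <- SiteCalls("chr1", 9100L, "*", 10L, 5L)
  p <- metaProfile(gs, s)
  up <- p[p$segment == "upstream", ]
  expect_equal(up$n_sites[up$bin == 1], 1)
  expect_equal(sum(up$n_sites), 1)

  # a site 50 bp into gB's body (plus-strand-left of TSS) -> early body bin
  s2 <- SiteCalls("chr1", 8950L, "*", 10L, 5L)
  p2 <- metaProfile(gs, s2)
  body <- p2[p2$segment == "body", ]
  expect_equal(body$n_sites[body$bin == 2], 1)  # 50/2000 * 40 = bin 2
})

test_that("GBM-planted synthetic data: body bins exceed flank bins", {
  sim <- simulateMethylome(fastConfig(seed = 101))
  prof <- metaProfile(sim$genes, sim$sites)
  body <- prof[prof$segment == "body", "weighted_methylation"]
  flank <- prof[prof$segment != "body", "weighted_methylation"]
  expect_gt(mean(body, na.rm = TRUE), mean(flank, na.rm = TRUE))
})

test_that("stage overlap reports shared methylated genes", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"),
                  class = c("GBM", "GBM", "UM"))
  b <- data.frame(gene_id = c("g1", "g2", "g3"),
                  class = c("GBM", "UM", "UM"))
  ov <- stageOverlap(list(s1 = a, s2 = b))
  expect_equal(ov$shared_all, "g1")
  expect_equal(unname(ov$counts), c(2L, 1L))
  expect_equal(unname(ov$shared_percent), c(50, 100))
})
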