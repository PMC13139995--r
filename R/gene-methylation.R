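#' Coverage-weighted methylation of a region set
#'
#' The weighted methylation level of a region: sum of methylated read
#' counts over sum of called read counts across all CpG sites falling in
#' the region (coverage-weighted, not a mean of frequencies). When all
#' coverages are equal it reduces to the simple mean of site frequencies.
#'
#' @param sites A [SiteCalls-class] table (already coverage-filtered).
#' @param region `GRanges` defining the region (may have several ranges).
#' @return List: `n_sites`, `methylated_reads`, `called_reads`,
#'   `weighted_methylation` (`NA` when no called reads fall in the region).
#' @export
weightedRegionMethylation <- function(sites, region) {
  i <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
    GenomicRanges::granges(sites), GenomicRanges::granges(region),
    ignore.strand = TRUE)))
  mr <- sum(methylatedReads(sites)[i])
  cr <- sum(calledReads(sites)[i])
  list(n_sites = length(i), methylated_reads = mr, called_reads = cr,
       weighted_methylation = if (cr > 0) mr / cr else NA_real_)
}

# per-site membership + per-range aggregation helper: for each range in
# `regions`, counts of covered sites, methylated (binarized) sites and read
# sums. `flags` = per-site logical.
.perRangeSiteStats <- function(sites, regions, flags) {
  n <- length(regions)
  hits <- GenomicRanges::findOverlaps(GenomicRanges::granges(sites),
                                      GenomicRanges::granges(regions),
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  agg <- function(v, f) {
    out <- rep(0, n)
    if (length(sh)) {
      a <- tapply(v[qh], sh, f)
      out[as.integer(names(a))] <- as.numeric(a)
    }
    out
  }
  data.frame(
    n_sites = agg(rep(1L, length(sites)), sum),
    n_methylated_sites = agg(as.integer(flags), sum),
    methylated_reads = agg(methylatedReads(sites), sum),
    called_reads = agg(calledReads(sites), sum)
  )
}

#' Binarize CpG sites into methylated / unmethylated
#'
#' Two modes. `site-binomial` (default): a one-sided binomial test of
#' `methylated_reads` out of `called_reads` against the per-read error rate
#' `error_rate`, Benjamini-Hochberg corrected across all sites; a site is
#' methylated when `q < alpha`. `frequency-threshold`: methylated when
#' `frequency >= freq_cutoff`.
#'
#' @param sites A [SiteCalls-class] table (coverage-filtered).
#' @param mode `"site-binomial"` or `"frequency-threshold"`.
#' @param error_rate Per-read false-methylation rate epsilon (default 0.05).
#' @param freq_cutoff Frequency cutoff (default 0.5).
#' @param alpha FDR level for the binomial mode (default 0.05).
#' @return Logical vector, one flag per site.
#' @examples
#' x <- SiteCalls("chr1", c(100, 200), "*", c(10, 10), c(8, 0))
#' binarizeSites(x) # TRUE FALSE
#' @export
binarizeSites <- function(sites, mode = c("site-binomial",
                                          "frequency-threshold"),
                          error_rate = 0.05, freq_cutoff = 0.5,
                          alpha = 0.05) {
  mode <- match.arg(mode)
  if (mode == "frequency-threshold") {
    return(methFrequency(sites) >= freq_cutoff)
  }
  p <- binomialUpperTail(methylatedReads(sites), calledReads(sites),
                         error_rate)
  q <- bhAdjust(p)
  q < alpha
}

.classifyRegions <- function(sites, regions, region_name, gene_ids,
                             alpha, background_p, site_mode, error_rate,
                             freq_cutoff, site_alpha) {
  flags <- binarizeSites(sites, mode = site_mode, error_rate = error_rate,
                         freq_cutoff = freq_cutoff, alpha = site_alpha)
  if (is.null(background_p)) background_p <- mean(flags)
  st <- .perRangeSiteStats(sites, regions, flags)
  covered <- st$n_sites > 0
  p <- rep(NA_real_, length(regions))
  p[covered] <- binomialUpperTail(st$n_methylated_sites[covered],
                                  st$n_sites[covered], background_p)
  q <- rep(NA_real_, length(regions))
  q[covered] <- bhAdjust(p[covered])
  data.frame(
    gene_id = gene_ids,
    region = region_name,
    n_sites = as.integer(st$n_sites),
    n_methylated_sites = as.integer(st$n_methylated_sites),
    weighted_methylation = ifelse(st$called_reads > 0,
                                  st$methylated_reads / st$called_reads,
                                  NA_real_),
    p_value = p,
    q_value = q,
    background_p = background_p,
    stringsAsFactors = FALSE
  )
}

#' Classify genes as gene-body methylated (GBM) or unmethylated (UM)
#'
#' The Takuno-Gaut construction: sites are first binarized (see
#' [binarizeSites()]); then for each gene body (TSS to TTS, introns
#' included) the count `k` of methylated sites out of `n` covered sites is
#' tested against the genome-wide methylated-site fraction `p0` with a
#' one-sided binomial upper tail, Benjamini-Hochberg corrected across genes
#' (per stage). A gene is GBM when `q < alpha`, UM otherwise; genes without
#' covered sites are `unclassified` and excluded from the BH family.
#'
#' @param genes A [GeneSet-class].
#' @param sites A [SiteCalls-class] table for one stage/caste,
#'   coverage-filtered.
#' @param alpha FDR level (default 0.05).
#' @param background_p Genome-wide methylated-site fraction `p0`; default
#'   `NULL` uses the observed fraction of binarized-methylated sites in
#'   `sites` (the stage's own genome-wide average).
#' @param site_mode,site_error_rate,site_freq_cutoff,site_alpha Passed to
#'   [binarizeSites()].
#' @return data.frame (one row per gene): `gene_id`, `region`, `n_sites`,
#'   `n_methylated_sites`, `weighted_methylation`, `p_value`, `q_value`,
#'   `background_p`, `class` in `{GBM, UM, unclassified}`.
#' @export
classifyGeneBodies <- function(genes, sites, alpha = 0.05,
                               background_p = NULL,
                               site_mode = "site-binomial",
                               site_error_rate = 0.05,
                               site_freq_cutoff = 0.5,
                               site_alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  res <- .classifyRegions(sites, geneRanges(genes), "body", geneIds(genes),
                          alpha, background_p, site_mode, site_error_rate,
                          site_freq_cutoff, site_alpha)
  res$class <- ifelse(res$n_sites == 0, "unclassified",
                      ifelse(res$q_value < alpha, "GBM", "UM"))
  if (!is.null(background_p) && background_p == 0 &&
      any(res$n_methylated_sites > 0)) {
    res$zero_background <- TRUE
  }
  res
}

#' Classify promoters as methylated (PMG) or unmethylated (PUM)
#'
#' Same binomial + BH machinery as [classifyGeneBodies()] applied to the
#' promoter window (`promoter_bp` upstream of the TSS, strand-aware), with
#' one extra rule: a promoter is PMG only if `q < alpha` AND its weighted
#' methylation exceeds `promoter_floor` (default 0.03, i.e. a promoter is
#' only considered methylated above the 3% level); otherwise PUM. Promoters
#' without covered sites are `unclassified`.
#'
#' @inheritParams classifyGeneBodies
#' @param promoter_bp Promoter width upstream of the TSS (default 200).
#' @param promoter_floor Minimum weighted methylation for PMG (default
#'   0.03).
#' @return data.frame as [classifyGeneBodies()] with `class` in
#'   `{PMG, PUM, unclassified}`.
#' @export
classifyPromoters <- function(genes, sites, alpha = 0.05,
                              background_p = NULL, promoter_bp = 200,
                              promoter_floor = 0.03,
                              site_mode = "site-binomial",
                              site_error_rate = 0.05,
                              site_freq_cutoff = 0.5,
                              site_alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  prom <- .promoterRanges(genes, promoter_bp)
  res <- .classifyRegions(sites, prom, "promoter", geneIds(genes),
                          alpha, background_p, site_mode, site_error_rate,
                          site_freq_cutoff, site_alpha)
  wm <- res$weighted_methylation
  res$class <- ifelse(res$n_sites == 0, "unclassified",
                      ifelse(res$q_value < alpha & !is.na(wm) &
                               wm > promoter_floor, "PMG", "PUM"))
  res
}

#' Metagene methylation profile
#'
#' Pools weighted methylation into bins along a normalized gene axis:
#' fixed-width flank bins over `upstream_bp` upstream of the TSS and
#' `downstream_bp` downstream of the TTS (strand-aware), and
#' `n_body_bins` proportionally scaled bins across each gene body. Per bin,
#' methylation is coverage-weighted across all sites of all genes falling
#' in it. Genes shorter than `n_body_bins` bp simply spread their sites
#' over proportional bins.
#'
#' @param genes A [GeneSet-class].
#' @param sites A [SiteCalls-class] table.
#' @param upstream_bp,downstream_bp Flank widths (default 4000 bp each).
#' @param n_body_bins Number of scaled body bins (default 40).
#' @param flank_bin_bp Width of each flank bin (default 200 bp, giving 20
#'   bins per 4 kb flank).
#' @return data.frame: `segment` (upstream/body/downstream), `bin`
#'   (1-based within segment; body bins run 5'-to-3', flank bins number
#'   outward from the gene so bin 1 is adjacent to the TSS/TTS),
#'   `n_sites`, `methylated_reads`, `called_reads`,
#'   `weighted_methylation`.
#' @export
metaProfile <- function(genes, sites, upstream_bp = 4000,
                        downstream_bp = 4000, n_body_bins = 40,
                        flank_bin_bp = 200) {
  g <- geneRanges(genes)
  minus <- as.character(GenomicRanges::strand(g)) == "-"
  tss <- geneTss(genes); tts <- geneTts(genes)
  s <- GenomicRanges::granges(sites)
  GenomicRanges::strand(s) <- "*"
  spos <- GenomicRanges::start(s)
  mr <- methylatedReads(sites); cr <- calledReads(sites)
  n_up <- as.integer(ceiling(upstream_bp / flank_bin_bp))
  n_dn <- as.integer(ceiling(downstream_bp / flank_bin_bp))

  collect <- function(regions, relFun, n_bins, segment) {
    hits <- GenomicRanges::findOverlaps(s, regions, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    bin <- relFun(spos[qh], sh)
    bin <- pmin(pmax(bin, 1L), n_bins)
    out <- data.frame(segment = segment, bin = seq_len(n_bins),
                      n_sites = 0L, methylated_reads = 0,
                      called_reads = 0)
    if (length(qh)) {
      out$n_sites <- as.integer(tabulate(bin, n_bins))
      for (col in c("methylated_reads", "called_reads")) {
        v <- if (col == "methylated_reads") mr[qh] else cr[qh]
        a <- tapply(v, bin, sum)
        out[[col]][as.integer(names(a))] <- as.numeric(a)
      }
    }
    out$weighted_methylation <- ifelse(out$called_reads > 0,
                                       out$methylated_reads /
                                         out$called_reads, NA_real_)
    out
  }

  # upstream flank: [tss - upstream_bp, tss - 1] on the gene's 5' side
  upr <- GenomicRanges::trim(GenomicRanges::promoters(
    g, upstream = upstream_bp, downstream = 0))
  up <- collect(upr, function(p, i) {
    d <- ifelse(minus[i], p - tss[i], tss[i] - p)  # 1..upstream_bp from TSS
    as.integer(ceiling(d / flank_bin_bp))
  }, n_up, "upstream")

  body <- collect(g, function(p, i) {
    len <- GenomicRanges::width(g)[i]
    d <- ifelse(minus[i], tss[i] - p, p - tss[i])  # 0..len-1 from TSS
    as.integer(floor(d / len * n_body_bins)) + 1L
  }, n_body_bins, "body")

  dnr <- GenomicRanges::trim(GenomicRanges::flank(
    g, width = downstream_bp, start = FALSE, ignore.strand = FALSE))
  dn <- collect(dnr, function(p, i) {
    d <- ifelse(minus[i], tts[i] - p, p - tts[i])  # 1..downstream_bp
    as.integer(ceiling(d / flank_bin_bp))
  }, n_dn, "downstream")

  rbind(up, body, dn)
}

#' Write a per-stage gene classification table
#'
#' TSV column order: gene_id, region, n_sites, n_methylated_sites,
#' weighted_methylation, p_value, q_value, class.
#'
#' @param classification data.frame from [classifyGeneBodies()] or
#'   [classifyPromoters()].
#' @param path Output file.
#' @export
writeClassification <- function(classification, path) {
  cols <- c("gene_id", "region", "n_sites", "n_methylated_sites",
            "weighted_methylation", "p_value", "q_value", "class")
  writeTsv(classification[, cols], path)
}

#' Stage-overlap of methylated gene sets
#'
#' Pairwise and all-stage intersections of GBM (or PMG) gene-id sets, with
#' shared percentages reported against each stage's own methylated-gene
#' count.
#'
#' @param class_list Named list of classification data.frames (one per
#'   stage).
#' @param class_label Which class counts as methylated (default `"GBM"`).
#' @return List: `counts` (per-stage methylated counts), `shared_all`
#'   (ids in every stage), `shared_percent` (vs each stage's own count).
#' @export
stageOverlap <- function(class_list, class_label = "GBM") {
  sets <- lapply(class_list, function(d) d$gene_id[d$class == class_label])
  shared <- Reduce(intersect, sets)
  counts <- vapply(sets, length, 1L)
  list(counts = counts, shared_all = shared,
       shared_percent = 100 * length(shared) / pmax(counts, 1L))
}
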