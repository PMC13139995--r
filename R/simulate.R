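#' SimulationConfig: parameters of the synthetic methylome generator
#'
#' Defaults emulate the statistical structure of an ant-scale CpG
#' methylome at desk scale: a multi-chromosome genome, ~3% background
#' CpG methylation, a planted set of gene-body-methylated (GBM) genes at
#' 30% per-site methylation, promoter-methylated (PMG) genes planted
#' independently, TE copies clustered into islands, ~30x per-site read
#' coverage, and gene expression tied to gene-body methylation with a
#' configurable slope and noise. Identical config + seed gives
#' byte-identical outputs.
#'
#' @slot seed Master seed; every stochastic step derives its own stream
#'   from it via [mixSeed()], keyed by stage/chromosome/replicate, so
#'   partial regeneration is stable.
#' @slot n_chrom,chrom_length Genome shape (default 2 x 2 Mb).
#' @slot n_genes Total genes genome-wide (default 200).
#' @slot gene_length_mean Mean gene-body length in bp (default 3000; gene
#'   bodies are never shorter than 20 CpG spacings, so every gene carries
#'   enough sites for classification).
#' @slot exons_per_gene_mean Mean exon count (default 4).
#' @slot n_te_islands_per_chrom,island_width Planted TE islands (default
#'   2 per chromosome, 300 kb wide — TE islands span many 50 kb analysis
#'   windows, as in real repeat landscapes).
#' @slot te_density_island,te_density_background TE bp density inside
#'   islands vs elsewhere (defaults 0.6 / 0.08).
#' @slot p_background Per-site background methylation probability
#'   (default 0.03, the genome-wide low-methylation regime).
#' @slot gbm_fraction Fraction of genes planted GBM (default 0.3;
#'   exactly `floor(gbm_fraction * n_genes)` genes).
#' @slot p_gbm_site Per-site methylation probability inside GBM gene
#'   bodies (default 0.30).
#' @slot pmg_fraction,p_pmg_site Promoter planting, independent of GBM
#'   status (defaults 0.1 and 0.5; promoters are short, so the planted
#'   per-site level is high — promoter methylation is near-bimodal).
#' @slot promoter_bp Promoter width used for planting (default 200).
#' @slot cpg_spacing CpG sites sit on a regular grid with this spacing
#'   (default 100 bp); only positions and counts matter downstream, so no
#'   sequence is simulated.
#' @slot jitter_concentration Beta concentration of per-site jitter
#'   around the regime probability (default 50), giving the
#'   overdispersion real methylomes show.
#' @slot coverage_mean Poisson mean reads per site (default 30).
#' @slot llr_mu,llr_sigma Read-level LLR distribution: methylated reads
#'   draw `Normal(+llr_mu, llr_sigma)`, unmethylated
#'   `Normal(-llr_mu, llr_sigma)` (defaults 5 and 1.5).
#' @slot expr_slope,expr_intercept,expr_noise_sd The planted
#'   `log(1 + FPKM) = intercept + slope * methylation + Normal(0, sd)`
#'   relationship (defaults 3, 2, 1 — implying r ~ 0.35 at the default
#'   methylation spread).
#' @slot n_expression_samples Expression samples (default 22).
#' @slot library_size_mean Mean per-sample total mapped reads (1e6).
#' @export
setClass("SimulationConfig", representation(
  seed = "integer", n_chrom = "integer", chrom_length = "integer",
  n_genes = "integer", gene_length_mean = "numeric",
  exons_per_gene_mean = "numeric", n_te_islands_per_chrom = "integer",
  island_width = "integer", te_density_island = "numeric",
  te_density_background = "numeric", p_background = "numeric",
  gbm_fraction = "numeric", p_gbm_site = "numeric",
  pmg_fraction = "numeric", p_pmg_site = "numeric",
  promoter_bp = "integer", cpg_spacing = "integer",
  jitter_concentration = "numeric", coverage_mean = "numeric",
  llr_mu = "numeric", llr_sigma = "numeric", expr_slope = "numeric",
  expr_intercept = "numeric", expr_noise_sd = "numeric",
  n_expression_samples = "integer", library_size_mean = "numeric"
))

.validSimulationConfig <- function(object) {
  msg <- NULL
  fr <- c(te_density_island = object@te_density_island,
          te_density_background = object@te_density_background,
          p_background = object@p_background,
          gbm_fraction = object@gbm_fraction,
          p_gbm_site = object@p_gbm_site,
          pmg_fraction = object@pmg_fraction,
          p_pmg_site = object@p_pmg_site)
  bad <- fr < 0 | fr > 1
  if (any(bad)) {
    msg <- c(msg, paste0("fraction(s) outside [0,1]: ",
                         paste(names(fr)[bad], collapse = ", ")))
  }
  if (object@p_gbm_site <= object@p_background) {
    msg <- c(msg, "p_gbm_site must exceed p_background")
  }
  if (object@n_chrom < 1 || object@chrom_length < 1 || object@n_genes < 1) {
    msg <- c(msg, "genome shape parameters must be positive")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("SimulationConfig", .validSimulationConfig)

#' @rdname SimulationConfig-class
#' @param ... Named slot overrides (see slots for defaults).
#' @examples
#' simulationConfig(seed = 7, n_genes = 100)
#' @export
simulationConfig <- function(...) {
  defaults <- list(
    seed = 1L, n_chrom = 2L, chrom_length = 2000000L, n_genes = 200L,
    gene_length_mean = 3000, exons_per_gene_mean = 4,
    n_te_islands_per_chrom = 2L, island_width = 300000L,
    te_density_island = 0.6, te_density_background = 0.08,
    p_background = 0.03, gbm_fraction = 0.3, p_gbm_site = 0.30,
    pmg_fraction = 0.1, p_pmg_site = 0.5, promoter_bp = 200L,
    cpg_spacing = 100L, jitter_concentration = 50, coverage_mean = 30,
    llr_mu = 5, llr_sigma = 1.5, expr_slope = 3, expr_intercept = 2,
    expr_noise_sd = 1, n_expression_samples = 22L,
    library_size_mean = 1e6
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  vals <- utils::modifyList(defaults, over)
  int_slots <- c("seed", "n_chrom", "chrom_length", "n_genes",
                 "n_te_islands_per_chrom", "island_width", "promoter_bp",
                 "cpg_spacing", "n_expression_samples")
  for (s in int_slots) vals[[s]] <- as.integer(vals[[s]])
  do.call(new, c(list("SimulationConfig"), vals))
}

#' GroundTruth: simulation manifest
#'
#' Everything a recovery test needs to score the pipeline against the
#' planted signal.
#'
#' @slot gbm_genes,pmg_genes Planted gene-id sets.
#' @slot islands Planted TE-island intervals (`GRanges`, disjoint,
#'   sorted, within chromosome bounds).
#' @slot site_probs All simulated CpG sites with their true per-site
#'   methylation probability (`GRanges`, mcol `true_p`).
#' @slot expr_slope,expr_intercept,expr_noise_sd Planted expression
#'   relationship.
#' @slot planted_r Implied methylation-expression correlation (set by
#'   [simulateExpression()]; `NA` before).
#' @export
setClass("GroundTruth", representation(
  gbm_genes = "character", pmg_genes = "character", islands = "GRanges",
  site_probs = "GRanges", expr_slope = "numeric",
  expr_intercept = "numeric", expr_noise_sd = "numeric",
  planted_r = "numeric"
))

.validGroundTruth <- function(object) {
  msg <- NULL
  isl <- object@islands
  if (length(isl) > 1L) {
    srt <- GenomicRanges::sort(isl, ignore.strand = TRUE)
    if (!all(GenomicRanges::start(srt) == GenomicRanges::start(isl)) ||
        !all(as.character(GenomeInfoDb::seqnames(srt)) ==
               as.character(GenomeInfoDb::seqnames(isl)))) {
      msg <- c(msg, "islands must be sorted")
    }
    red <- GenomicRanges::reduce(isl, min.gapwidth = 0L,
                                 ignore.strand = TRUE)
    if (length(red) != length(isl)) msg <- c(msg, "islands must be disjoint")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("GroundTruth", .validGroundTruth)

# alternating exponential cover process: intervals of expected density d
# over [from, to], mean interval length len_mean (300 bp, the scale of
# fragmented RepeatMasker hits, so 50 kb windows average over many copies)
.coverProcess <- function(from, to, density, len_mean = 300) {
  if (density <= 0 || to < from) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  if (density >= 1) return(cbind(start = from, end = to))
  gap_mean <- len_mean * (1 - density) / density
  out <- list()
  pos <- from + round(stats::rexp(1, 1 / gap_mean))
  while (pos <= to) {
    len <- max(50, round(stats::rexp(1, 1 / len_mean)))
    out[[length(out) + 1L]] <- c(pos, min(pos + len - 1, to))
    pos <- pos + len + max(1, round(stats::rexp(1, 1 / gap_mean)))
  }
  if (!length(out)) return(cbind(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  cbind(start = m[, 1], end = m[, 2])
}

#' Generate a synthetic annotated genome with known ground truth
#'
#' Lays out per chromosome: non-overlapping gene bodies with exons
#' (strand randomized, exon ranks 5'-to-3'), TE islands placed disjointly
#' (one per equal-width sector, so `island_width * n` must fit the
#' chromosome), TE copies at `te_density_island` inside islands and
#' `te_density_background` elsewhere, and a regular CpG grid whose true
#' per-site methylation probability is `p_gbm_site` inside planted GBM
#' gene bodies, `p_pmg_site` inside planted PMG promoters and
#' `p_background` elsewhere, each with Beta-distributed per-site jitter.
#'
#' @param config A [SimulationConfig-class].
#' @return List: `genes` ([GeneSet-class]), `repeats`
#'   ([RepeatSet-class]), `truth` ([GroundTruth-class]), `chrom_sizes`.
#' @export
simulateAnnotation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  chroms <- paste0("chr", seq_len(config@n_chrom))
  chrom_sizes <- stats::setNames(rep(config@chrom_length, config@n_chrom),
                                 chroms)
  min_len <- max(20L * config@cpg_spacing, 500L)
  n_per <- diff(round(seq(0, config@n_genes,
                          length.out = config@n_chrom + 1)))

  gene_rows <- list(); exon_list <- list(); island_rows <- list()
  te_rows <- list()
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    # ---- islands: one per equal sector, random offset within it
    nisl <- config@n_te_islands_per_chrom
    if (nisl > 0) {
      sector <- config@chrom_length %/% nisl
      if (config@island_width > sector) {
        stop("infeasible packing: island_width * n_te_islands_per_chrom ",
             "exceeds chrom_length")
      }
      withSeed(mixSeed(config@seed, "islands", chrom), {
        off <- floor(stats::runif(nisl, 0, sector - config@island_width))
        starts <- (seq_len(nisl) - 1L) * sector + off + 1L
      })
      island_rows[[chrom]] <- data.frame(
        chrom = chrom, start = as.integer(starts),
        end = as.integer(starts + config@island_width - 1L))
    }
    # ---- TE copies: island density inside, background elsewhere
    withSeed(mixSeed(config@seed, "te", chrom), {
      bounds <- if (nisl > 0) island_rows[[chrom]] else NULL
      segs <- list()
      cur <- 1L
      if (!is.null(bounds)) {
        for (k in seq_len(nrow(bounds))) {
          if (bounds$start[k] > cur) {
            segs[[length(segs) + 1L]] <-
              list(cur, bounds$start[k] - 1L, config@te_density_background)
          }
          segs[[length(segs) + 1L]] <-
            list(bounds$start[k], bounds$end[k], config@te_density_island)
          cur <- bounds$end[k] + 1L
        }
      }
      if (cur <= config@chrom_length) {
        segs[[length(segs) + 1L]] <-
          list(cur, config@chrom_length, config@te_density_background)
      }
      tes <- do.call(rbind, lapply(segs, function(s) {
        .coverProcess(s[[1]], s[[2]], s[[3]])
      }))
      if (!is.null(tes) && nrow(tes)) {
        te_rows[[chrom]] <- data.frame(
          chrom = chrom, start = tes[, "start"], end = tes[, "end"],
          te_class = sample(c("LTR", "DNA", "LINE", "SINE"), nrow(tes),
                            replace = TRUE, prob = c(0.35, 0.3, 0.2, 0.15)))
      }
    })
    # ---- genes: sequential layout with random gaps
    ng <- n_per[ci]
    if (ng > 0) {
      withSeed(mixSeed(config@seed, "genes", chrom), {
        lens <- pmax(min_len, round(stats::rgamma(
          ng, shape = 4, scale = config@gene_length_mean / 4)))
        margin <- 5000L
        free <- config@chrom_length - 2L * margin - sum(lens)
        if (free < 200L * (ng + 1L)) {
          stop("infeasible packing: requested genes exceed chromosome ",
               "capacity (need ", sum(lens) + 200L * (ng + 1L) +
                 2L * margin, " bp, have ", config@chrom_length, ")")
        }
        w <- stats::runif(ng + 1L, 0.5, 1.5)
        gaps <- floor(free * w / sum(w))
        starts <- margin + cumsum(gaps[seq_len(ng)]) +
          c(0, cumsum(lens))[seq_len(ng)] + 1L
        strands <- sample(c("+", "-"), ng, replace = TRUE)
        ids <- sprintf("%s_g%04d", chrom, seq_len(ng))
        gene_rows[[chrom]] <- data.frame(
          gene_id = ids, chrom = chrom, start = as.integer(starts),
          end = as.integer(starts + lens - 1L), strand = strands)
        # exon/intron structure per gene
        for (gi in seq_len(ng)) {
          L <- lens[gi]
          nex <- 1L + stats::rpois(1, max(0, config@exons_per_gene_mean - 1))
          nparts <- 2L * nex - 1L
          while (nparts * 60L > L) {
            nex <- nex - 1L
            nparts <- 2L * nex - 1L
          }
          wpart <- stats::runif(nparts, 0.5, 1.5)
          plen <- pmax(50L, floor(L * wpart / sum(wpart)))
          plen[nparts] <- L - sum(plen[-nparts])
          if (plen[nparts] < 50L) {  # degenerate split: single-exon gene
            nparts <- 1L
            plen <- L
          }
          pend <- cumsum(plen)
          pstart <- pend - plen + 1L
          ex_idx <- seq(1L, nparts, by = 2L)
          exon_list[[ids[gi]]] <- GenomicRanges::GRanges(
            chrom,
            IRanges::IRanges(starts[gi] + pstart[ex_idx] - 1L,
                             starts[gi] + pend[ex_idx] - 1L),
            strand = strands[gi])
        }
      })
    }
  }
  gene_df <- do.call(rbind, gene_rows)
  genes_gr <- GenomicRanges::GRanges(
    gene_df$chrom, IRanges::IRanges(gene_df$start, gene_df$end),
    strand = gene_df$strand)
  names(genes_gr) <- gene_df$gene_id
  GenomeInfoDb::seqlevels(genes_gr) <- chroms
  exl <- GenomicRanges::GRangesList(exon_list[gene_df$gene_id])
  genes <- GeneSet(genes_gr, .orientExons(exl, genes_gr))

  te_df <- do.call(rbind, te_rows)
  repeats <- if (!is.null(te_df) && nrow(te_df)) {
    RepeatSet(te_df$chrom, te_df$start, te_df$end, te_df$te_class)
  } else {
    RepeatSet(GenomicRanges::GRanges(), te_class = character(0))
  }

  # ---- planted gene classes
  n_gbm <- floor(config@gbm_fraction * config@n_genes)
  n_pmg <- floor(config@pmg_fraction * config@n_genes)
  gbm <- withSeed(mixSeed(config@seed, "gbm"),
                  sort(sample(gene_df$gene_id, n_gbm)))
  pmg <- withSeed(mixSeed(config@seed, "pmg"),
                  sort(sample(gene_df$gene_id, n_pmg)))

  # ---- CpG grid with true per-site probabilities
  site_list <- lapply(chroms, function(chrom) {
    pos <- seq.int(config@cpg_spacing %/% 2L, config@chrom_length,
                   by = config@cpg_spacing)
    gr <- GenomicRanges::GRanges(factor(chrom, levels = chroms),
                                 IRanges::IRanges(pos, width = 1L))
    p <- rep(config@p_background, length(gr))
    gb <- genes_gr[gbm[gbm %in% gene_df$gene_id[gene_df$chrom == chrom]]]
    p[IRanges::overlapsAny(gr, gb, ignore.strand = TRUE)] <- config@p_gbm_site
    if (length(pmg)) {
      pm <- .promoterRanges(genes, config@promoter_bp)
      pm <- pm[names(pm) %in% pmg &
                 as.character(GenomeInfoDb::seqnames(pm)) == chrom]
      p[IRanges::overlapsAny(gr, pm, ignore.strand = TRUE)] <-
        config@p_pmg_site
    }
    c0 <- config@jitter_concentration
    pj <- withSeed(mixSeed(config@seed, "jitter", chrom), {
      out <- stats::rbeta(length(p), c0 * p, c0 * (1 - p))
      out[p == 0] <- 0  # Beta degenerates at the endpoints
      out[p == 1] <- 1
      out
    })
    gr$true_p <- pj
    gr
  })
  site_probs <- do.call(c, site_list)

  islands_gr <- if (length(island_rows)) {
    idf <- do.call(rbind, island_rows)
    GenomicRanges::GRanges(idf$chrom, IRanges::IRanges(idf$start, idf$end))
  } else {
    GenomicRanges::GRanges()
  }

  truth <- new("GroundTruth", gbm_genes = gbm, pmg_genes = pmg,
               islands = islands_gr, site_probs = site_probs,
               expr_slope = config@expr_slope,
               expr_intercept = config@expr_intercept,
               expr_noise_sd = config@expr_noise_sd,
               planted_r = NA_real_)
  list(genes = genes, repeats = repeats, truth = truth,
       chrom_sizes = chrom_sizes)
}

#' Generate read- and site-level methylation calls from planted truth
#'
#' Per CpG site: coverage ~ Poisson(`coverage_mean`); each read's true
#' methylation state ~ Bernoulli(true per-site probability); read LLR ~
#' `Normal(+llr_mu, llr_sigma)` if methylated else
#' `Normal(-llr_mu, llr_sigma)`. The returned site table is the exact
#' aggregation of the read-level truth (so in the noiseless-LLR limit,
#' re-aggregating the read table reproduces it exactly). Sites drawing
#' coverage 0 are absent from the site table.
#'
#' @param truth A [GroundTruth-class].
#' @param config The [SimulationConfig-class] used to generate it.
#' @param replicate Integer tag seeding an independent replicate (e.g. a
#'   second technology measuring the same truth).
#' @param read_level Also generate the per-read table (default TRUE).
#' @return List: `sites` ([SiteCalls-class], strand `*`), `reads`
#'   (data.frame `chrom`, `pos`, `strand`, `read_id`, `llr`, or NULL).
#' @export
simulateSiteCalls <- function(truth, config, replicate = 1,
                              read_level = TRUE) {
  if (config@coverage_mean <= 0) stop("coverage_mean must be positive")
  gr <- truth@site_probs
  n <- length(gr)
  withSeed(mixSeed(config@seed, "sites", replicate), {
    cov <- stats::rpois(n, config@coverage_mean)
    k <- stats::rbinom(n, cov, gr$true_p)
    reads <- NULL
    if (read_level) {
      tot <- sum(cov)
      site_of <- rep.int(seq_len(n), cov)
      # the first k reads of each site are the methylated ones
      within <- sequence(cov)
      meth <- as.integer(within <= rep.int(k, cov))
      llr <- stats::rnorm(tot, ifelse(meth == 1L, config@llr_mu,
                                      -config@llr_mu), config@llr_sigma)
      reads <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(gr))[site_of],
        pos = GenomicRanges::start(gr)[site_of],
        strand = "+",
        read_id = paste0("read_", site_of, "_", within),
        llr = llr,
        stringsAsFactors = FALSE
      )
    }
  })
  keep <- cov > 0
  sites <- SiteCalls(
    chrom = as.character(GenomeInfoDb::seqnames(gr))[keep],
    pos = GenomicRanges::start(gr)[keep],
    strand = "*",
    called_reads = cov[keep],
    methylated_reads = k[keep]
  )
  list(sites = sites, reads = reads)
}

#' Split a motif-level site table into complementary strand counts
#'
#' The inverse of [mergeComplementaryCpg()] up to the random split:
#' each site's reads are divided binomially between the plus-strand C
#' (same position) and the minus-strand C (position + 1), with the
#' methylated reads apportioned hypergeometrically. Useful for emulating
#' per-cytosine bisulfite reports.
#'
#' @param sites Motif-level [SiteCalls-class] (strand `*`).
#' @param seed Integer seed.
#' @return Strand-resolved [SiteCalls-class] with two rows per site.
#' @export
splitStrandCounts <- function(sites, seed = 1) {
  n <- length(sites)
  cr <- calledReads(sites); mr <- methylatedReads(sites)
  withSeed(mixSeed(seed, "strand-split"), {
    cr_p <- stats::rbinom(n, cr, 0.5)
    mr_p <- stats::rhyper(n, mr, cr - mr, cr_p)
  })
  chr <- as.character(GenomeInfoDb::seqnames(sites))
  pos <- GenomicRanges::start(sites)
  SiteCalls(
    chrom = c(chr, chr),
    pos = c(pos, pos + 1L),
    strand = rep(c("+", "-"), each = n),
    called_reads = c(cr_p, cr - cr_p),
    methylated_reads = c(mr_p, mr - mr_p)
  )
}

#' Generate expression counts tied to gene-body methylation
#'
#' Per gene, `log(1 + FPKM_true) = intercept + slope * m + Normal(0, sd)`
#' where `m` is the gene's weighted body methylation computed from the
#' generated site table. Per sample, the library size is drawn around
#' `library_size_mean` and counts are drawn
#' `Poisson(FPKM_true * total * length_bp / 1e9)` — the FPKM formula run
#' backwards. The implied planted correlation
#' `slope * sd(m) / sqrt(slope^2 var(m) + sd_noise^2)` is recorded in the
#' returned `truth`.
#'
#' @param genes A [GeneSet-class].
#' @param sites The generated [SiteCalls-class] table.
#' @param truth The [GroundTruth-class] (updated and returned).
#' @param config A [SimulationConfig-class].
#' @return List: `counts` (genes x samples integer matrix),
#'   `gene_lengths` (named, bp), `fpkm_true` (named), `methylation`
#'   (named, the m used), `truth` (with `planted_r` filled in).
#' @export
simulateExpression <- function(genes, sites, truth, config) {
  if (config@n_expression_samples < 2L) {
    stop("need at least 2 expression samples")
  }
  g <- geneRanges(genes)
  st <- .perRangeSiteStats(sites, g, rep(FALSE, length(sites)))
  m <- ifelse(st$called_reads > 0,
              st$methylated_reads / st$called_reads, 0)
  names(m) <- names(g)
  withSeed(mixSeed(config@seed, "expression"), {
    loge <- config@expr_intercept + config@expr_slope * m +
      stats::rnorm(length(m), 0, config@expr_noise_sd)
    fpkm_true <- pmax(0, expm1(loge))
    totals <- round(stats::runif(config@n_expression_samples, 0.8, 1.2) *
                      config@library_size_mean)
    lens <- GenomicRanges::width(g)
    lam <- outer(fpkm_true * lens / 1e9, totals)
    counts <- matrix(stats::rpois(length(lam), lam), nrow = length(m),
                     dimnames = list(names(m),
                                     paste0("s", seq_along(totals))))
  })
  sig <- config@expr_slope * stats::sd(m)
  truth@planted_r <- sig / sqrt(sig^2 + config@expr_noise_sd^2)
  list(counts = counts, gene_lengths = stats::setNames(
         as.numeric(GenomicRanges::width(g)), names(g)),
       fpkm_true = fpkm_true, methylation = m, truth = truth)
}

#' One-call synthetic methylome
#'
#' Runs [simulateAnnotation()], [simulateSiteCalls()] and
#' [simulateExpression()] under one config.
#'
#' @param config A [SimulationConfig-class].
#' @param read_level Generate the per-read table too (default FALSE).
#' @return List: `genes`, `repeats`, `truth`, `chrom_sizes`, `sites`,
#'   `reads`, `counts`, `gene_lengths`, `fpkm_true`, `methylation`.
#' @export
simulateMethylome <- function(config = simulationConfig(),
                              read_level = FALSE) {
  ann <- simulateAnnotation(config)
  sc <- simulateSiteCalls(ann$truth, config, read_level = read_level)
  ex <- simulateExpression(ann$genes, sc$sites, ann$truth, config)
  list(genes = ann$genes, repeats = ann$repeats, truth = ex$truth,
       chrom_sizes = ann$chrom_sizes, sites = sc$sites, reads = sc$reads,
       counts = ex$counts, gene_lengths = ex$gene_lengths,
       fpkm_true = ex$fpkm_true, methylation = ex$methylation)
}

#' Write read-level calls in the nanopolish methylation-calls dialect
#'
#' @param reads data.frame from [simulateSiteCalls()].
#' @param path Output TSV.
#' @export
writeNanopolishCalls <- function(reads, path) {
  df <- data.frame(
    chromosome = reads$chrom,
    strand = reads$strand,
    start = reads$pos - 1L,  # dialect is 0-based
    end = reads$pos - 1L,
    read_name = reads$read_id,
    log_lik_ratio = reads$llr,
    log_lik_methylated = pmax(reads$llr, 0),
    log_lik_unmethylated = pmax(-reads$llr, 0),
    num_calling_strands = 1L,
    num_motifs = 1L,
    sequence = "AAAAACGAAAAA"
  )
  writeTsv(df, path)
}

#' Write a site table in the Bismark coverage dialect
#'
#' Six standard columns plus the optional strand column (see
#' [readBismarkCoverage()]).
#'
#' @param sites A [SiteCalls-class] table.
#' @param path Output TSV (headerless, per the dialect).
#' @export
writeBismarkCoverage <- function(sites, path) {
  cr <- calledReads(sites); mr <- methylatedReads(sites)
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(sites)),
    start = GenomicRanges::start(sites),
    end = GenomicRanges::start(sites),
    pct = ifelse(cr > 0, 100 * mr / cr, 0),
    n_meth = mr,
    n_unmeth = cr - mr,
    strand = as.character(GenomicRanges::strand(sites))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the ground-truth manifest as JSON
#'
#' @param truth A [GroundTruth-class].
#' @param path Output JSON file.
#' @export
writeGroundTruth <- function(truth, path) {
  isl <- truth@islands
  jsonlite::write_json(list(
    gbm_genes = truth@gbm_genes,
    pmg_genes = truth@pmg_genes,
    islands = data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(isl)),
      start = GenomicRanges::start(isl),
      end = GenomicRanges::end(isl)),
    expr_slope = truth@expr_slope,
    expr_intercept = truth@expr_intercept,
    expr_noise_sd = truth@expr_noise_sd,
    planted_r = truth@planted_r
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
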