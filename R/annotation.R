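#' Read gene models from GFF3
#'
#' Imports `gene`/`mRNA`/`exon` features (ID/Parent attributes) and builds
#' one gene model per gene. Genes with several transcripts are collapsed to
#' the longest transcript; exon ranks are assigned 5'-to-3' on the gene's
#' strand. GFF3 1-based closed coordinates are kept as-is (the package's
#' internal convention).
#'
#' @param path GFF3 file.
#' @return A [GeneSet-class].
#' @export
readGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  mrnas <- gr[type == "mRNA"]
  exons <- gr[type == "exon"]
  if (!length(genes)) stop("no gene features in ", path)
  names(genes) <- genes$ID
  parent1 <- function(x) {
    vapply(as.list(x$Parent), function(p) {
      if (length(p)) as.character(p[1]) else NA_character_
    }, "")
  }
  if (length(mrnas)) {
    mrna_gene <- parent1(mrnas)
    exon_mrna <- parent1(exons)
    bad <- is.na(exon_mrna) | !(exon_mrna %in% mrnas$ID)
    if (any(bad)) {
      stop("exon(s) without resolvable gene parent: ",
           paste(utils::head(exons$ID[bad], 5), collapse = ", "))
    }
    # longest transcript per gene
    ord <- order(mrna_gene, -GenomicRanges::width(mrnas))
    pick <- mrnas$ID[ord][!duplicated(mrna_gene[ord])]
    gene_of <- mrna_gene[match(pick, mrnas$ID)]
    keep <- exon_mrna %in% pick
    exons <- exons[keep]
    exon_gene <- gene_of[match(exon_mrna[keep], pick)]
  } else {
    exon_gene <- parent1(exons)
    bad <- is.na(exon_gene) | !(exon_gene %in% names(genes))
    if (any(bad)) stop("exon(s) without resolvable gene parent")
  }
  exl <- GenomicRanges::split(GenomicRanges::granges(exons),
                              factor(exon_gene, levels = names(genes)))
  exl <- .orientExons(exl, genes)
  gg <- GenomicRanges::granges(genes)
  names(gg) <- names(genes)
  GeneSet(gg, exl)
}

# order each gene's exons 5'->3' on the gene's strand
.orientExons <- function(exl, genes) {
  minus <- as.character(GenomicRanges::strand(genes))[
    match(names(exl), names(genes))] == "-"
  ord <- lapply(seq_along(exl), function(i) {
    e <- exl[[i]]
    o <- order(GenomicRanges::start(e), decreasing = minus[i])
    e[o]
  })
  out <- GenomicRanges::GRangesList(ord)
  names(out) <- names(exl)
  out
}

#' Write a GeneSet as GFF3
#'
#' Emits gene, mRNA (one per gene) and exon features with ID/Parent
#' attributes; [readGff3()] on the output reconstructs the same models.
#'
#' @param genes A [GeneSet-class].
#' @param path Output file.
#' @export
writeGff3 <- function(genes, path) {
  g <- geneRanges(genes)
  ex <- geneExons(genes)
  gid <- names(g)
  tid <- paste0(gid, ".t1")
  gg <- GenomicRanges::granges(g)
  gg$type <- "gene"; gg$ID <- gid; gg$Parent <- IRanges::CharacterList(
    vector("list", length(gg)))
  tt <- GenomicRanges::granges(g)
  tt$type <- "mRNA"; tt$ID <- tid
  tt$Parent <- IRanges::CharacterList(as.list(gid))
  exu <- unlist(ex, use.names = FALSE)
  nex <- S4Vectors::elementNROWS(ex)
  ee <- GenomicRanges::granges(exu)
  ee$type <- "exon"
  ee$ID <- paste0(rep(tid, nex), ".e", unlist(lapply(nex, seq_len)))
  ee$Parent <- IRanges::CharacterList(as.list(rep(tid, nex)))
  all <- c(gg, tt, ee)
  all$source <- "methylomer"
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read / write repeat annotations as BED
#'
#' BED6 (name column = TE class) for repeats; BED intervals are 0-based
#' half-open on disk and converted to 1-based closed in memory.
#'
#' @param path BED file.
#' @return A [RepeatSet-class].
#' @export
readRepeatBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  cls <- if (!is.null(gr$name)) gr$name else "TE"
  RepeatSet(GenomicRanges::granges(gr), te_class = cls)
}

#' @rdname readRepeatBed
#' @param repeats A [RepeatSet-class].
#' @export
writeRepeatBed <- function(repeats, path) {
  gr <- GenomicRanges::granges(repeats)
  gr$name <- S4Vectors::mcols(repeats)$te_class
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# promoter windows: [tss - promoter_bp, tss) strand-adjusted, clipped at 1
.promoterRanges <- function(genes, promoter_bp) {
  g <- geneRanges(genes)
  p <- GenomicRanges::promoters(g, upstream = promoter_bp, downstream = 0)
  GenomicRanges::trim(p)
}

# per-gene intron ranges with 5'->3' ranks
.intronRanges <- function(genes) {
  ex <- geneExons(genes)
  g <- geneRanges(genes)
  introns <- GenomicRanges::psetdiff(GenomicRanges::granges(g), ex)
  .orientExons(introns, g)
}

#' Assign each CpG site a genomic region label
#'
#' Labels each site one of `exon`, `intron`, `promoter`, `TE`, `intergenic`
#' with fixed precedence exon > intron > promoter > TE > intergenic, so the
#' genic methylation signal is never masked by an overlapping repeat.
#' Exonic sites also receive the 5'-to-3' exon rank (smallest rank if a
#' site touches several genes).
#'
#' @param sites A [SiteCalls-class] table.
#' @param genes A [GeneSet-class].
#' @param repeats A [RepeatSet-class].
#' @param promoter_bp Promoter width upstream of the TSS (default 200).
#' @return data.frame with columns `label` (factor) and `exon_rank`
#'   (integer, `NA` unless label is `exon`), one row per site.
#' @export
assignRegion <- function(sites, genes, repeats, promoter_bp = 200) {
  n <- length(sites)
  lab <- rep("intergenic", n)
  rank_out <- rep(NA_integer_, n)
  s <- GenomicRanges::granges(sites)
  GenomicRanges::strand(s) <- "*"

  te <- GenomicRanges::reduce(GenomicRanges::granges(repeats),
                              ignore.strand = TRUE)
  lab[IRanges::overlapsAny(s, te, ignore.strand = TRUE)] <- "TE"

  prom <- .promoterRanges(genes, promoter_bp)
  lab[IRanges::overlapsAny(s, prom, ignore.strand = TRUE)] <- "promoter"

  introns <- unlist(.intronRanges(genes), use.names = FALSE)
  lab[IRanges::overlapsAny(s, introns, ignore.strand = TRUE)] <- "intron"

  ex <- geneExons(genes)
  exu <- unlist(ex, use.names = FALSE)
  exrank <- unlist(lapply(S4Vectors::elementNROWS(ex), seq_len))
  hits <- GenomicRanges::findOverlaps(s, exu, ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    rk <- exrank[S4Vectors::subjectHits(hits)]
    best <- tapply(rk, qh, min)
    idx <- as.integer(names(best))
    lab[idx] <- "exon"
    rank_out[idx] <- as.integer(best)
  }
  data.frame(
    label = factor(lab, levels = c("exon", "intron", "promoter", "TE",
                                   "intergenic")),
    exon_rank = rank_out
  )
}

#' Region-level methylation summary
#'
#' Mean site frequency and coverage-weighted methylation
#' (sum of methylated reads / sum of called reads) per region label.
#' Labels with no sites are flagged (`n_sites = 0`, `NA` means).
#'
#' @inheritParams assignRegion
#' @return data.frame: `label`, `n_sites`, `mean_frequency`,
#'   `weighted_methylation`.
#' @export
regionMethylationSummary <- function(sites, genes, repeats,
                                     promoter_bp = 200) {
  reg <- assignRegion(sites, genes, repeats, promoter_bp)
  fr <- methFrequency(sites)
  mr <- methylatedReads(sites)
  cr <- calledReads(sites)
  out <- do.call(rbind, lapply(levels(reg$label), function(lv) {
    i <- which(reg$label == lv)
    data.frame(
      label = lv,
      n_sites = length(i),
      mean_frequency = if (length(i)) mean(fr[i]) else NA_real_,
      weighted_methylation = if (length(i) && sum(cr[i]) > 0) {
        sum(mr[i]) / sum(cr[i])
      } else NA_real_
    )
  }))
  out
}

#' Methylation by exon / intron rank
#'
#' Mean and SD of site frequencies per exon rank and per intron rank
#' (5'-to-3'); ranks above `max_rank` are pooled into the `max_rank`-plus
#' bucket.
#'
#' @param sites A [SiteCalls-class] table.
#' @param genes A [GeneSet-class].
#' @param max_rank Highest unpooled rank.
#' @return data.frame: `feature` (exon/intron), `rank`, `pooled`,
#'   `n_sites`, `mean_frequency`, `sd_frequency`.
#' @export
exonRankProfile <- function(sites, genes, max_rank = 6) {
  s <- GenomicRanges::granges(sites)
  GenomicRanges::strand(s) <- "*"
  fr <- methFrequency(sites)
  oneFeature <- function(frl, featname) {
    u <- unlist(frl, use.names = FALSE)
    rk <- unlist(lapply(S4Vectors::elementNROWS(frl), seq_len))
    hits <- GenomicRanges::findOverlaps(s, u, ignore.strand = TRUE)
    rks <- pmin(rk[S4Vectors::subjectHits(hits)], max_rank)
    f <- fr[S4Vectors::queryHits(hits)]
    do.call(rbind, lapply(seq_len(max_rank), function(r) {
      v <- f[rks == r]
      data.frame(feature = featname, rank = r, pooled = r == max_rank,
                 n_sites = length(v),
                 mean_frequency = if (length(v)) mean(v) else NA_real_,
                 sd_frequency = if (length(v) > 1) stats::sd(v) else NA_real_)
    }))
  }
  rbind(oneFeature(geneExons(genes), "exon"),
        oneFeature(.intronRanges(genes), "intron"))
}

#' Classify each TE copy by genomic context
#'
#' Assigns every repeat copy one of `intronic`, `upstream2kb` (within
#' `upstream_bp` of a TSS) or `intergenic` by majority overlap fraction,
#' ties broken toward the gene-proximal class (intronic first). If a site
#' table is supplied, coverage-weighted methylation of the sites inside the
#' TEs of each context (and of each TE class) is reported too.
#'
#' @param repeats A [RepeatSet-class].
#' @param genes A [GeneSet-class].
#' @param sites Optional [SiteCalls-class] table.
#' @param upstream_bp Width of the gene-proximal upstream window.
#' @return List with `te_context` (per-copy data.frame) and, when `sites`
#'   is given, `context_methylation` and `class_methylation` summaries.
#' @export
teContextClassify <- function(repeats, genes, sites = NULL,
                              upstream_bp = 2000) {
  te <- GenomicRanges::granges(repeats)
  introns <- GenomicRanges::reduce(
    unlist(.intronRanges(genes), use.names = FALSE), ignore.strand = TRUE)
  up <- GenomicRanges::reduce(GenomicRanges::trim(
    GenomicRanges::promoters(geneRanges(genes), upstream = upstream_bp,
                             downstream = 0)), ignore.strand = TRUE)
  ovFrac <- function(q, subj) {
    frac <- numeric(length(q))
    hits <- GenomicRanges::findOverlaps(q, subj, ignore.strand = TRUE)
    if (length(hits)) {
      w <- GenomicRanges::width(IRanges::pintersect(
        q[S4Vectors::queryHits(hits)], subj[S4Vectors::subjectHits(hits)]))
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      frac[as.integer(names(agg))] <- as.numeric(agg)
    }
    frac / GenomicRanges::width(q)
  }
  fi <- ovFrac(te, introns)
  fu <- ovFrac(te, up)
  ctx <- ifelse(fi == 0 & fu == 0, "intergenic",
                ifelse(fi >= fu, "intronic", "upstream2kb"))
  per_te <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(te)),
    start = GenomicRanges::start(te), end = GenomicRanges::end(te),
    te_class = S4Vectors::mcols(repeats)$te_class,
    context = ctx, frac_intronic = fi, frac_upstream = fu
  )
  out <- list(te_context = per_te)
  if (!is.null(sites)) {
    hits <- GenomicRanges::findOverlaps(GenomicRanges::granges(sites), te,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    wm <- function(group) {
      do.call(rbind, lapply(sort(unique(group)), function(gv) {
        i <- unique(qh[group == gv])
        data.frame(group = gv, n_sites = length(i),
                   weighted_methylation = if (length(i)) {
                     sum(methylatedReads(sites)[i]) /
                       sum(calledReads(sites)[i])
                   } else NA_real_)
      }))
    }
    out$context_methylation <- wm(ctx[sh])
    out$class_methylation <- wm(per_te$te_class[sh])
  }
  out
}

#' Tile a genome into fixed windows
#'
#' Contiguous, ordered windows of `width` bp per chromosome; the last
#' window of each chromosome is truncated at the chromosome end.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param width Window width in bp (default 50 kb, the TE-island scale).
#' @return `GRanges` of windows.
#' @export
makeWindows <- function(chrom_sizes, width = 50000) {
  stopifnot(width > 0, all(chrom_sizes > 0))
  sl <- vapply(chrom_sizes, as.integer, 1L)
  GenomicRanges::tileGenome(sl, tilewidth = as.integer(width),
                            cut.last.tile.in.chrom = TRUE)
}

#' Fraction of each window covered by a set of intervals
#'
#' Input intervals are flattened (reduced) first, so the result is
#' invariant to splitting an interval into abutting pieces.
#'
#' @param windows `GRanges` of windows.
#' @param intervals `GRanges` (or [RepeatSet-class]) of intervals.
#' @return Numeric vector in `[0, 1]`, parallel to `windows`.
#' @export
intervalCoverageFraction <- function(windows, intervals) {
  iv <- GenomicRanges::reduce(GenomicRanges::granges(intervals),
                              ignore.strand = TRUE)
  cov <- numeric(length(windows))
  hits <- GenomicRanges::findOverlaps(windows, iv, ignore.strand = TRUE)
  if (length(hits)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      windows[S4Vectors::queryHits(hits)], iv[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    cov[as.integer(names(agg))] <- as.numeric(agg)
  }
  cov / GenomicRanges::width(windows)
}

#' Subtract one interval set from another
#'
#' Returns the parts of `a` not overlapped by `b` (clipped remainders),
#' strand-blind. Base-pair conservation holds:
#' `subtract(a, b)` plus `intersect(a, b)` covers exactly `reduce(a)`.
#'
#' @param a,b `GRanges` interval sets.
#' @return `GRanges`.
#' @export
intervalSubtract <- function(a, b) {
  a <- GenomicRanges::granges(a); b <- GenomicRanges::granges(b)
  GenomicRanges::strand(a) <- "*"; GenomicRanges::strand(b) <- "*"
  GenomicRanges::setdiff(a, b, ignore.strand = TRUE)
}

#' Read / write chromosome sizes
#'
#' Two-column TSV: chromosome name, length in bp.
#' @param path TSV file.
#' @return Named integer vector.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- as.integer(df[[2]])
  names(out) <- df[[1]]
  out
}
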