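#' Join two site tables on genomic position
#'
#' Exact (chrom, pos) matching of two site tables (e.g. nanopore vs
#' bisulfite), both expected in the same strand-merge convention; an
#' optional +/-1 bp tolerance covers dialect off-by-one between C and
#' CpG-start anchoring. Sites present in only one table are returned as
#' unique-site tables.
#'
#' @param a,b [SiteCalls-class] tables.
#' @param tolerance 0 (exact, default) or 1 bp.
#' @return List: `shared` (data.frame with `chrom`, `pos`, `freq_a`,
#'   `freq_b`, `called_a`, `called_b`), `unique_a`, `unique_b`
#'   ([SiteCalls-class]).
#' @export
joinSites <- function(a, b, tolerance = 0) {
  sa <- sort(unique(as.character(GenomicRanges::strand(a))))
  sb <- sort(unique(as.character(GenomicRanges::strand(b))))
  if (length(sa) && length(sb) && !identical(sa, sb)) {
    stop("strand conventions disagree between the two tables (",
         paste(sa, collapse = ""), " vs ", paste(sb, collapse = ""),
         "); merge both to the same convention first")
  }
  ga <- GenomicRanges::granges(a); gb <- GenomicRanges::granges(b)
  GenomicRanges::strand(ga) <- "*"; GenomicRanges::strand(gb) <- "*"
  hits <- GenomicRanges::findOverlaps(ga, gb, maxgap = tolerance,
                                      ignore.strand = TRUE)
  # one partner per site: keep the first hit per query and per subject
  hits <- hits[!duplicated(S4Vectors::queryHits(hits))]
  hits <- hits[!duplicated(S4Vectors::subjectHits(hits))]
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  shared <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(a))[qh],
    pos = GenomicRanges::start(a)[qh],
    freq_a = methFrequency(a)[qh],
    freq_b = methFrequency(b)[sh],
    called_a = calledReads(a)[qh],
    called_b = calledReads(b)[sh]
  )
  list(shared = shared,
       unique_a = a[setdiff(seq_along(a), qh)],
       unique_b = b[setdiff(seq_along(b), sh)])
}

#' Cross-technology concordance report
#'
#' Joins two site tables and quantifies agreement: shared/unique site
#' counts, per-site Pearson correlation of methylation frequencies with
#' its t-based p-value, and optionally the correlation of window-mean
#' frequencies at one or more window sizes (window means damp the
#' per-site binomial sampling noise, so windowed r is typically higher).
#' P-values are reported, never thresholded, by this module.
#'
#' @param a,b [SiteCalls-class] tables.
#' @param window_sizes Optional numeric vector of window widths (bp).
#' @param chrom_sizes Required when `window_sizes` is given.
#' @param tolerance Join tolerance in bp (see [joinSites()]).
#' @return List: `n_shared`, `n_unique_a`, `n_unique_b`, `pearson_r`,
#'   `r_p_value`, `windowed` (data.frame window_bp/r/n, if requested),
#'   `join` (the [joinSites()] result).
#' @export
concordanceReport <- function(a, b, window_sizes = NULL,
                              chrom_sizes = NULL, tolerance = 0) {
  jn <- joinSites(a, b, tolerance)
  ct <- pearsonCorTest(jn$shared$freq_a, jn$shared$freq_b)
  out <- list(
    n_shared = nrow(jn$shared),
    n_unique_a = length(jn$unique_a),
    n_unique_b = length(jn$unique_b),
    pearson_r = ct$r,
    r_p_value = ct$p_value,
    join = jn
  )
  if (!is.null(window_sizes)) {
    stopifnot(!is.null(chrom_sizes))
    out$windowed <- do.call(rbind, lapply(window_sizes, function(wbp) {
      win <- makeWindows(chrom_sizes, wbp)
      gr <- GenomicRanges::GRanges(jn$shared$chrom,
                                   IRanges::IRanges(jn$shared$pos, width = 1))
      idx <- GenomicRanges::findOverlaps(gr, win, select = "first")
      ok <- !is.na(idx)
      ma <- tapply(jn$shared$freq_a[ok], idx[ok], mean)
      mb <- tapply(jn$shared$freq_b[ok], idx[ok], mean)
      keep <- !is.na(ma) & !is.na(mb)
      r <- if (sum(keep) >= 3 && stats::sd(ma[keep]) > 0 &&
               stats::sd(mb[keep]) > 0) {
        stats::cor(ma[keep], mb[keep])
      } else NA_real_
      data.frame(window_bp = wbp, r = r, n_windows = sum(keep))
    }))
  }
  out
}
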