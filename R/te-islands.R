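#' Exact penalized changepoint segmentation (piecewise-constant mean)
#'
#' Optimal-partitioning dynamic programming for the L2 (Gaussian mean)
#' cost: finds the segmentation minimizing
#' `sum over segments of SSE(segment) + penalty * k`, where `k` is the
#' number of changepoints. The O(n^2) recursion is exact — no heuristic
#' pruning — and ties are broken toward fewer changepoints, so a constant
#' signal yields no changepoints at any positive penalty.
#'
#' @param y Numeric signal, one value per window (e.g. TE coverage
#'   fraction per 50 kb window).
#' @param penalty Penalty per changepoint (default 40, the conventional
#'   mean-model penalty at the 50 kb TE-island scale).
#' @return A [Segmentation-class].
#' @examples
#' segmentChangepoints(c(rep(0.1, 20), rep(0.6, 20)), penalty = 0.5)
#' @export
segmentChangepoints <- function(y, penalty = 40) {
  n <- length(y)
  if (n == 0L) stop("empty signal")
  stopifnot(penalty >= 0, all(is.finite(y)))
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  sse <- function(i, j) {  # segment y[i..j], 1-based inclusive
    s <- cs[j + 1] - cs[i]
    cs2[j + 1] - cs2[i] - s * s / (j - i + 1)
  }
  # F[t+1] = best cost of y[1..t] counting penalty per segment, seeded with
  # -penalty so the first segment is free: F[n+1] = total SSE + penalty * k
  F <- c(-penalty, rep(Inf, n))
  nseg <- c(0L, rep(NA_integer_, n))
  back <- rep(NA_integer_, n)
  tol <- 1e-10
  for (t in seq_len(n)) {
    best <- Inf; bestns <- NA_integer_; bests <- NA_integer_
    for (s in 0:(t - 1)) {
      cand <- F[s + 1] + sse(s + 1, t) + penalty
      ns <- nseg[s + 1] + 1L
      if (cand < best - tol ||
          (cand < best + tol && (is.na(bestns) || ns < bestns))) {
        best <- cand; bestns <- ns; bests <- s
      }
    }
    F[t + 1] <- best; nseg[t + 1] <- bestns; back[t] <- bests
  }
  tau <- integer(0)
  t <- n
  while (t > 0L) {
    s <- back[t]
    if (s > 0L) tau <- c(s, tau)
    t <- s
  }
  starts <- c(1L, tau + 1L)
  ends <- c(tau, n)
  means <- (cs[ends + 1] - cs[starts]) / (ends - starts + 1)
  new("Segmentation", n = n, changepoints = as.integer(tau),
      means = as.numeric(means), cost = F[n + 1], penalty = penalty)
}

#' Call TE islands from a segmentation
#'
#' A segment is island-labelled when its mean TE fraction is at least
#' `drop_cutoff` above the baseline. The default baseline is the
#' length-weighted median of the segment means (the median of the fitted
#' per-window values), i.e. the chromosome's background TE level — an
#' unweighted median over segments would drift upward whenever islands
#' make up half the segments while covering a small fraction of the
#' windows. Adjacent island segments are merged and window indices
#' converted to bp using the window ranges.
#'
#' @param seg A [Segmentation-class] for one chromosome.
#' @param windows `GRanges` of the windows the signal was computed on
#'   (same chromosome, same order, length `seg@n`).
#' @param drop_cutoff Minimum elevation of a segment mean above baseline
#'   (default 0.2).
#' @param baseline `"median"` (weighted median of segment means) or a
#'   numeric value.
#' @return A [TEIslandSet-class].
#' @export
callTEIslands <- function(seg, windows, drop_cutoff = 0.2,
                          baseline = "median") {
  stopifnot(length(windows) == seg@n)
  st <- segmentTable(seg)
  base <- if (identical(baseline, "median")) {
    stats::median(rep(st$mean, st$end - st$start + 1L))
  } else {
    as.numeric(baseline)
  }
  st$island <- st$mean >= base + drop_cutoff
  # merge runs of adjacent island segments
  iv <- list()
  i <- 1L
  while (i <= nrow(st)) {
    if (st$island[i]) {
      j <- i
      while (j < nrow(st) && st$island[j + 1L]) j <- j + 1L
      w <- sum((st$end[i:j] - st$start[i:j] + 1L) * st$mean[i:j])
      iv[[length(iv) + 1L]] <- c(st$start[i], st$end[j],
                                 w / (st$end[j] - st$start[i] + 1L))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(iv)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$mean_te_fraction <- numeric(0)
    return(new("TEIslandSet", gr))
  }
  m <- do.call(rbind, iv)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(GenomeInfoDb::seqnames(windows))[1],
    ranges = IRanges::IRanges(
      start = GenomicRanges::start(windows)[m[, 1]],
      end = GenomicRanges::end(windows)[m[, 2]]),
    mean_te_fraction = m[, 3]
  )
  new("TEIslandSet", gr)
}

#' Noise variance of a piecewise-constant signal
#'
#' Difference-based estimator robust to level shifts: the lower quartile
#' of the squared first differences, rescaled by the corresponding
#' chi-square(1) quantile so it is unbiased for Gaussian noise. Using the
#' lower quartile (rather than the median) keeps the estimate stable even
#' when level shifts and their ramp windows contaminate a quarter of the
#' differences, which a handful of islands on a short chromosome easily
#' does.
#'
#' @param y Numeric signal.
#' @return Estimated noise variance (0 for signals of length < 2 or
#'   constant signals).
#' @export
estimateNoiseVariance <- function(y) {
  if (length(y) < 2L) return(0)
  unname(stats::quantile(diff(y)^2, 0.25)) /
    (2 * stats::qchisq(0.25, 1))
}

#' Segment TE content and call islands genome-wide
#'
#' Convenience wrapper: computes the per-window TE coverage fraction,
#' segments each chromosome independently with
#' [segmentChangepoints()] and calls islands with [callTEIslands()]
#' (per-chromosome median baseline). The penalty follows the likelihood
#' convention of mean-model changepoint fitting: it applies to the
#' variance-standardized cost `SSE / sigma^2`, with the noise variance
#' estimated per chromosome by [estimateNoiseVariance()] — so the
#' default of 40 is meaningful regardless of the signal's absolute
#' scale. Pass `normalize_variance = FALSE` to apply the penalty to the
#' raw SSE instead.
#'
#' @param repeats A [RepeatSet-class] (or `GRanges`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window_bp Window width (default 50 kb).
#' @param penalty Changepoint penalty on the standardized scale
#'   (default 40).
#' @param drop_cutoff Island elevation cutoff (default 0.2).
#' @param baseline `"median"` or numeric (passed per chromosome).
#' @param normalize_variance Standardize the cost by the estimated noise
#'   variance (default TRUE).
#' @return List: `islands` ([TEIslandSet-class], all chromosomes),
#'   `windows` (`GRanges` with `te_fraction` score),
#'   `segmentations` (named list per chromosome).
#' @export
findTEIslands <- function(repeats, chrom_sizes, window_bp = 50000,
                          penalty = 40, drop_cutoff = 0.2,
                          baseline = "median", normalize_variance = TRUE) {
  win <- makeWindows(chrom_sizes, window_bp)
  win$te_fraction <- intervalCoverageFraction(win, repeats)
  segs <- list()
  isl <- list()
  for (chrom in names(chrom_sizes)) {
    wc <- win[as.character(GenomeInfoDb::seqnames(win)) == chrom]
    if (!length(wc)) next
    pen <- if (normalize_variance) {
      penalty * max(estimateNoiseVariance(wc$te_fraction), 1e-12)
    } else penalty
    seg <- segmentChangepoints(wc$te_fraction, pen)
    segs[[chrom]] <- seg
    isl[[chrom]] <- callTEIslands(seg, wc, drop_cutoff, baseline)
  }
  islands <- if (length(isl)) {
    new("TEIslandSet", do.call(c, lapply(unname(isl), function(x) {
      gr <- GenomicRanges::granges(x)
      gr$mean_te_fraction <- x$mean_te_fraction
      GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
      gr
    })))
  } else {
    callTEIslands(segmentChangepoints(0, 1), makeWindows(c(chr = 1), 1))
  }
  list(islands = islands, windows = win, segmentations = segs)
}

#' Compare methylation inside vs outside TE islands
#'
#' Two-sided Wilcoxon rank-sum test (tie-corrected normal approximation;
#' exact for tiny samples) of per-site methylation frequencies inside the
#' islands versus the rest of the genome.
#'
#' @param sites A [SiteCalls-class] table.
#' @param islands A [TEIslandSet-class].
#' @return List: `statistic` (W), `p_value`, `median_inside`,
#'   `median_outside`, `n_inside`, `n_outside`.
#' @export
compareIslandMethylation <- function(sites, islands) {
  if (!length(islands)) stop("island set is empty")
  inside <- IRanges::overlapsAny(GenomicRanges::granges(sites),
                                 GenomicRanges::granges(islands),
                                 ignore.strand = TRUE)
  fin <- methFrequency(sites)[inside]
  fout <- methFrequency(sites)[!inside]
  if (!length(fin) || !length(fout)) {
    stop("one of the groups (inside/outside islands) is empty")
  }
  w <- wilcoxonRankSum(fin, fout)
  list(statistic = w$statistic, p_value = w$p_value,
       median_inside = stats::median(fin),
       median_outside = stats::median(fout),
       n_inside = length(fin), n_outside = length(fout))
}

#' Write TE islands as BED (score = mean TE fraction)
#'
#' @param islands A [TEIslandSet-class].
#' @param path Output BED file.
#' @export
writeIslandBed <- function(islands, path) {
  gr <- GenomicRanges::granges(islands)
  if (length(gr)) {
    gr$name <- paste0("island_", seq_along(gr))
    gr$score <- S4Vectors::mcols(islands)$mean_te_fraction
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
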