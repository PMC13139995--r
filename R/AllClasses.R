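#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
NULL

#' SiteCalls: per-CpG methylation call table
#'
#' The common currency of the pipeline: one range of width 1 per CpG site
#' (the cytosine position, 1-based), with metadata columns `called_reads`,
#' `methylated_reads` and `frequency`. Strand is `+`/`-` for strand-resolved
#' tables (e.g. bisulfite per-cytosine reports) and `*` for CpG-motif-level
#' or strand-merged tables.
#'
#' @slot elementMetadata inherited from [GenomicRanges::GRanges]; must carry
#'   the three columns above.
#' @seealso [aggregateFrequencies()], [mergeComplementaryCpg()],
#'   [filterSites()]
#' @export
setClass("SiteCalls", contains = "GRanges")

.validSiteCalls <- function(object) {
  msg <- NULL
  mc <- S4Vectors::mcols(object)
  need <- c("called_reads", "methylated_reads", "frequency")
  miss <- setdiff(need, colnames(mc))
  if (length(miss)) {
    return(paste0("missing metadata column(s): ", paste(miss, collapse = ", ")))
  }
  if (length(object)) {
    if (any(GenomicRanges::width(object) != 1L)) {
      msg <- c(msg, "all sites must have width 1")
    }
    cr <- mc$called_reads
    mr <- mc$methylated_reads
    if (any(cr < 0) || any(mr < 0) || any(mr > cr)) {
      msg <- c(msg, "need 0 <= methylated_reads <= called_reads")
    }
    pos <- cr > 0
    if (any(pos)) {
      dev <- abs(mc$frequency[pos] - mr[pos] / cr[pos])
      if (any(dev > 1e-9)) {
        msg <- c(msg, "frequency must equal methylated_reads/called_reads")
      }
    }
    key <- paste(GenomeInfoDb::seqnames(object), GenomicRanges::start(object),
                 GenomicRanges::strand(object))
    if (anyDuplicated(key)) msg <- c(msg, "(chrom, pos, strand) must be unique")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("SiteCalls", .validSiteCalls)

#' Construct a SiteCalls table
#'
#' @param chrom Character vector of chromosome names (or a `GRanges` of
#'   width-1 sites carrying the count columns, in which case the remaining
#'   arguments are ignored).
#' @param pos 1-based cytosine positions.
#' @param strand `+`, `-` or `*` (motif-level / merged).
#' @param called_reads,methylated_reads Non-negative integer counts;
#'   `methylated_reads <= called_reads`.
#' @return A [SiteCalls-class] object sorted by (chrom, pos).
#' @examples
#' SiteCalls("chr1", c(100, 200), "+", c(10, 12), c(3, 0))
#' @export
SiteCalls <- function(chrom, pos = NULL, strand = "*",
                      called_reads = integer(), methylated_reads = integer()) {
  if (is(chrom, "GRanges")) {
    gr <- chrom
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = pos, width = 1L),
      strand = rep(strand, length.out = length(pos))
    )
    S4Vectors::mcols(gr)$called_reads <- as.integer(called_reads)
    S4Vectors::mcols(gr)$methylated_reads <- as.integer(methylated_reads)
  }
  cr <- S4Vectors::mcols(gr)$called_reads
  mr <- S4Vectors::mcols(gr)$methylated_reads
  S4Vectors::mcols(gr)$frequency <- ifelse(cr > 0, mr / cr, NA_real_)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  new("SiteCalls", gr)
}

#' GeneSet: gene models with ranked exons
#'
#' Gene bodies (TSS to TTS, 1-based closed, as a named `GRanges`) together
#' with each gene's exons as a `GRangesList` ordered 5'-to-3' on the gene's
#' own strand. Multi-transcript genes are collapsed to their longest
#' transcript on import.
#'
#' @slot genes `GRanges` of gene bodies, names = gene ids, strand required.
#' @slot exons `GRangesList` parallel to `genes`; exon rank = list position.
#' @export
setClass("GeneSet",
  representation(genes = "GRanges", exons = "GRangesList")
)

.validGeneSet <- function(object) {
  msg <- NULL
  g <- object@genes
  e <- object@exons
  if (length(g) != length(e)) msg <- c(msg, "genes and exons lengths differ")
  if (length(g)) {
    if (is.null(names(g)) || anyDuplicated(names(g))) {
      msg <- c(msg, "genes must have unique names (gene ids)")
    }
    if (any(GenomicRanges::strand(g) == "*")) {
      msg <- c(msg, "gene strand must be + or -")
    }
    if (!identical(names(g), names(e))) {
      msg <- c(msg, "exon list names must match gene names")
    }
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("GeneSet", .validGeneSet)

#' @rdname GeneSet-class
#' @param genes,exons See slot descriptions.
#' @export
GeneSet <- function(genes, exons) {
  if (is.null(names(exons))) names(exons) <- names(genes)
  new("GeneSet", genes = genes, exons = exons[names(genes)])
}

#' RepeatSet: transposable-element annotation
#'
#' TE copies as a `GRanges` with a `te_class` metadata column
#' (e.g. LTR/DNA/LINE/SINE). Overlapping (nested) repeats are permitted.
#' @export
setClass("RepeatSet", contains = "GRanges")

.validRepeatSet <- function(object) {
  if (!"te_class" %in% colnames(S4Vectors::mcols(object))) {
    "missing metadata column te_class"
  } else TRUE
}
setValidity("RepeatSet", .validRepeatSet)

#' @rdname RepeatSet-class
#' @param chrom Chromosome names or a ready `GRanges` with `te_class`.
#' @param start,end 1-based closed interval bounds.
#' @param te_class Repeat class labels.
#' @export
RepeatSet <- function(chrom, start = NULL, end = NULL, te_class = "TE") {
  if (is(chrom, "GRanges")) {
    gr <- chrom
    if (!"te_class" %in% colnames(S4Vectors::mcols(gr))) {
      S4Vectors::mcols(gr)$te_class <- te_class
    }
  } else {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 te_class = te_class)
  }
  new("RepeatSet", GenomicRanges::sort(gr, ignore.strand = TRUE))
}

#' Segmentation: a piecewise-constant mean fit of a windowed signal
#'
#' Result of the exact penalized changepoint solver: changepoints are stored
#' as the last window index of every segment except the final one, so `k`
#' changepoints define `k + 1` segments partitioning `1..n`.
#'
#' @slot n Number of windows.
#' @slot changepoints Integer vector `0 < tau_1 < ... < tau_k < n`.
#' @slot means Per-segment arithmetic means (length `k + 1`).
#' @slot cost Total cost: sum of segment SSEs plus `penalty * k`.
#' @slot penalty The penalty per changepoint used in the fit.
#' @export
setClass("Segmentation",
  representation(n = "integer", changepoints = "integer",
                 means = "numeric", cost = "numeric", penalty = "numeric")
)

.validSegmentation <- function(object) {
  msg <- NULL
  tau <- object@changepoints
  if (length(tau)) {
    if (is.unsorted(tau, strictly = TRUE) || tau[1] <= 0 ||
        tau[length(tau)] >= object@n) {
      msg <- c(msg, "changepoints must satisfy 0 < tau_1 < ... < tau_k < n")
    }
  }
  if (length(object@means) != length(tau) + 1L) {
    msg <- c(msg, "need one mean per segment (k + 1)")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("Segmentation", .validSegmentation)

#' TEIslandSet: called TE islands
#'
#' Disjoint, sorted genomic intervals of elevated TE density, each spanning
#' whole analysis windows, with the segment's mean TE fraction in
#' `mean_te_fraction`.
#' @export
setClass("TEIslandSet", contains = "GRanges")

.validTEIslandSet <- function(object) {
  msg <- NULL
  if (!"mean_te_fraction" %in% colnames(S4Vectors::mcols(object))) {
    msg <- c(msg, "missing metadata column mean_te_fraction")
  }
  if (length(object) > 1L) {
    red <- GenomicRanges::reduce(GenomicRanges::granges(object),
                                 min.gapwidth = 0L, ignore.strand = TRUE)
    if (length(red) != length(object)) msg <- c(msg, "islands must be disjoint")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("TEIslandSet", .validTEIslandSet)
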