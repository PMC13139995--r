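#' @rdname SiteCalls-class
#' @param x A `SiteCalls` object.
#' @export
calledReads <- function(x) S4Vectors::mcols(x)$called_reads

#' @rdname SiteCalls-class
#' @export
methylatedReads <- function(x) S4Vectors::mcols(x)$methylated_reads

#' @rdname SiteCalls-class
#' @export
methFrequency <- function(x) S4Vectors::mcols(x)$frequency

#' @rdname GeneSet-class
#' @param x A `GeneSet`.
#' @export
geneRanges <- function(x) x@genes

#' @rdname GeneSet-class
#' @export
geneExons <- function(x) x@exons

#' @rdname GeneSet-class
#' @export
geneIds <- function(x) names(x@genes)

#' Strand-aware transcription start / termination sites
#'
#' @param x A `GeneSet`.
#' @return Named integer vector of plus-strand coordinates of each gene's
#'   TSS (resp. TTS); for minus-strand genes the TSS is the gene end.
#' @export
geneTss <- function(x) {
  g <- x@genes
  ifelse(as.character(GenomicRanges::strand(g)) == "-",
         GenomicRanges::end(g), GenomicRanges::start(g))
}

#' @rdname geneTss
#' @export
geneTts <- function(x) {
  g <- x@genes
  ifelse(as.character(GenomicRanges::strand(g)) == "-",
         GenomicRanges::start(g), GenomicRanges::end(g))
}

setMethod("length", "GeneSet", function(x) length(x@genes))

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet with", length(object), "genes on",
      length(unique(as.character(GenomeInfoDb::seqnames(object@genes)))),
      "sequence(s)\n")
  nex <- S4Vectors::elementNROWS(object@exons)
  if (length(object)) {
    cat("  exons per gene: median", stats::median(nex),
        "range", paste(range(nex), collapse = "-"), "\n")
  }
})

setMethod("show", "Segmentation", function(object) {
  cat("Segmentation of", object@n, "windows:",
      length(object@changepoints), "changepoint(s), penalty",
      object@penalty, "\n")
  cat("  segment means:", paste(signif(object@means, 3), collapse = " "), "\n")
  cat("  total cost:", format(object@cost), "\n")
})

#' @rdname Segmentation-class
#' @param x A `Segmentation`.
#' @export
changepoints <- function(x) x@changepoints

#' @rdname Segmentation-class
#' @export
segmentMeans <- function(x) x@means

#' Segment index bounds of a Segmentation
#'
#' @param x A `Segmentation`.
#' @return data.frame with one row per segment: `start`, `end` (window
#'   indices, inclusive) and `mean`.
#' @export
segmentTable <- function(x) {
  starts <- c(1L, x@changepoints + 1L)
  ends <- c(x@changepoints, x@n)
  data.frame(start = starts, end = ends, mean = x@means)
}
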