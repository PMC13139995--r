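#' Read per-read nanopore methylation calls (nanopolish dialect)
#'
#' Parses the tab-separated per-read output of an LLR-emitting nanopore
#' methylation caller. Required columns: `chromosome`, `strand`, `start`,
#' `end`, `read_name`, `log_lik_ratio`, `num_motifs`, `sequence` (the
#' dialect's `log_lik_methylated`, `log_lik_unmethylated` and
#' `num_calling_strands` columns are tolerated and ignored). Coordinates in
#' the file are 0-based; returned positions are 1-based cytosine positions.
#'
#' Callers group nearby CpGs (short k-mer motifs) into a single call that
#' carries one LLR for `num_motifs` sites. With `split_groups = TRUE`
#' (default) each grouped call is expanded into one record per CG in
#' `sequence`, every record inheriting the group's LLR; positions are
#' located at each CG of the motif sequence relative to the first.
#'
#' @param path TSV file with header.
#' @param split_groups Expand grouped calls into per-motif records.
#' @return data.frame with columns `chrom`, `pos` (1-based C position),
#'   `strand`, `read_id`, `llr`, `num_motifs`.
#' @export
readNanopolishCalls <- function(path, split_groups = TRUE) {
  df <- readTsv(path)
  need <- c("chromosome", "strand", "start", "end", "read_name",
            "log_lik_ratio", "num_motifs", "sequence")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  llr <- suppressWarnings(as.numeric(df$log_lik_ratio))
  bad <- which(is.na(llr) & !is.na(df$log_lik_ratio) | is.na(df$log_lik_ratio))
  if (length(bad)) {
    stop("malformed log_lik_ratio at line ", bad[1] + 1L,
         " (1 header line + record ", bad[1], ")")
  }
  start1 <- as.integer(df$start) + 1L  # 0-based file -> 1-based internal
  nm <- as.integer(df$num_motifs)
  if (!nrow(df)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), read_id = character(),
                      llr = numeric(), num_motifs = integer()))
  }
  if (split_groups) {
    offs <- lapply(seq_len(nrow(df)), function(i) {
      if (nm[i] <= 1L) return(0L)
      hits <- gregexpr("CG", df$sequence[i], fixed = TRUE)[[1]]
      if (hits[1] == -1L || length(hits) < nm[i]) {
        # sequence does not expose the motif positions; keep the group call
        return(0L)
      }
      as.integer(hits[seq_len(nm[i])] - hits[1])
    })
    reps <- lengths(offs)
    out <- data.frame(
      chrom = rep(df$chromosome, reps),
      pos = rep(start1, reps) + unlist(offs),
      strand = rep(df$strand, reps),
      read_id = rep(df$read_name, reps),
      llr = rep(llr, reps),
      num_motifs = 1L,
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(chrom = df$chromosome, pos = start1, strand = df$strand,
                      read_id = df$read_name, llr = llr, num_motifs = nm,
                      stringsAsFactors = FALSE)
  }
  out
}

#' Aggregate read-level LLR calls into per-site methylation frequencies
#'
#' Per (chrom, pos): reads with `llr > +threshold` count as methylated,
#' reads with `llr < -threshold` as unmethylated, and reads with
#' `|llr| <= threshold` are ambiguous and excluded from both numerator and
#' denominator. Frequency = methylated / called. The result is
#' motif-level (strand `*`).
#'
#' @param calls data.frame as returned by [readNanopolishCalls()] (columns
#'   `chrom`, `pos`, `llr` required).
#' @param llr_threshold Positive LLR magnitude below which a call is
#'   ambiguous (default 2.0, the conventional aggregation cutoff).
#' @return A [SiteCalls-class] table.
#' @export
aggregateFrequencies <- function(calls, llr_threshold = 2) {
  stopifnot(llr_threshold > 0)
  if (!nrow(calls)) {
    return(SiteCalls(character(), integer(), "*", integer(), integer()))
  }
  keep <- abs(calls$llr) > llr_threshold
  calls <- calls[keep, , drop = FALSE]
  if (!nrow(calls)) {
    return(SiteCalls(character(), integer(), "*", integer(), integer()))
  }
  key <- paste(calls$chrom, calls$pos, sep = "\r")
  called <- tapply(calls$llr, key, length)
  meth <- tapply(calls$llr, key, function(v) sum(v > llr_threshold))
  parts <- strsplit(names(called), "\r", fixed = TRUE)
  SiteCalls(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    strand = "*",
    called_reads = as.integer(called),
    methylated_reads = as.integer(meth)
  )
}

#' Read a Bismark-style per-cytosine coverage report
#'
#' Dialect: `chrom`, `start` (1-based), `end`, `methylation_percentage`,
#' `count_methylated`, `count_unmethylated`, with an optional 7th `strand`
#' column (absent from the upstream tool's output; emitted by this
#' package's synthetic writer so complementary strands can be merged).
#' The frequency is always recomputed from the counts; if the percentage
#' column disagrees with the counts by more than 0.5 percentage points a
#' warning is raised and the counts win. Rows with zero total counts are
#' dropped with a warning.
#'
#' @param path TSV file, no header.
#' @return A [SiteCalls-class] table (strand-resolved if the file has the
#'   strand column, otherwise strand `*`).
#' @export
readBismarkCoverage <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("expected >= 6 columns in coverage file")
  names(df)[1:6] <- c("chrom", "start", "end", "pct", "n_meth", "n_unmeth")
  strand <- if (ncol(df) >= 7L) as.character(df[[7]]) else rep("*", nrow(df))
  called <- df$n_meth + df$n_unmeth
  zero <- called == 0
  if (any(zero)) {
    warning(sum(zero), " row(s) with zero counts dropped")
    df <- df[!zero, , drop = FALSE]
    strand <- strand[!zero]
    called <- called[!zero]
  }
  if (nrow(df)) {
    freq_pct <- 100 * df$n_meth / called
    off <- abs(freq_pct - df$pct) > 0.5
    if (any(off)) {
      warning(sum(off), " row(s) with percentage inconsistent with counts ",
              "(>0.5); counts win")
    }
  }
  SiteCalls(df$chrom, as.integer(df$start), strand,
            as.integer(called), as.integer(df$n_meth))
}

#' Merge complementary CpG strands
#'
#' In a strand-resolved per-cytosine table the minus-strand C of a CpG sits
#' one bp 3' of the plus-strand C. Pairs of rows `(+, pos)` / `(-, pos + 1)`
#' on the same chromosome are merged: counts summed, position = plus-strand
#' C, strand set to `*` (the merged marker), frequency recomputed. Unpaired
#' stranded rows and rows already at strand `*` pass through unchanged.
#' Total called and methylated reads are conserved.
#'
#' @param sites A strand-resolved [SiteCalls-class] table.
#' @return A [SiteCalls-class] table.
#' @export
mergeComplementaryCpg <- function(sites) {
  if (!length(sites)) return(sites)
  chr <- as.character(GenomeInfoDb::seqnames(sites))
  pos <- GenomicRanges::start(sites)
  str <- as.character(GenomicRanges::strand(sites))
  plus <- which(str == "+")
  minus <- which(str == "-")
  mkey <- paste(chr[minus], pos[minus], sep = "\r")
  hit <- match(paste(chr[plus], pos[plus] + 1L, sep = "\r"), mkey)
  paired_p <- plus[!is.na(hit)]
  paired_m <- minus[hit[!is.na(hit)]]
  cr <- calledReads(sites)
  mr <- methylatedReads(sites)
  keep <- setdiff(seq_along(sites), c(paired_p, paired_m))
  merged <- SiteCalls(
    chrom = c(chr[keep], chr[paired_p]),
    pos = c(pos[keep], pos[paired_p]),
    strand = c(str[keep], rep("*", length(paired_p))),
    called_reads = c(cr[keep], cr[paired_p] + cr[paired_m]),
    methylated_reads = c(mr[keep], mr[paired_p] + mr[paired_m])
  )
  merged
}

#' Filter sites on minimum read coverage
#'
#' Removes sites with fewer than `min_coverage` called reads (default 10,
#' the conventional per-CpG depth floor for methylation frequency
#' estimates). The number of removed sites is recorded in
#' `metadata(result)$n_removed`.
#'
#' @param sites A [SiteCalls-class] table.
#' @param min_coverage Integer >= 1.
#' @return Filtered [SiteCalls-class] table.
#' @export
filterSites <- function(sites, min_coverage = 10) {
  stopifnot(min_coverage >= 1)
  keep <- calledReads(sites) >= min_coverage
  out <- sites[keep]
  S4Vectors::metadata(out)$n_removed <- sum(!keep)
  out
}

#' Build a genome CpG index
#'
#' Per-chromosome counts of all CpG positions in the genome, used by the
#' call-density filter. Accepts a named integer vector directly, a BED file
#' of CpG positions, or a `GRanges` of CpG sites.
#'
#' @param x Named integer vector, BED3 path, or `GRanges`.
#' @return Named integer vector: chromosome -> CpG count.
#' @export
cpgIndex <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    bed <- utils::read.delim(x, header = FALSE, stringsAsFactors = FALSE)
    counts <- table(bed[[1]])
  } else if (is(x, "GRanges")) {
    counts <- table(as.character(GenomeInfoDb::seqnames(x)))
  } else if (is.numeric(x) && !is.null(names(x))) {
    return(vapply(x, as.integer, 1L))
  } else {
    stop("cannot build a CpG index from this input")
  }
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Drop chromosomes with too few called CpGs
#'
#' Removes every site of any sequence where the fraction of its CpGs that
#' received a call is strictly below `min_fraction` (default 0.10) —
#' sequences with calls at less than 10% of their CpGs are considered
#' unreliable. Dropped sequences are recorded in
#' `metadata(result)$dropped_sequences`.
#'
#' @param sites A [SiteCalls-class] table.
#' @param index Genome CpG index (see [cpgIndex()]); every chromosome in
#'   `sites` must be present.
#' @param min_fraction Call-density threshold (strict less-than).
#' @return Filtered [SiteCalls-class] table.
#' @export
filterLowCallSequences <- function(sites, index, min_fraction = 0.10) {
  chr <- as.character(GenomeInfoDb::seqnames(sites))
  chroms <- unique(chr)
  missing <- setdiff(chroms, names(index))
  if (length(missing)) {
    stop("chromosome(s) absent from CpG index: ",
         paste(missing, collapse = ", "))
  }
  called <- table(chr)
  frac <- as.numeric(called[chroms]) / as.numeric(index[chroms])
  drop <- chroms[frac < min_fraction]
  out <- sites[!chr %in% drop]
  S4Vectors::metadata(out)$dropped_sequences <- drop
  out
}

#' Write / read the canonical site TSV
#'
#' Column order: `chrom`, `pos` (1-based C position), `strand`,
#' `called_reads`, `methylated_reads`, `frequency`. The round trip
#' `readSiteTable(writeSiteTable(x))` is the identity.
#'
#' @param sites A [SiteCalls-class] table.
#' @param path Output file.
#' @return `path`, invisibly (writer); a [SiteCalls-class] table (reader).
#' @export
writeSiteTable <- function(sites, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(sites)),
    pos = GenomicRanges::start(sites),
    strand = as.character(GenomicRanges::strand(sites)),
    called_reads = calledReads(sites),
    methylated_reads = methylatedReads(sites),
    frequency = methFrequency(sites)
  )
  writeTsv(df, path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
  df <- readTsv(path)
  SiteCalls(df$chrom, as.integer(df$pos), df$strand,
            as.integer(df$called_reads), as.integer(df$methylated_reads))
}
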