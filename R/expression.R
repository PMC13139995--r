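#' Compute FPKM from raw gene counts
#'
#' Standard FPKM: `counts * 1e9 / (total_mapped_reads * gene_length_bp)`,
#' with per-sample totals defaulting to column sums. The `"printed"`
#' variant uses gene length in kb with the same 1e9 numerator (a form that
#' appears in some write-ups and is dimensionally 1000x the standard
#' scale); it is provided for comparability only.
#'
#' @param counts Integer matrix, genes x samples (rownames = gene ids).
#' @param gene_lengths Numeric vector of gene lengths in bp, parallel to
#'   rows (or named by gene id).
#' @param totals Per-sample total mapped reads; default `colSums(counts)`.
#' @param variant `"standard"` (bp, default) or `"printed"` (kb).
#' @return Numeric matrix of FPKM values, same dimensions as `counts`.
#' @examples
#' computeFpkm(matrix(100, 1, 1), 1000, totals = 1e6) # 100
#' @export
computeFpkm <- function(counts, gene_lengths, totals = colSums(counts),
                        variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  stopifnot(length(gene_lengths) == nrow(counts))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(totals <= 0)) stop("per-sample totals must be positive")
  len <- if (variant == "standard") gene_lengths else gene_lengths / 1000
  sweep(counts * 1e9 / len, 2, totals, "/")
}

#' Read a gene counts table
#'
#' TSV with columns `gene_id`, `length` (bp) and one column per sample.
#'
#' @param path TSV file with header.
#' @return List: `counts` (integer matrix), `gene_lengths` (named).
#' @export
readCountsTable <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("gene_id", "length") %in% colnames(df)))
  samples <- setdiff(colnames(df), c("gene_id", "length"))
  counts <- as.matrix(df[, samples, drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  lens <- df$length
  names(lens) <- df$gene_id
  list(counts = counts, gene_lengths = lens)
}

#' @rdname readCountsTable
#' @param counts,gene_lengths As in [computeFpkm()].
#' @export
writeCountsTable <- function(counts, gene_lengths, path) {
  df <- data.frame(gene_id = rownames(counts),
                   length = as.numeric(gene_lengths),
                   counts, check.names = FALSE)
  writeTsv(df, path)
}

#' Expression difference between methylation classes
#'
#' Two-sided Wilcoxon rank-sum test of per-gene mean FPKM between two
#' methylation classes (GBM vs UM by default, or PMG vs PUM).
#'
#' @param fpkm FPKM matrix (genes x samples) or a per-gene numeric vector
#'   of mean FPKM, named by gene id.
#' @param classification data.frame from [classifyGeneBodies()] or
#'   [classifyPromoters()].
#' @param classes Length-2 character: the two class labels to compare.
#' @return List: `statistic` (W), `p_value`, `median_1`, `median_2`,
#'   `n_1`, `n_2`, `classes`.
#' @export
compareExpressionByClass <- function(fpkm, classification,
                                     classes = c("GBM", "UM")) {
  expr <- if (is.matrix(fpkm)) rowMeans(fpkm) else fpkm
  g1 <- classification$gene_id[classification$class == classes[1]]
  g2 <- classification$gene_id[classification$class == classes[2]]
  x <- expr[names(expr) %in% g1]
  y <- expr[names(expr) %in% g2]
  if (!length(x) || !length(y)) {
    stop("class '", classes[which(!c(length(x), length(y)))],
         "' has no genes with expression values")
  }
  w <- wilcoxonRankSum(x, y)
  list(statistic = w$statistic, p_value = w$p_value,
       median_1 = stats::median(x), median_2 = stats::median(y),
       n_1 = length(x), n_2 = length(y), classes = classes)
}

#' Correlation between gene-body methylation and expression
#'
#' Pearson correlation (with t-based p-value) between per-gene weighted
#' body methylation and per-gene mean FPKM, optionally log1p-transformed.
#'
#' @param fpkm FPKM matrix or named per-gene mean FPKM vector.
#' @param classification data.frame from [classifyGeneBodies()] (uses
#'   `gene_id` and `weighted_methylation`).
#' @param transform `"identity"` (default) or `"log1p"`.
#' @return List: `r`, `p_value`, `n`.
#' @export
methylationExpressionCorrelation <- function(fpkm, classification,
                                             transform = c("identity",
                                                           "log1p")) {
  transform <- match.arg(transform)
  expr <- if (is.matrix(fpkm)) rowMeans(fpkm) else fpkm
  idx <- match(classification$gene_id, names(expr))
  keep <- !is.na(idx) & !is.na(classification$weighted_methylation)
  x <- classification$weighted_methylation[keep]
  y <- expr[idx[keep]]
  if (transform == "log1p") y <- log1p(y)
  pearsonCorTest(x, y)
}
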