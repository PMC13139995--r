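# methylomer

Downstream analysis of whole-genome CpG methylation in low-methylation
(insect-style) genomes, from per-site or per-read methylation calls to
biological summaries:

* **Site tables** — aggregate nanopore per-read log-likelihood-ratio
  calls into per-CpG methylation frequencies, read bisulfite
  per-cytosine coverage reports, merge complementary CpG strands, and
  apply coverage (≥ 10 reads/site) and call-density (≥ 10% of a
  sequence's CpGs) filters.
* **Gene-body / promoter classification** — the two-stage binomial
  construction: sites are binarized against a per-read error rate, then
  each gene body (TSS–TTS) is tested for an excess of methylated sites
  over the genome-wide fraction `p0`,
  `P(X >= k | Binomial(n, p0))`, with Benjamini–Hochberg correction
  across genes. `q < alpha` ⇒ **GBM**, else **UM**. Promoters (200 bp
  upstream of the TSS) use the same test plus a 3% weighted-methylation
  floor for **PMG** vs **PUM**.
* **Metagene profiles** — weighted methylation in 200-bp bins across
  4-kb flanks and 40 scaled bins across gene bodies, strand-aware.
* **TE islands** — exact penalized changepoint segmentation
  (optimal partitioning, L2 cost, `sum SSE + penalty * k`) of 50-kb
  window TE fractions; segments elevated ≥ 0.2 above the background
  baseline are islands; methylation inside vs outside is compared by
  Wilcoxon rank-sum.
* **Concordance** — join two site tables (e.g. nanopore vs bisulfite) by
  position and report shared/unique sites and the Pearson correlation of
  frequencies, optionally window-averaged.
* **Expression link** — FPKM from raw counts
  (`counts * 1e9 / (total_mapped * length_bp)`), GBM-vs-UM expression by
  rank-sum, and the methylation–expression Pearson correlation.
* **Synthetic methylomes** — a fully seeded generator (annotated
  multi-chromosome genome, TE islands, ~3% background methylation,
  planted GBM/PMG gene sets, read-level LLR calls, expression counts
  tied to methylation) with complete ground truth, so every stage is
  testable without sequencing data.

Everything is built on Bioconductor containers (`GRanges`-backed S4
classes with validity checks and accessors).

## Worked example

```r
library(methylomer)

cfg  <- simulationConfig(seed = 42)          # 2 x 2 Mb, 200 genes, 30x
sim  <- simulateMethylome(cfg)
sites <- filterSites(sim$sites, min_coverage = 10)

cl <- classifyGeneBodies(sim$genes, sites)
table(cl$class)
#> GBM  UM
#>  60 140
```

Sixty genes are called gene-body methylated against the genome-wide
methylated-site fraction (`p0 = 0.0399` here) — exactly the planted set:

```r
mean(sim$truth@gbm_genes %in% cl$gene_id[cl$class == "GBM"])
#> [1] 1
head(cl[cl$class == "GBM", c("gene_id", "n_sites", "n_methylated_sites",
                             "weighted_methylation", "q_value")], 3)
#>      gene_id n_sites n_methylated_sites weighted_methylation      q_value
#> 1 chr1_g0001      58                 43            0.2659875 3.794676e-46
#> 2 chr1_g0002      40                 33            0.3203320 2.134832e-38
#> 4 chr1_g0004      25                 21            0.3242188 3.012887e-25
```

Per gene: `n_sites` covered CpGs, of which `n_methylated_sites` passed
the site-level binomial test; `weighted_methylation` is summed methylated
reads over summed called reads (~0.30, the planted gene-body level); the
BH-adjusted binomial tail `q_value` drives the class.

```r
isl <- findTEIslands(sim$repeats, sim$chrom_sizes,
                     window_bp = 50000, penalty = 40, drop_cutoff = 0.2)
GenomicRanges::granges(isl$islands)
#> GRanges object with 4 ranges and 0 metadata columns:
#>       seqnames          ranges strand
#>   [1]     chr1   200001-500000      *
#>   [2]     chr1 1600001-1900000      *
#>   [3]     chr2    50001-350000      *
#>   [4]     chr2 1450001-1750000      *
```

All four planted 300-kb islands are recovered at window resolution.

```r
fpkm <- computeFpkm(sim$counts, sim$gene_lengths)
compareExpressionByClass(fpkm, cl)
#> GBM vs UM: W = 5478, p = 0.00066, medians 1142.9 vs 681.9
methylationExpressionCorrelation(fpkm, cl, transform = "log1p")
#> r = 0.238, p = 0.000697
```

GBM genes are more expressed than UM genes, and gene-body methylation
correlates positively with expression — the planted relationship
(`log(1+FPKM) = 2 + 3*m + N(0,1)`, implying r ≈ 0.35 at the default
methylation spread; a single 200-gene genome recovers it with sampling
error of roughly ±0.07).

The whole chain also runs as one call (and from a shell via
`inst/scripts/run_pipeline.R`):

```r
report <- runPipeline(readRunConfig(overrides = list(seed = 42, outdir = "run1")))
```

writing the site tables, classifications, metaprofile, island BED and a
JSON run report with row counts and content checksums; identical config +
seed reproduces every file byte for byte.

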