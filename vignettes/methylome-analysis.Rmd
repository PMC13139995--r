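---
title: "Methylome analysis with methylomer: models, parameters and design"
author: "methylomer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome analysis with methylomer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylomer)
```

# Scope

`methylomer` takes per-CpG methylation calls — from a nanopore
log-likelihood-ratio caller or a bisulfite per-cytosine coverage report —
and carries them through the downstream analyses typical of low-methylation
invertebrate genomes: site-level aggregation and filtering, gene-body and
promoter methylation classification, metagene profiles, TE-island
segmentation, cross-technology concordance and the methylation–expression
link. A seeded synthetic-methylome generator with complete ground truth
makes every stage testable end to end.

# From reads to sites

A nanopore methylation caller emits one log-likelihood ratio (LLR) per
read per CpG group: positive values support methylation. `aggregateFrequencies()`
counts, per site, reads with `llr > t` as methylated and reads with
`llr < -t` as unmethylated; calls with `|llr| <= t` are ambiguous and enter
neither the numerator nor the denominator. The threshold `t` defaults to
2.0, the conventional aggregation cutoff for this dialect, and is exposed
as an argument. Grouped calls (`num_motifs > 1`) are optionally split into
one record per CG of the motif sequence, each inheriting the group LLR.

Bisulfite coverage reports arrive per cytosine and per strand. The two
cytosines of a CpG measure the same methylation state, so
`mergeComplementaryCpg()` sums the counts of `(+, pos)` / `(-, pos + 1)`
pairs at the plus-strand C position; read counts are conserved exactly,
and unpaired rows pass through. The reported percentage column is never
trusted: frequency is always recomputed from the counts.

Two filters follow the field's conventions: a minimum of 10 called reads
per site (below which frequency estimates are too noisy to classify), and
removal of whole sequences in which fewer than 10% of the genome's CpGs
received a call (an indicator of mapping or coverage pathology on that
contig). Both thresholds are arguments.

Coordinates are 1-based closed throughout, the GenomicRanges convention;
the 0-based dialects (nanopore caller TSV, BED) are converted at the
readers and writers so no other code handles offsets.

# Gene-body and promoter classification

The classification is the two-stage binomial construction standard for
invertebrate methylomes:

1. **Site binarization.** Each site's `methylated_reads` out of
   `called_reads` is tested against a per-read error rate
   $\varepsilon = 0.05$ (one-sided binomial upper tail), BH-corrected
   across all sites; a site is *methylated* when $q < 0.05$. A simple
   frequency cutoff (default 0.5) is available as an alternative mode.
2. **Gene-level test.** For each gene body (TSS–TTS, introns included),
   the count $k$ of methylated sites among $n$ covered sites is tested
   against the genome-wide methylated-site fraction $p_0$ with the exact
   binomial upper tail $P(X \ge k \mid \mathrm{Bin}(n, p_0))$,
   BH-corrected across genes within the stage. $q < \alpha$ (default
   0.05) gives class GBM, otherwise UM; genes with no covered sites are
   `unclassified` and excluded from the BH family.

$p_0$ defaults to the observed methylated-site fraction of the stage's own
table, matching the idea of testing against that stage's genome-wide
average; it can be overridden. The per-gene construction is used because
the alternative reading (a single test per cytosine with no gene stage)
cannot yield a per-gene class at all; the per-read-count variant of the
gene test is not offered because it conflates coverage with methylation
extent.

Promoters (200 bp upstream of the TSS, strand-aware) use the same
machinery plus a floor: PMG additionally requires weighted methylation
above 3%, reflecting the convention that a promoter is only called
methylated above that level. Weighted methylation is always
$\sum \text{methylated reads} / \sum \text{called reads}$ over the
region's sites — coverage-weighted, not a mean of frequencies.

The metagene profile pools weighted methylation into 20 fixed 200-bp bins
per 4-kb flank and 40 proportionally scaled bins across each body,
strand-aware; flank bins number outward from the gene, so bin 1 touches
the TSS/TTS. Genes shorter than the bin count simply spread their sites
over proportional bins.

# TE islands

TE content is summarized as the covered fraction of fixed 50-kb windows
(intervals are flattened first, so fragmented annotations count once).
Each chromosome's window signal is segmented by exact optimal-partitioning
dynamic programming under the L2 (Gaussian mean) cost:

$$\min \sum_{\text{segments}} \mathrm{SSE} + \lambda \cdot k$$

with $k$ the number of changepoints. The $O(n^2)$ recursion is exact (no
pruning) and ties break toward fewer changepoints, so constant signals
yield none. The default penalty is 40 on the *standardized* scale: the
convention of mean-model changepoint packages, where the penalty applies
to $\mathrm{SSE}/\sigma^2$. `findTEIslands()` therefore multiplies the
penalty by a noise-variance estimate before calling the raw solver; a raw
SSE penalty of 40 on a [0, 1] fraction signal of a few hundred windows
could never be paid by any split, so the standardized reading is the only
one under which the published parameter is meaningful. The variance is
estimated from the lower quartile of squared first differences
(chi-square(1)-calibrated): with a handful of islands on a short
chromosome, level shifts and their ramp windows contaminate a quarter of
the differences, and a median-based estimator inflates severalfold,
silently tripling the penalty.

A segment is called an island when its mean exceeds the baseline by the
drop cutoff (default 0.2). The baseline defaults to the length-weighted
median of segment means — the median of the fitted per-window values. An
unweighted median over segments drifts upward whenever islands account
for half the *segments* while covering a small fraction of the *windows*,
which is exactly the planted-island regime; the weighted median is the
background level the rule intends. Adjacent island segments merge, and
methylation inside vs outside islands is compared with the two-sided
Wilcoxon rank-sum test.

# Concordance and expression

`joinSites()` matches two strand-merged tables by exact position (a
±1 bp flag covers C- vs CpG-anchored dialects) and partitions both into
shared and unique sites. Agreement is summarized as the Pearson
correlation of shared-site frequencies, with optional window-mean
correlations: window means damp the per-site binomial sampling noise, so
on spatially structured methylomes the windowed correlation is at least
the per-site one.

FPKM is computed in the standard form
$\text{counts} \times 10^9 / (\text{total mapped reads} \times \text{length}_{bp})$.
A `"printed"` variant with gene length in kb (dimensionally 1000× the
standard scale) is kept behind a flag for comparability with write-ups
that state the formula that way; it rescales every gene identically, so
correlations and rank tests are unaffected. GBM-vs-UM expression uses the
rank-sum test on per-gene mean FPKM; the methylation–expression
correlation is Pearson on weighted body methylation vs mean FPKM, with a
`log1p` option.

# Statistical cores

Binomial tails are exact (log-space via `pbinom`). BH is the literal
step-up, validated against a brute-force implementation of its
definition. The rank-sum test uses midranks, and switches between exact
enumeration (combined $n \le 10$) and a tie-corrected,
continuity-corrected normal approximation. The approximation tracks the
exact two-sided p-value within 0.02 for equal group sizes of five and
above — exhaustively over every achievable statistic, not just sampled
data. Below that, the exact distribution has too few atoms for any
continuous approximation to sit within 0.02 (the worst gap is 0.088 at
$n_1 = n_2 = 2$), which is immaterial in practice because those sizes
always take the exact path.

# The synthetic methylome

The generator plants a known truth so recovery is measurable:

* **Genome**: `n_chrom` chromosomes (default 2 × 2 Mb); CpG sites on a
  regular grid (default 100 bp spacing — only positions and counts matter
  downstream, so no sequence is simulated).
* **Genes**: 200 non-overlapping bodies, gamma-distributed lengths around
  3 kb with a floor of 20 CpG spacings so every gene is classifiable;
  random strand; alternating exon/intron splits (mean 4 exons).
* **Methylation**: background per-site probability 0.03 (the ~3% regime
  of low-methylation insect genomes); a planted 30% of genes carry
  gene-body methylation at per-site probability 0.30; an independent 10%
  of genes carry promoter methylation at 0.50. Promoters are short (two
  grid CpGs), so a planted promoter level of 0.3 would be statistically
  unrecoverable from a 2-site binomial regardless of implementation; 0.5
  reflects the near-bimodal promoter methylation real methylomes show and
  makes the planted class detectable — a power consideration, decided
  once at design time. Every regime probability gets Beta-distributed
  per-site jitter (concentration 50), the overdispersion real methylomes
  show; the concentration is a free parameter the source material does
  not constrain.
* **Reads**: coverage Poisson(30) per site; methylated reads draw LLR
  from $N(+5, 1.5)$, unmethylated from $N(-5, 1.5)$. In the noiseless
  limit (`llr_sigma = 0`) re-aggregating the read table reproduces the
  site table exactly, which the tests exploit as an identity.
* **TE landscape**: two islands per chromosome, 300 kb wide (several
  50-kb analysis windows, as in real repeat landscapes where islands are
  hundred-kb blocks), TE fragments of mean length 300 bp (the scale of
  fragmented RepeatMasker hits) covering 60% of island bp and 8%
  elsewhere.
* **Expression**: per gene,
  $\log(1 + \mathrm{FPKM}) = 2 + 3 \cdot m + N(0, 1)$ with $m$ the gene's
  weighted body methylation; counts are drawn
  $\mathrm{Poisson}(\mathrm{FPKM} \cdot \text{total} \cdot \ell / 10^9)$
  per sample (22 samples, ~1e6 reads each) — the FPKM formula run
  backwards. At the default methylation spread this implies a planted
  correlation near 0.35, and the implied value is recorded in the ground
  truth for recovery tests.

Randomness is drawn from one master seed via per-stage, per-chromosome
derived streams (`mixSeed`), so identical config + seed is byte-identical
end to end and regenerating one stage never perturbs another.

What the generator does **not** emulate: sequence content (no FASTA, no
motif effects), bisulfite conversion chemistry or its failure modes,
mapping bias, copy-number variation, correlated methylation between
neighboring CpGs beyond the regime structure, and biological replicate
variance in expression beyond Poisson counting. Passing recovery tests
therefore demonstrates that the algorithms recover the statistical
structure they model — not that they are robust to artifacts those
omitted processes create in real data.

# Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on
2 × 2 Mb genomes (40,000 CpGs, 200 genes) across 10 seeds for recovery
checks, 1 × 1 Mb null genomes across 10–20 seeds for type-I control, and
brute-force-verifiable signals ($n \le 12$) for the changepoint oracle —
sizes chosen so the whole suite completes in minutes while every gene
still carries enough CpGs (≥ 20) for the binomial machinery to operate in
its intended regime. Degenerate inputs are handled explicitly: empty
site tables aggregate to empty tables; zero-coverage sites are absent
from site tables (no reads, no call); `p0 = 0` with observed methylated
sites yields an exact zero p-value; genes shorter than the body bin count
pool proportionally; empty island sets are an error for the methylation
comparison (no comparison group exists) but write as empty BED.

# Configuration and orchestration

`runPipeline()` executes simulate → filter → classify → islands →
concordance → expression from a single validated configuration
(`readRunConfig()`; YAML on disk, unknown keys rejected), writing every
stage's tables plus a JSON run report with row counts, parameters and
content checksums. A thin Rscript wrapper
(`inst/scripts/run_pipeline.R`) exposes the same entry point from a
shell. Logging goes to stderr with stage prefixes; exit codes distinguish
configuration from data errors.

# Limitations

* The classification is per stage; no joint model across stages/castes is
  fitted (stage overlaps are set intersections, as in the descriptive
  practice this follows).
* The island caller assumes a piecewise-constant mean; gradual TE
  density clines are split into steps rather than modeled.
* The 10%-of-CpGs call-density filter is applied per chromosome; if a
  different unit (e.g. scaffold groups) is wanted, pass a different CpG
  index.
* The generator's independence assumptions (sites, reads, samples) make
  its confidence statements optimistic relative to real data with
  correlated errors.
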