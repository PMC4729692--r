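---
title: "Methods: models, parameters and design choices in epistate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in epistate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(epistate)
```

`epistate` analyzes the interplay of two repressive histone
modifications — H3K9me2 (deposited by G9a/GLP) and H3K27me3 (deposited
by PRC2) — with transcription, DNA methylation and regulatory elements
in early mammalian development. This vignette is the package's own
account of its models and numerical choices: what each procedure
assumes, which parameters matter, what the synthetic-data generators do
and do not emulate, and where the design was genuinely open.

## Coordinates and region model

All coordinates are 0-based half-open, BED-native, everywhere
internally; 1-based display is formatting only. This removes any
off-by-one ambiguity between readers, tilers and overlap tests. Tiling
(`make_tiles`) keeps a final truncated tile reaching the chromosome end
so per-chromosome coverage sums are conserved; dropping it would bias
tile summaries against chromosome ends. Promoters default to
TSS −2000/+500 bp strand-aware — a common convention, deliberately
exposed as parameters because annotation-specific promoter definitions
vary and no single window is canonical. CpG promoter classes (HCP, ICP,
LCP) are ordinarily input labels; when sequences are supplied,
`classify_cpg` applies Weber-style thresholds (CpG observed/expected
\> 0.75 with GC \> 0.55 in a 500 bp window for HCP, o/e \< 0.48 for
LCP), documented as one published interpretation of the three-class
scheme.

## ChIP enrichment

Per-region enrichment is log2(normalized ChIP density / normalized
input density), with density = (reads + 0.5) / (library in millions) /
(region length in kb). The 0.5-read pseudocount keeps values finite at
zero-count regions without materially affecting covered regions (a
region with 100 input reads shifts by \< 0.01). Replicates are averaged
*after* the log transform, matching the averaging of two biological
replicates that defines the mark-calling input. Enrichment is invariant
under joint rescaling of ChIP and input library totals, and
monotonically increasing in the region's ChIP count.

One consequence of normalizing by realized library totals: planting a
log2 fold-change of 2 at 10% of regions inflates the ChIP library, so
*absolute* enrichment values shift down by the composition log-ratio
(~0.4 here) while the marked-vs-unmarked contrast stays exactly 2. All
calling operates on relative values, so this does not affect results,
but comparisons across cell types on an absolute scale need
`scale_absolute` with an externally measured global abundance factor.

## Mark calling by exact 1-D k-means

Regions are partitioned into k = 3 clusters on their enrichment values
and the highest-mean cluster is called marked. Because 1-D squared-error
optima are contiguous in sorted order, the package solves the problem
exactly by dynamic programming (O(k·n²) with O(1) segment costs from
prefix sums) rather than by restarted Lloyd iterations. This was a
deliberate design choice: the DP is deterministic, needs no seed, and is
always the global optimum, so the documented equivalence with exhaustive
partition enumeration holds by construction. The `restarts` and `seed`
arguments are accepted for interface stability and ignored.

k = 3 (background / intermediate / marked) is the operative default; it
presumes marked regions are a *minority tail* of the distribution, which
is true genome-wide. When a mark covers the majority of a focused region
subset (e.g. H3K27ac on enhancers, most of which are active), the
top-of-3 rule under-calls: `run_all` therefore clusters enhancers
jointly with a 4× excess of unmarked background windows, emulating
genome-wide calling. Whether the emulated analysis ran k-means per
region class or jointly is not recoverable; the package calls per region
class and per mark.

Differential enrichment between cell types keeps the conventional
thresholds (p \< 0.05, |log2 FC| \> 2) but replaces the count-based
package test with the same fully specified NB machinery used for
expression (below), applied to library-normalized replicate ChIP counts
with a pooled moments dispersion. A region is A-only if marked in A and
either unmarked in B or significantly higher in A; marked in both
without a significant difference is "both".

## The per-embryo DE procedure

Single-embryo RNA-seq is heterogeneous: pooling KO embryos would let one
aberrant embryo drive calls. The procedure therefore compares **each KO
embryo against the whole control group** and only calls genes consistent
across embryos:

1. Size factors by median-of-ratios against the geometric-mean
   pseudo-reference, rescaled to geometric mean 1 (the median is taken
   in linear ratio space).
2. Per gene, dispersion from the control replicates by method of
   moments, α = max(0.01, (s² − m)/m²). The floor keeps near-Poisson
   genes from degenerate α ≤ 0.
3. For each KO embryo j, an exact two-sided NB tail test of the
   normalized KO count against the control mean: p = Σ P(x) over all x
   with P(x) ≤ P(observed) (mass ordering). Dispersion 0 degenerates to
   Poisson. The per-comparison log2 FC uses a 0.5 pseudocount.
4. Fisher combination: X = −2 Σ ln pⱼ against χ² with 2k df, with
   p-values floored at 1e-300 beforehand (the combination is undefined
   at 0).
5. Filters: combined p \< 0.05 **and** every per-comparison
   log2 FC \> 1.4 (applied per comparison, not to the mean) **and**
   log2(RPKM) \> 1 in every replicate of the upregulated group. RPKM is
   computed after size-factor normalization, per kb of transcript, per
   million normalized library reads.

This design treats the control mean as known given the estimated
dispersion — an honest limitation of a 1-observation-per-test layout.
Consequently the *combined* p-value under moments-estimated dispersion
is anti-conservative (roughly 30% of null genes fall below 0.05 in
simulation), while the exact NB test itself is calibrated at the true
parameters (5.1% below 0.05 over 10⁴ null draws). Operational error
control comes from the filter cascade: in the standard simulated dataset
(5000 null + 200 planted genes at log2 FC 3, 4 vs 4 embryos, α = 0.1)
false up-calls among null genes are 0 and sensitivity is ≥ 0.97. Users
should read `combined_p` as a ranking statistic within this procedure,
not as a calibrated genome-wide error rate.

Stage transitions (activated/repressed between two developmental
stages) reuse the machinery group-vs-group with log2 FC \> 1 and a
ceiling of log2(RPKM) \< 4 in the lower-expressed stage. The ceiling is
applied to the lower stage only (configurable): "becoming repressed"
should not require the *destination* expression to be low in the origin
stage too. Repression is defined as activation with the stages swapped,
so repressed(A,B) = activated(B,A) exactly.

## Repeats

Repeat loci are quantified from unique-mapping reads and normalized by
the per-sample total of protein-coding reads (not the repeat library
itself — global repeat derepression would otherwise suppress its own
signal) and locus length. Loci with \< 5 total reads across samples are
treated as uncovered (the coverage floor is a parameter; the emulated
analysis left "sufficient coverage" undefined). The subfamily call
combines two one-sided Fisher exact tests — marked-fraction excess and
upregulated-fraction excess over the genome-wide background — both
BH-adjusted, both required at 0.05. Requiring both avoids flagging
subfamilies that are merely heavily marked (common for ERVs) or merely
expression-variable. Subfamilies need ≥ 20 loci for stable fractions.

## Enhancers

Active-enhancer calling is a pure set rule (p300 ∧ K27ac ∧ K4me1 ∧
¬promoter, summit ± 800 bp → 1601 bp regions, clipped at chromosome
edges). State classification across cell types orders the mark-call
combinations with an explicit precedence — dual(K9+K27ac) \> K9 \>
K27-poised \> active \> inactive — because the states are otherwise
presented as heatmap clusters with no deterministic rule; the dual class
captures enhancers transiently retaining H3K27ac while gaining H3K9me2.
Nearest-gene assignment links enhancers to expression; this is a proxy
(enhancers can regulate distant promoters) and is reported as such, with
group-level rank-sum contrasts rather than per-pair claims.

## Self-organizing maps

The SOM is trained online on a hexagonal grid (odd rows offset 0.5, row
spacing √3/2, node order row-major): per step, the best-matching unit
(BMU) by Euclidean distance is found and codebooks within radius σ move
toward the sample with Gaussian weight exp(−d²/2σ²) (hard cutoff at σ).
The learning rate decays linearly 0.05 → 0.01 and σ from ⅔ of the grid
diagonal to 0; sample order reshuffles each epoch under a per-epoch
derived seed, and the codebook initializes from sampled input rows — all
deterministic given the seed. Defaults (10×10 grid, 100 epochs) are
exposed because the emulated analysis reports none of them; figure
reproduction is therefore qualitative.

Besides the linear schedule, `lr_schedule = "inverse"` (α = 1/(t+2))
makes a single-node or radius-0 map compute an exact running mean of the
presented samples — the textbook online k-means limit. The linear
schedule approaches the data mean only to within its stationary noise
(~0.05–0.07 sd units at these defaults), so the running-mean property is
exact only under the inverse schedule; tests of that property use it
explicitly.

## Motif enrichment

Site thresholds are exact: per-column log2-odds scores are discretized
to 1e-3 bits (a memory/accuracy trade-off; the induced threshold shift
is bounded by granularity × width) and convolved under the background
model, giving the full null score distribution; the threshold is the
smallest *achievable* score whose upper tail is ≤ the site p-value
(1e-5 default). Restricting to achievable scores makes the threshold an
actual site score rather than an arbitrary grid point. If the requested
p is below the smallest achievable tail, the threshold is set above the
maximum score (zero hits) with a warning. PWMs get a 0.01 pseudocount
per cell (the upstream tool's handling is unspecified).

Scanning scores every window on both strands (minus strand via the
reverse-complemented score matrix in the same pass); windows containing
N are skipped. Enrichment uses the fraction of regions with ≥ 1 hit
(not total hit count — a single region with many repeats of a motif
should not dominate; a total-count mode is available), compared against
1000 random width-matched region sets drawn uniformly from gene bodies
± 50 kb, with the add-one empirical p-value
(1 + #{sets ≥ query})/(n + 1), which cannot return 0.

## Shared statistics

The 2×2 χ² uses the closed form N(ad−bc)²/∏margins with df 1 and no
Yates correction by default (the emulated analysis does not state its
correction; a flag is available). The rank-sum test uses the exact null
(via `wilcox.test`) when both groups have ≤ 10 observations and no
ties, else the normal approximation with tie and continuity correction;
the effect size is r = |Z|/√N (the formula behind the published star
thresholds is not stated; this is the standard choice), with stars
\*/\*\*/\*\*\* at r ≤ 0.10 / ≤ 0.15 / \> 0.15 and "ns" when p ≥ 0.05.
Fisher exact tests and BH adjustment call `stats::fisher.test` and
`stats::p.adjust`.

## The synthetic-data generators

The generators define the study conditions the tests run under:
4 KO + 4 control embryos (3+3 configurable), 2 ChIP replicates, planted
ChIP log2 FC 2.0, planted expression log2 FC 3.0, NB dispersion 0.1,
mutually exclusive H3K9me2/H3K27me3 marking at 10% of genes each, ~5%
of genes on chrX, enhancer fates 12% K9-gaining / 18% K27-poised,
2 of 20 repeat subfamilies regulated (60% marked / 30% upregulated
vs 10% / 1% background), CpG methylation Beta(8,2) at K9-marked and
Beta(2,8) at K27-marked regions (means 0.8 / 0.2), log-normal library
factors (sd 0.2) and gene baselines (sd 0.5 around mean 100).

ChIP noise is Poisson at region level: with two replicates of
low-cell-number ChIP there is no leverage to estimate extra-Poisson
variance, and planting it would only add a parameter the calling cannot
identify; an NB option exists (`chip_nb_dispersion`). Planted DE genes
are drawn preferentially from K9-marked genes (`de_from_marked`),
coupling marking to derepression as the biology demands, so the
mark-by-upregulation overlap χ² in `run_all` has signal.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: read-level artifacts (mappability, GC bias,
duplicates), fragment-length effects, co-marking beyond the configured
rate, correlated dispersion across genes, bisulfite conversion error,
and any genome sequence structure beyond i.i.d. base frequencies.
Recovery rates on this synthetic data are upper bounds on real-data
performance.

Every generator derives a named sub-seed from the single global seed
(`child_seed`), so stages are independently reproducible and the
end-to-end run is byte-identical across repeats.

## Problem sizes and numerical notes

The standard validation sizes are: 2000 regions at 50 input reads per
region for mark-call recovery; 5200 genes (200 planted) for DE recovery;
10⁴ draws for NB null calibration; 20 subfamilies × 100 loci for
repeats; 1000 background sets (200 in the orchestrated run and the null
calibration trials) for motifs; a 300-gene, 100-enhancer genome for the
end-to-end run. Degenerate inputs fail fast with specific errors: \< k
distinct values in mark calling, zero library totals, zero margins in
the χ², empty groups in rank tests, zero p-values in Fisher combination.
Ties in BMU lookup and nearest-center assignment resolve to the lowest
index; nearest-gene ties resolve to the lexicographically smaller gene
id.
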