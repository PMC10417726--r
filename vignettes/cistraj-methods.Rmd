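---
title: "Methods and design of the cistraj pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the cistraj pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistraj)
```

# The study design this package models

cistraj analyzes bulk RNA-seq count matrices from staged tumor-initiation
studies in lineage-traced mouse models: two genotypes (a wild-type arm and a
conditional knockout arm), tumors and age-matched tumor-free glands sampled
at 6, 8, 10 and 12 weeks, with three tumor and two tumor-free replicates per
genotype-timepoint. Cells are sorted on a Cre-switchable dual-fluorescence
reporter (membrane tdTomato before recombination, membrane GFP after), so
the reporter transcripts double as count-level quality controls, as does the
loxP-flanked exon of the conditionally deleted gene: a cleanly recombined
knockout sample carries no reads on that exon, and a sample that does is a
recombination escapee.

The pipeline runs, in order: count-level QC, prefiltering, median-of-ratios
normalization, a stage-matched negative-binomial Wald test per timepoint and
genotype, DEG set algebra across timepoints, k-means clustering of temporal
expression trajectories, genotype-exclusivity partitioning, preranked
gene-set enrichment and hypergeometric over-representation, and finally a
genomic-window-plus-correlation screen that nominates cis-regulating
lncRNA/protein-coding gene pairs. Every stage is also exposed as an exported
function.

# Differential expression

## Model

Counts are modeled as negative binomial with variance
$\mu + \alpha\mu^2$. For one contrast (tumor vs age-matched tumor-free
within one genotype and timepoint) the condition means are estimated with
size-factor offsets, $\hat\mu_c = \sum_j K_{gj} / \sum_j s_j$, where the
$s_j$ are median-of-ratios size factors. The reported effect is

$$\widehat{\mathrm{log_2FC}} = \log_2\frac{\hat\mu_T + \varepsilon}
{\hat\mu_F + \varepsilon}, \qquad \varepsilon = 0.5$$

normalized counts, which keeps the fold change bounded for all-zero
conditions. The Wald statistic divides this by its delta-method standard
error and is referred to a standard normal, two-sided; Benjamini-Hochberg
adjustment runs over all tested genes.

## Dispersion: why a trend across genes

With three versus two replicates, a per-gene method-of-moments dispersion
estimate has about three degrees of freedom. Plugging such an estimate into
a Wald statistic with a normal reference inflates the type-I error roughly
threefold (we measured a null $p<0.05$ fraction of ~0.14); switching to a
Student-t reference with the residual degrees of freedom restores
calibration but leaves the test so weak that moderate true effects can
never clear an FDR threshold inside a 2000-gene matrix. Neither extreme is
usable, which is exactly why every serious count-model package shares
dispersion information across genes.

cistraj uses the minimal such device: genes are ranked by base mean, cut
into bins of at least ~50 genes, and each gene receives its bin's average
method-of-moments estimate ("mean-binned dispersion trend"), clamped to
$[10^{-8}, 10]$. Because the trend is estimated from thousands of
observations it is nearly noise-free, so the normal reference is honest
again: on a null simulation at the study's design (2000 genes, $n = 3$ vs
$2$, $\alpha = 0.1$) the raw $p<0.05$ fraction is 0.05-0.06, and planted
$\mathrm{log_2FC} = 2$ effects at base mean 100 are recovered essentially
completely. The cost is that gene-specific departures from the
mean-dispersion trend are not modeled: a single gene that is far more
variable than its expression peers will be anti-conservative. No shrinkage
of fold changes, no outlier replacement and no independent filtering are
performed.

## Thresholds

DEG calling uses strict inequalities, with the fold-change threshold on the
linear scale by default (`fold change > 1.5` means
$|\mathrm{log_2FC}| > \log_2 1.5$); an alternative reading that applies the
threshold to the log2 value directly is available via
`call_degs(..., lfc_scale = "log2")`. Two threshold sets are used by the
pipeline: stagewise DEG counting at fold change 1.5, FDR 0.1, and the
temporal-clustering input (hyperplasia-stage DEGs) at fold change 2,
FDR 0.1.

# Temporal clustering

## Stage alignment

The wild-type arm reaches hyperplasia, adenoma and carcinoma at weeks
6/8/10; the knockout arm, with its delayed initiation, at weeks 8/10/12.
Profiles from the two genotypes are therefore aligned by *stage order*
(first, second, third tumor timepoint), not by absolute week, and the union
of both genotypes' hyperplasia DEGs is clustered jointly, one row per
(gene, genotype).

## Profile scaling

Rows are transformed as $\log_2(\bar x + 1)$ and mean-centered before
clustering (`scaling = "center_log2"`), which removes each gene's baseline
while preserving the shape *and amplitude* of its trajectory. Full
z-scoring is offered but is not the default, for a concrete reason: the
"early drop, maintained low" archetype is essentially flat across tumor
stages, so dividing by the row SD amplifies pure measurement noise into a
random shape (and an exactly flat row has no z-score at all), making that
archetype unrecoverable. Mean-centering keeps flat-low trajectories near
the origin where they form a coherent cluster.

## Algorithm

Lloyd's algorithm with k-means++ seeding, best of `n_init = 25` restarts by
total within-cluster sum of squares, at most 300 iterations, centroid
movement tolerance $10^{-6}$; an empty cluster is re-seeded at the point
farthest from its centroid. The fit is deterministic given the seed, and
the test suite checks the restarted optimum against `stats::kmeans` with
many restarts and against exhaustive enumeration on tiny instances. With
$K = 3$ the arbitrary k-means labels are renamed to the field's archetypes
by centroid trend: most negative stage trend = early peak then decay (1),
most positive = sustained rise (2), intermediate = early drop / flat low
(3). The elbow curve (`elbow_curve()`) reports the total within-SS across a
K range; the analysis design selects $K = 3$.

# Enrichment

`enrichment_score()` is the weighted Kolmogorov-Smirnov running sum: a set
member at rank $i$ adds $|m_i|^w / \sum_{hits}|m|^w$, a non-member subtracts
$1/(N - N_{hits})$, and the score is the signed maximal deviation (an exact
positive/negative tie resolves to the positive side so the statistic does
not depend on floating-point accumulation order). With $w = 0$ this is the
classic unweighted KS statistic. Significance uses *gene-set permutation* —
random member sets of equal size drawn from the ranked universe — because
phenotype permutation is meaningless at $n = 3$ vs $2$. The normalized
score divides by the mean absolute null score of matching sign, and the
p-value is two-sided and empirical with add-one correction,
$p = \min\!\big(1,\, 2(1 + \#\{\text{sign-matched } |ES^\ast| \ge |ES|\})
/(1 + n_{perm})\big)$, so the smallest attainable p at 1000 permutations is
$2/1001 \approx 0.002$. The ranking metric defaults to the Wald statistic
(variance-aware); signed log2 fold change is available.
Over-representation of a query list against a collection uses the
upper-tail hypergeometric test with BH correction across sets.

# The cis-regulation screen

A candidate pair is a lncRNA and a protein-coding gene on the same
chromosome within 500 kb (span gap, inclusive boundary; gap 0 for
overlapping spans; start-to-start and strand-aware TSS-to-TSS anchors are
options) whose $\log_2(\text{normalized}+1)$ expression correlates at
$r \ge 0.80$ with correlation $p < 0.01$ (Pearson; two-sided t test on
$n-2$ df). Every evaluated pair is returned with its three flags; the
report is the subset passing all three, sorted by descending $r$.

Two scope decisions deserve explanation:

* **Samples entering the correlation.** The default correlates over *all*
  samples of the experiment. The degrees of freedom implied by published
  pair p-values in this analysis design (e.g. $r = 0.91$ with
  $p \approx 10^{-13}$ requires $n \approx 32$) show that the correlations
  are computed across the full sample set, not within one genotype's
  tumors; a restricted scope remains available through `screen_config()`.
* **DEG input.** The pipeline screens the hyperplasia-stage DEG lists of
  the wild-type arm split by biotype. Restricting to genotype-exclusive
  DEGs (the exclusivity partition is computed and reported in any case) is
  fragile as a *screen input*: one false-positive knockout DEG silently
  ejects a true pair. Users wanting the exclusive-only screen can pass the
  partition's gene lists to `screen_pairs()` directly.

# The synthetic-data generator

`sim_config()` declares the full study design (40 samples), a toy genome
(five 10-Mb chromosomes), NB counts with dispersion $\alpha = 0.1$,
log-normal library-size multipliers, the GFP-high/mTd-near-zero reporter
pattern of sorted GFP+ cells, a floxed-exon feature that is zero in all
knockout samples except declared escapees, and planted structure with a
recoverable answer key: three temporal archetypes, genotype-exclusive
effects (the knockout arm sees each trajectory one timepoint late, modeling
delayed initiation), and cis pairs placed with a span gap uniform on
[0, 500 kb].

## Planted trajectories and the noise floor

At three replicates and $\alpha = 0.1$, the standard deviation of a stage
mean on the log2 scale has a floor of about
$\log_2(e)\sqrt{\alpha/3} \approx 0.26$ regardless of expression level —
shot noise that no baseline can buy off. The planted archetype amplitudes
were therefore chosen by a design-time power analysis so that (i) each
archetype's hyperplasia $|\mathrm{log_2FC}|$ clears the fold-change-2 input
threshold with a comfortable Wald margin, and (ii) the three mean-centered
log2 stage shapes are separated by several multiples of that noise floor:

| archetype | log2FC at weeks 6/8/10/12 (WT) |
|---|---|
| 1 early peak, decay | 2.4, 1.0, 0.3, 0.1 |
| 2 sustained rise | 1.3, 2.4, 3.0, 3.1 |
| 3 early drop, stays low | -2.0, -2.2, -2.3, -2.3 |

Planted DE genes draw baselines from the upper expression range, emulating
detectable tumor drivers. These are generator constants, fixed once;
scientists wanting weaker planted signal can scale `planted_lfc`.

## Planting the pair correlation

A naive way to plant $r \approx 0.9$ between two genes is a large shared
per-sample latent factor — but the shared variance required
($r/(1-r)\cdot v$, with $v$ the per-gene measurement variance of log2
counts) is an order of magnitude larger than the NB noise, and it lands
inside each condition, destroying the very differential expression the
screen must detect. The generator instead lets the correlation ride the
*shared tumor trajectory*: it computes the trajectory's variance across the
design analytically, scales the pair's amplitude up (capped at 1.5x) if
that shared variance falls short of the requirement, tops up any remainder
with a shared latent factor, and adds a small independent per-gene jitter
when the trajectory overshoots, so that the expected correlation hits the
target from either side. Cis pairs use a high-amplitude sustained-rise
trajectory (log2FC 2.6 to 4.2) that satisfies the DE margin, the clustering
amplitude and the correlation variance simultaneously.

## What the generator does not emulate

Single fixed dispersion (no mean-dispersion relationship, no per-gene
dispersion outliers), no batch effects beyond library size, no unbalanced
or missing samples, no gene-length effects, no correlated background
structure between non-paired genes, and counts drawn independently across
genes given the planted structure. Passing tests on this generator
demonstrate the pipeline's statistical machinery (calibration, recovery,
exactness against oracles, determinism); they do not certify performance on
real libraries, where dispersion heterogeneity and hidden covariates are
the dominant hazards.

# Numerical and reproducibility choices

* All internal coordinates are 0-based half-open; GTF I/O converts at the
  boundary. The 500-kb window is inclusive.
* Size factors: median of count/geometric-mean ratios over genes with no
  zero count; a single sample gets factor 1.
* Ties in gene ranking break lexicographically by gene id; k-means ties in
  assignment take the first centroid; the ES extreme prefers the positive
  side on exact ties.
* One global seed fans out to per-stage seeds by fixed offsets, so a rerun
  of the pipeline at the same seed is byte-identical, while stages remain
  individually reproducible.
* Default problem sizes (2000 genes, 40 samples, 1000 permutations, 25
  k-means restarts) were chosen as the smallest sizes at which the
  statistical properties above are comfortably measurable; the full test
  suite and the acceptance script run in about a minute.

# Known limitations

The Wald test trusts the mean-binned dispersion trend; datasets with strong
per-gene dispersion outliers need a heavier estimator (shrinkage toward a
trend with gene-wise components). The exclusivity partition inherits the
noise of both genotypes' DEG calls at FDR 0.1. Gene-set permutation
p-values test a different null than phenotype permutation and are known to
be liberal for strongly correlated sets. The screen's correlation is
marginal Pearson on log counts: it nominates, and cannot by itself
establish, cis-regulation.
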