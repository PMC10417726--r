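# cistraj

Stage-matched differential expression, temporal trajectory clustering and
cis-lncRNA screening for lineage-traced tumor RNA-seq.

## What problem this package addresses

Mouse studies of tumor initiation often sample tumors and age-matched
tumor-free glands from two genotypes (wild type and a conditional knockout)
across several timepoints, with very few replicates, from cells sorted on a
Cre-switchable fluorescence reporter. The questions such a design can
answer — which genes drive the hyperplasia stage, how their expression
evolves through adenoma and carcinoma, how the knockout's delayed
initiation reshapes those programs, and which differentially expressed
lncRNAs sit within cis-regulatory reach of co-expressed protein-coding
genes — require a chain of analyses that is usually assembled ad hoc.
cistraj packages that chain as tested, reusable functions plus a one-call
pipeline, and ships a synthetic-data generator that reproduces the full
statistical structure of the design (negative-binomial counts, reporter
spike-ins, a floxed-exon feature, planted temporal archetypes and planted
cis pairs) so every stage can be validated against a known answer key.

## The statistics at its core

* **Differential expression.** Per gene, counts are NB with variance
  $\mu + \alpha\mu^2$; condition means use median-of-ratios size-factor
  offsets; $\log_2\mathrm{FC} = \log_2\frac{\hat\mu_T + 0.5}{\hat\mu_F + 0.5}$;
  the Wald statistic $\log_2\mathrm{FC}/\mathrm{se}$ uses a delta-method
  standard error with a mean-binned dispersion trend across genes
  (calibrated at n = 3 vs 2, where per-gene plug-in estimates are not),
  standard-normal two-sided p, Benjamini-Hochberg FDR. DEGs: fold change
  > 1.5 (stagewise) or > 2 (clustering input), FDR < 0.1, strict.
* **Temporal clustering.** Mean expression trajectories over tumor stages
  (stage-aligned across genotypes: WT weeks 6/8/10, KO 8/10/12), k-means
  (k-means++ seeding, best of 25 restarts, deterministic by seed) on
  row-centered log2 profiles, with an elbow diagnostic; K = 3 clusters map
  to early-peak, sustained-rise and early-drop archetypes.
* **Enrichment.** Preranked GSEA (weighted running-sum enrichment score,
  gene-set permutation null, sign-matched NES, add-one two-sided empirical
  p, BH across sets) and hypergeometric over-representation.
* **Cis screen.** A lncRNA and a protein-coding gene on the same chromosome
  within 500 kb (span gap, inclusive) whose log2 normalized expression has
  Pearson $r \ge 0.80$ with correlation $p < 0.01$ (t on n-2 df).

See `vignettes/cistraj-methods.Rmd` for assumptions, parameter rationale
and limitations.

## Worked example

Generate a synthetic study and run the whole pipeline:

```r
library(cistraj)
dir <- file.path(tempdir(), "demo")
export_fixture(sim_config(seed = 7, n_escapees = 2), dir)
cfg <- pipeline_config(
  counts      = file.path(dir, "counts.tsv"),
  samples     = file.path(dir, "samples.tsv"),
  annotation  = file.path(dir, "annotation.gtf"),
  gmt         = file.path(dir, "sets.gmt"),
  exon_counts = file.path(dir, "exon_counts.tsv"),
  out_dir     = file.path(dir, "results"), seed = 7)
report <- run_pipeline(cfg)
print(report)
```

```
cistraj run report (seed 7)
  DEGs per contrast:
    WT: wk6=122, wk8=97, wk10=84
    KO: wk8=61, wk10=54, wk12=42
  timecourse input: WT=122 KO=61
  cluster sizes: 1=56, 2=53, 3=74
  WT-exclusive DEGs: 81 (15 lncRNA)
  cis pairs: 53 evaluated, 15 reported
```

Reading it: each contrast line counts DEGs for tumor vs age-matched
tumor-free at that week (the knockout arm is tested one stage later,
matching its delayed initiation); `timecourse input` are the
hyperplasia-stage DEGs (fold change > 2) that feed the K = 3 temporal
clustering; `WT-exclusive DEGs` are clustered genes absent from the
knockout's DEG input, split by biotype; and the cis screen evaluated 53
lncRNA-PCG window pairs, of which 15 passed the r >= 0.80, p < 0.01 gates.
The top of `results/pairs.tsv`:

```
    lncRNA protein_coding_gene      PCC     p_value distance_bp n_samples
  LNC00047            PCG00602 0.935645 8.89911e-19      392080        40
  LNC_CIS1            PCG_CIS1 0.928154 6.74790e-18       94677        40
  LNC_CIS4            PCG_CIS4 0.921323 3.56743e-17       61877        40
```

`LNC_CIS*`/`PCG_CIS*` are the generator's planted cis pairs — all five are
recovered — alongside decoy pairs that genuinely co-vary by construction of
the shared tumor trajectories. Other stage outputs (`de_*.tsv`, `qc.tsv`,
`clusters.tsv`, `gsea.tsv`, `ora.tsv`, `run_report.yaml`) land in the same
directory, and a rerun at the same seed is byte-identical.

A thin command-line wrapper with `simulate`, `qc`, `de` and `run-all`
subcommands is installed at `exec/cistraj` inside the package.

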