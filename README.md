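# loopgene

Linking GWAS risk loci to candidate target genes through H3K27ac HiChIP
chromatin loops.

## The problem

Most disease-associated variants found by GWAS fall in non-coding,
regulatory sequence, and the gene they perturb is often *not* the nearest
one: enhancers reach their targets through chromatin loops that can skip
genes and span hundreds of kilobases. H3K27ac HiChIP assays the active
chromatin interactome — loops whose anchors carry the acetylation mark of
active enhancers and promoters — and therefore provides direct, cell-type
specific evidence connecting a risk variant to the promoter it contacts.

`loopgene` implements that variant-to-gene assignment as a tested,
reusable pipeline, for statistical geneticists and regulatory genomicists
who have significant-interaction calls (FitHiChIP-style BEDPE), H3K27ac
peaks, a gene annotation, an expression table, and a table of lead SNPs
with their LD proxies.

## The method

For every variant *v* of a locus (a lead SNP plus proxies with
r² ≥ 0.8 by default) and every transcript TSS *t* (protein-coding, from a
Gencode-style GTF, strand-aware):

* **loop evidence** — *v* lies inside one loop anchor and
  d(*t*, other anchor) ≤ 5 kb, where d(·,·) is the base-pair distance
  from a point to a half-open interval (0 inside);
* **promoter evidence** — *v* overlaps an H3K27ac peak and
  |*t* − *v*| ≤ 1 kb.

Transcript hits are grouped by gene, and genes are kept when expressed at
≥ 1 TPM in the cell type that supplied the evidence. The package also
computes the statistics used to characterize such datasets: loop-distance
distributions (lower-median of anchor-midpoint distances), the fraction
of loops contained within TADs, replicate loop-set concordance (binned
Jaccard), interactions per gene, per-locus eQTL concordance (recall and
precision of linked genes against eQTL-supported genes), closest-gene
classification for narrow LD blocks, gene-desert detection (no
protein-coding TSS within 50 kb of the LD block), and a permutation test
for GWAS-SNP enrichment in peaks.

A seeded synthetic-genome generator (`simulate_dataset()`) emits a
coherent toy dataset — TADs, genes, peaks, loops, loci, expression, eQTLs
— together with its ground-truth locus→gene map, so the entire pipeline
is testable end to end without downloads.

## Worked example

```r
library(loopgene)

ds  <- simulate_dataset(simulation_config(seed = 7), "sim")
cfg <- list(
  inputs = list(
    loops = list(list(path = "sim/loops_kc_unstim.bedpe", sample_id = "kc_unstim"),
                 list(path = "sim/loops_kc_stim.bedpe",   sample_id = "kc_stim")),
    peaks = list(list(path = "sim/peaks_kc_unstim.narrowPeak", sample_id = "kc_unstim"),
                 list(path = "sim/peaks_kc_stim.narrowPeak",   sample_id = "kc_stim")),
    gtf = "sim/genes.gtf", expression = "sim/expression.tsv",
    snps = "sim/gwas_snps.tsv", tads = "sim/tads.bed",
    eqtl = "sim/eqtl.tsv", background_snps = "sim/background_snps.tsv"),
  seed = 7)
res <- run_pipeline(cfg, "run")

res$link_table
#> <link_table> 237 evidence rows (237 expressed), 40 loci, 157 genes
str(res$stats[c("loop_distance", "tad", "eqtl")])
#> $ loop_distance:List of 2
#>  ..$ median: num 260000
#>  ..$ mean  : num 342605
#> $ tad          :List of 3
#>  ..$ n_within       : int 907
#>  ..$ n_crossing     : int 99
#>  ..$ fraction_within: num 0.902
#> $ eqtl         :List of 5
#>  ..$ recall   : num 0.787
#>  ..$ precision: num 0.716
#>  ..
```

The numbers mean: the 1,006 simulated loops have a lower-median
anchor-midpoint distance of 260 kb; 90.2% of them are fully contained in
a single TAD; of the eQTL-supported locus–gene pairs, 78.7% are recovered
by the linker (recall), and 71.6% of the linked, expressed genes are
eQTL-supported (precision — the quantity sometimes reported as
"specificity"). `run/link_table.tsv` holds one auditable evidence row per
(locus, gene, evidence type, sample), including the rows that failed the
expression filter (`expressed = 0`).

A thin command-line wrapper is installed under `inst/cli/loopgene.R`
(subcommands `simulate`, `link`, `run`; exit codes 0/2/3 for
success/config error/data error).

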