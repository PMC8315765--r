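---
title: "Linking GWAS loci to target genes with H3K27ac HiChIP loops: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking GWAS loci to target genes with H3K27ac HiChIP loops: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopgene)
```

## The model

GWAS risk variants mostly land in regulatory sequence, and the affected
gene is frequently not the nearest one: enhancers act on promoters
through chromatin loops. H3K27ac HiChIP calls significant contacts
between active regions, so a loop whose one anchor covers a risk variant
and whose other anchor sits at a promoter is direct evidence for a
variant→gene assignment in that cell type.

`loopgene` encodes this as two evidence rules applied to every variant
*v* of a locus (lead SNP plus LD proxies) and every transcript start
site *t*:

1. **Loop rule.** *v* lies inside one anchor of a significant loop
   (distance 0; a configurable variant-side tolerance
   `snp_anchor_window` defaults to 0), and
   d(*t*, other anchor) ≤ `loop_window` (5 kb). When *v* sits in both
   anchors — short loops, wide anchors — both directions are evaluated.
2. **Promoter rule.** *v* overlaps any H3K27ac peak of the same sample
   and |*t* − *v*| ≤ `promoter_window` (1 kb). The peak does not have to
   be a loop anchor: occupancy at the variant plus immediate proximity
   to a promoter is evidence on its own.

Here d(·,·) is `point_interval_distance()`: 0 inside the half-open
interval, distance to the nearest retained base otherwise. Transcript
hits are collapsed to gene level — one row per (locus, gene, sample,
loop) — and a gene is *reported* for a locus when at least one of its
evidence rows comes from a sample where the gene is expressed at
`tpm_threshold` (1 TPM, inclusive) or more. Rows that fail the filter
are retained with `expressed = FALSE`, so the filter's effect is always
auditable; every reported count uses expressed rows only.

### Assumptions

* Loop files are *pre-filtered significant interactions* (FitHiChIP-like
  output). No significance re-thresholding happens at ingest unless a
  score column and threshold are passed explicitly, in which case the
  column is treated as a q-value (keep `score <= threshold`).
* Anchors are interval-resolution evidence: containment of the variant
  is what makes an anchor "the variant's side". The 5 kb TSS window
  absorbs anchor-resolution uncertainty on the promoter side.
* Expression is matched by sample: stimulated and unstimulated
  conditions are distinct `sample_id`s, and the ≥ 1 TPM filter uses the
  sample that supplied the evidence row.
* Genes absent from the expression table are treated as not expressed
  (conservative), with the count logged.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `loop_window` | 5,000 | bp | TSS-to-opposite-anchor distance, inclusive |
| `promoter_window` | 1,000 | bp | TSS-to-variant distance, inclusive |
| `tpm_threshold` | 1.0 | TPM | expressed-gene filter, inclusive (1.0 passes) |
| `r2_threshold` | 0.8 | r² | proxy inclusion, inclusive by default |
| `block_width_cutoff` | 100,000 | bp | closest-gene report restricted to blocks strictly narrower |
| `gene_desert_window` | 50,000 | bp | desert = no protein-coding TSS within this distance of the block |
| `snp_anchor_window` | 0 | bp | variant-side anchor tolerance |

Boundary semantics are fixed and tested: "within N kb" is inclusive
(distance exactly N·1000 links; N·1000 + 1 does not), "at least 1 TPM"
is inclusive (TPM 1.0 passes, 0.999 fails), "smaller than 100 kb" is
strict (99,999 is small, 100,000 is not), and the 50 kb gene-desert rule
is an exclusive lower bound on the minimum distance (a TSS at distance
exactly 50,000 prevents desert status).

Two conventions were genuinely open and are resolved as configurable
defaults: the r² cutoff is applied inclusively (`>=`), with a `strict`
flag for catalogs that mean `>`; and the variant-side loop test demands
strict containment (`snp_anchor_window = 0`), since anchor-sized bins
already buffer positional noise on that side.

## Statistics

* **eQTL concordance** (`eqtl_validation`): per-locus matching of linked
  genes against eQTL-supported genes. *Recall* = matched / eQTL pairs;
  *precision* = matched / linked pairs. The quantity some reports call
  "specificity" is a precision — the fraction of linked genes with eQTL
  support — not a true-negative rate, so the field is named `precision`
  and printed with both labels. A global-union mode exists
  (`per_locus = FALSE`) for comparison.
* **TAD containment** (`tad_overlap_stats`): a loop is *within* iff a
  single TAD fully contains both anchors; everything else, including
  loops spanning inter-TAD gaps, is *crossing*. Overlapping TADs are a
  data error, not silently tolerated.
* **Distances** (`loop_distance_stats`): anchor midpoints
  (`floor((start+end)/2)`), absolute difference, intra-chromosomal loops
  only; the median is the lower median for even counts so the statistic
  is always a realized loop distance.
* **Interactions per gene** (`interactions_per_gene`): loops with any
  anchor within 5 kb of any TSS of the gene, counted once per gene;
  the mean includes zero-count genes.
* **Replicate concordance** (`loop_set_concordance`): anchors snapped to
  a 5 kb grid; Jaccard over binned loop sets.
* **SNP-in-peak enrichment** (`snp_peak_enrichment`): the observed
  in-peak fraction against resampling of equally many background
  variants without replacement; fold = observed / null mean; p-value by
  the add-one estimator `(1 + #{null >= obs}) / (n_perm + 1)`, which is
  never zero and keeps the test conservative (super-uniform under the
  null). If no background resample ever lands in a peak the fold is
  reported as `Inf` with a `degenerate` flag rather than failing.

## Numerical and representational choices

All internal coordinates are 0-based half-open (BED convention). The two
1-based dialects the pipeline meets — GTF features and SNP tables — are
converted exactly once, at ingest. Interval work is done with
`data.table` non-equi joins so a single coordinate convention flows
through the whole package; `rtracklayer` handles GTF parsing (including
gzip and the `gene_type`/`gene_biotype` attribute drift between Gencode
and Ensembl). Chromosome names are normalized by stripping the `chr`
prefix for comparisons only; files round-trip with their original names.

Ties in the closest-gene search are kept: every gene at the minimal
distance belongs to a locus's closest-gene set, and the per-locus
classification (`all`/`some`/`no_closest_linked`) intersects that set
with the locus's reported genes. Degenerate inputs fail loudly with
typed conditions: an empty TSS annotation is a configuration error
(distinct from legitimately zero links), an empty eQTL table makes
recall undefined and errors, zero intra-chromosomal loops error in the
distance statistics.

Deduplication keys follow the evidence model: loop rows are unique per
(locus, gene, sample, loop), promoter rows per (locus, gene, sample);
the surviving representative variant is the one with the smallest
distance. Genes-per-locus is reported as two means — over loci with at
least one gene and over all loci — because "average genes per locus" is
ambiguous between the two; both are emitted.

## The synthetic data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes: TADs tiling each chromosome; genes (1–3 transcripts each,
strand-aware TSS) and enhancers occupying alternating 20 kb slots;
H3K27ac peaks at expressed promoters and at every enhancer plus random
background peaks; enhancer–promoter truth loops whose TAD membership is
Bernoulli(`fraction_within_tads` = 0.9) and whose anchor distances
follow a gamma target (shape 2, scale 149 kb, median ≈ 250 kb — typical
of significant H3K27ac HiChIP interactions); GWAS loci whose lead SNP
sits in a truth enhancer, with LD proxies scattered ±4 kb; eQTL sets
derived from the truth map with dropout (0.3) and spurious additions
(Binomial(4, 0.25) per locus), emulating partial concordance between
chromatin and eQTL evidence; and a handful of gene-desert loci whose
lead enhancers sit in designated gene-free TADs and reach their targets
only through TAD-crossing loops.

The slot geometry is what makes truth recovery exact: the 20 kb pitch
exceeds every linking window plus anchor half-width, so on noise-free
data (no noise loops, no eQTL noise) the pipeline's reported links equal
the emitted truth set exactly — recall and precision 1 — which is the
package's strongest correctness check. Loop distances are realized by
matching each gamma draw to the nearest available enhancer–gene
distance, so the empirical distribution is the target quantized to the
slot geometry; the realized median runs somewhat above the gamma's
(≈ 260–300 kb), which is accepted and documented rather than tuned away.
Duplicate (enhancer, gene) pairs can repeat among the sampled loops and
are kept, preserving the configured loop count and the per-loop
Bernoulli TAD fraction.

All randomness flows from one master seed through per-component
substreams (genes, enhancers, truth loops, loci, expression, noise
loops, background SNPs, eQTLs, peaks — in that order), so adding an
output never perturbs earlier draws and the same configuration yields
byte-identical files.

What the generator does *not* emulate: read-level HiChIP noise,
anchor-size variability, correlated peak signal, realistic LD structure
(r² values are drawn uniformly, not from haplotypes), overlapping gene
models, or inter-chromosomal contacts. Passing tests therefore
demonstrate the correctness of the interval logic, grouping, filtering
and statistics — not robustness to every artifact of real HiChIP data.

## Problem sizes

The test suite exercises each linking operation against brute-force
exhaustive oracles on 100+ random instances of a few hundred features
each; generator-parameter recovery uses 10,000 loops (binomial standard
error ≈ 0.003 on the TAD fraction); permutation calibration uses 500
null datasets at 199 permutations each. These sizes give tight
statistical checks while the whole suite runs in about a minute, and the
acceptance script re-derives its quantities at the same scales.

## Known limitations

* "Specificity" ambiguity is resolved as precision (see above); numbers
  from sources using a true-negative-rate definition are not comparable.
* LD expansion consumes precomputed r² values; no reference panel is
  queried, so locus definitions are only as good as the supplied table.
* The promoter rule accepts any same-sample peak; pipelines that demand
  the peak also be a loop anchor will report fewer promoter links.
* Inter-chromosomal loops are carried through the link table but are
  excluded from distance and TAD statistics, where they are undefined.
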