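# placentomics

Statistical machinery for multi-omic analysis of the preeclamptic (PE)
placenta. Preeclampsia has been linked to delayed trophoblast development:
immature trophoblasts under-methylate imprinted loci, overexpress
maternally imprinted genes such as the endoretrovirus-derived *PEG10*,
and shed virus-like particles whose RNA cargo appears in neighboring
maternal endothelial cells whose own chromatin is silent at those loci.
This package implements, for analysts working with methylation,
single-cell RNA/ATAC, and CUT&Tag-style data, the bespoke procedures such
a study needs — each testable end-to-end on synthetic data with planted
ground truth, with no external downloads.

## What it computes

**DMR calling.** Per-CpG beta values (methylated reads / coverage) are
tested per locus (Welch t, p < 0.01 and |Δβ| > 0.1), merged within
100 bp, re-tested on per-sample averages (seed DMRs, p < 0.01), and the
Δβ track is segmented by circular binary segmentation: the arc of the
circularized track maximizing the two-sample t statistic

&nbsp;&nbsp;&nbsp;&nbsp;*t = (x̄_arc − x̄_rest) / (s_p √(1/k + 1/(n−k)))*

is accepted as a changepoint pair at permutation p ≤ 0.01 and recursed.
Segment means are clustered by 1-D k-means; segments fully encompassing a
seed become DMRs (hypo = PE lower).

**Trophoblast maturity.** Control latent times follow a two-component
Gaussian mixture fit by EM (components reported ascending: "juvenile"
≈ 0.15, "adult" ≈ 0.56); a cell is immature when CytoTRACE < 0.2 and
latent time < 0.4, and per-donor immature fractions are compared by Welch
t. Mitotic aging rate = inferred mitotic age / gestational week, compared
per lineage by Wilcoxon rank-sum.

**Expression statistics.** Rank-sum differential expression with
expressed-fraction bookkeeping (min.pct 0.1, Bonferroni, significance
p_adj < 0.05 & |log2FC| > 0.5); origin markers (p_adj < 0.001,
avg_logFC > 1, |pct1 − pct2| > 0.3); bin-matched module scores
(Seurat-style, 24 bins, 100 controls/gene); maternal/fetal assignment by
score argmax; imprinted-gene up/down 2×2 Fisher test.

**Cargo genes.** Genes differentially present in receiver endothelium
(|log2FC| > 0.5 or p_adj < 0.01) whose loci are completely inaccessible
in PE *and* control endothelium (no peak, fragment score < 0.01);
3′UTR read-fraction bias; allele-of-origin tracing at a trio-informative
SNP (paternal fraction per cell group); seeded k-mer motif discovery and
PWM Pearson similarity with a background Z-score.

**Histone domains.** Broad-peak merging within ±5 kb, RPKM, the
differential rule |mean(PE) − mean(ctrl)| / (sd(PE) + sd(ctrl)) > 2,
element-level Fisher overlap enrichment, and a permutation overlap
Z-score (length- and chromosome-preserving relocation, 1000 permutations).

## Worked example

```r
library(placentomics)

cfg <- sim_config(seed = 42)          # the default synthetic study
tab <- gen_methylation_cohort(cfg)    # 5000 CpGs, 10 PE vs 10 non-PE
res <- call_dmrs(tab, seed = 42)
res$dmrs[c("chrom", "start", "end", "direction", "mean_delta_beta", "n_cpg")]
#>   chrom start   end direction mean_delta_beta n_cpg
#> 1  chr1 10045 12005     hyper       0.2968321    39
#> 2  chr2 20034 22038      hypo      -0.3011832    41
dmr_recall(res$dmrs, attr(tab, "truth"))
#> [1] 0.98025
```

The two planted DMRs (chr1:10000–12000 at Δβ = +0.3, chr2:20000–22000 at
Δβ = −0.3) are recovered with the right direction, effect size (mean Δβ
≈ ±0.30), and 98% base-pair overlap.

```r
cells <- gen_trophoblast_cells(cfg)
ctrl <- cells[cells$phenotype == "control" &
              cells$lineage %in% trophoblast_lineages(), ]
fit_bimodal_latent(ctrl$latent_time, seed = 42)
#> Two-component Gaussian mixture fit
#>   means:   0.1591 / 0.5592
#>   sds:     0.0729 / 0.0807
#>   weights: 0.527 / 0.473
immature_frequency_test(cells)$p_value
#> [1] 0.00021
```

The EM fit recovers the juvenile/adult latent-time means (0.15 / 0.56;
the ≈ +0.006 offset on the juvenile mean is the [0,1] truncation bias),
and the planted PE excess of immature trophoblasts is detected.

```r
fx <- gen_cargo_fixture(cfg)
trace_allele(fx$allele)$per_group[c("cell_group", "paternal_fraction",
                                    "fetal_call")]
#>             cell_group paternal_fraction fetal_call
#> 1    fetal_trophoblast                 1       TRUE
#> 2    fetal_endothelial                 1       TRUE
#> 3 maternal_endothelial                 1       TRUE
#> 4      maternal_immune                 1       TRUE
```

With a mother homozygous T/T and father/progeny heterozygous T/A, every
transcript at the SNP — including those in maternal cells — carries the
paternal A allele: the transcripts are fetal in origin regardless of the
cell they were read in.

A full end-to-end run on the bundled demo configuration:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "placentomics"))
```

writes per-stage artifacts (TSV/BED/MatrixMarket/FASTA/JSON) and an
MD5-hashed `manifest.json`; rerunning the same config reproduces every
hash.

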