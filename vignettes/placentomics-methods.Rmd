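---
title: "Methods: multi-omic analysis of trophoblast development in preeclampsia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic analysis of trophoblast development in preeclampsia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`placentomics` implements, as reusable and tested functions, the bespoke
statistical procedures of a multi-omic study of the preeclamptic (PE)
placenta: calling differentially methylated regions (DMRs) from per-CpG
beta values, classifying trophoblast developmental state from RNA-velocity
latent time and CytoTRACE stemness scores, assigning maternal or fetal
origin to placental cells, testing parent-of-origin dosage imbalance of
imprinted genes, identifying virus-like-particle (VLP) "cargo" transcripts
that are present in receiver cells whose chromatin is silent, tracing the
parental allele of such transcripts in a family trio, and calling
differential broad histone domains with region-overlap enrichment
statistics. Upstream machinery (read mapping, peak calling, velocity model
fitting, CytoTRACE itself) is out of scope: those quantities enter as
inputs.

Every stage can be exercised on synthetic data with planted ground truth
(`sim_config()` and the `gen_*()` generators), so the whole pipeline is
testable without any external or controlled-access dataset.

# The DMR pipeline

Methylation is summarized per CpG as beta — methylated reads over total
coverage, in [0, 1] — for two groups of samples (PE vs non-PE). The
pipeline has five stages:

1. **DML calling** (`call_dml`): a CpG is a differentially methylated
   locus when the two-sided Welch t-test between groups gives p < 0.01
   *and* the group beta difference exceeds 0.1 in absolute value. The
   t-test is Welch (unequal variances) everywhere a t-test is named; the
   pooled-variance choice is not material at these thresholds but Welch is
   robust to unequal group dispersion. No multiple-testing correction is
   applied at this stage (raw p < 0.01 is the rule); this is deliberate
   and documented. CpGs with fewer than two non-missing betas in a group
   are skipped and counted.
2. **Merging** (`merge_dml`): DMLs within 100 bp of each other are merged
   into candidate intervals (singletons allowed); coordinates become
   0-based half-open.
3. **Seeding** (`seed_dmr`): per candidate, betas are averaged per sample
   over the encompassed CpGs and the group averages re-tested; candidates
   with p < 0.01 are "seed" DMRs.
4. **Segmentation** (`segment_delta`): the per-CpG beta-difference track
   is segmented per chromosome by circular binary segmentation: the track
   is treated as a circle and the arc maximizing the pooled-variance
   two-sample t statistic against its complement is a candidate
   changepoint pair, accepted when its permutation p-value is at most
   alpha = 0.01 (mirroring the DML cut-off) with 1000 permutations by
   default, then recursed. The O(n^2) arc scan and the permutation loop
   are compiled code; the permutation loop stops early once the exceedance
   count already implies rejection, which cannot change the decision.
   Chromosomes with fewer than 4 CpGs are a single segment. Segments tile
   each chromosome from its first to its last CpG, with internal
   boundaries at the first CpG of each new segment.
5. **Clustering and finalization** (`cluster_segments`, `finalize_dmr`):
   segment mean beta differences are clustered by 1-D k-means (k = 6 by
   default, overridable; ids are relabeled in ascending centroid order so
   results are label-stable). Initial centers are spread at within-cluster
   quantiles, which makes the fit deterministic and order-invariant.
   Clusters containing a segment that *fully encompasses* a seed are
   selected, and each seed-encompassing segment becomes a DMR (hypo when
   PE is lower). We read "fully encompassed" as segment ⊇ seed: seeds are
   short merges of ≤ 100-bp-apart loci while segments tile the genome, so
   the inverse reading would almost never fire. Note the construction
   makes cluster selection non-restrictive — every seed-encompassing
   segment lies in a selected cluster by definition — so the cluster id is
   provenance rather than an extra filter.

Bisulfite conversion QC (`conversion_qc`) applies the strict rule that a
sample passes only when its unmethylated-CHH fraction exceeds 0.99.

## Numerical choices

* `k = 6` for segment clustering: the analysis reports several hypo- and
  hyper-methylated cluster labels (more than four), so the default must
  allow at least that granularity; it is a flag, not a constant.
* Degenerate t-tests (zero variance in both groups) give p = 1 when the
  means agree and p = 0 when they differ — the latter is flagged by an
  infinite statistic in the domain module's analogous rule.
* If no seed exists, segmentation is skipped: no DMR can be finalized
  without a seed, so the result is provably identical.

# Synthetic methylation cohorts

`gen_methylation_cohort()` draws betas per CpG per sample from Beta
distributions parameterized by mean and concentration: a CpG with group
mean mu and concentration c draws from Beta(mu·c, (1−mu)·c), which keeps
betas in [0, 1] with tunable dispersion. Baseline means are uniform on
[0.35, 0.65]; inside a planted DMR the PE mean is shifted by the planted
signed effect (default ±0.3), and a configuration whose shift pushes a
mean outside (0, 1) is rejected. CpGs are spread over four chromosomes
(~1250 CpGs each at the 5000-CpG default) with 20–80 bp gaps — the
spacing of a dense capture panel, and small enough that loci within a
region merge under the 100-bp rule. Default concentration is 100
(between-sample beta sd ≈ 0.05 at mu = 0.5), a realistic between-donor
dispersion for bulk placenta; at that dispersion a chance |Δβ| > 0.1
excursion at 10 vs 10 samples is a ≈ 4.5-sigma event, so isolated false
DMLs — which would otherwise seed spurious whole-chromosome DMRs under a
null segmentation — are rare, matching the intended genome-wide null
behavior of the pipeline (mean false DMR count ≤ 1 per run).

# Trophoblast developmental state

Control trophoblasts segregate by RNA-velocity latent time into a
"juvenile" population (mean latent time 0.15) and an "adult" population
(mean 0.56); PE trophoblasts sit in between. `fit_bimodal_latent()` fits
a two-component Gaussian mixture by EM (k-means++-style initialization on
the 1-D values, convergence when the log-likelihood gain falls below
1e-8 or 500 iterations, jittered restarts on a collapsing component, up
to 10). Components are always reported ascending by mean, so label
swapping cannot occur. The mixture fit is a diagnostic; the canonical
immature-cell classifier is threshold-based, as printed in the source
analysis: a trophoblast is **immature** when CytoTRACE < 0.2 *and*
latent time < 0.4 (both strict). How those two thresholds were derived
from the mixture fit is not stated in the source; they are treated as
given constants and exposed as arguments.

`immature_frequency_test()` compares per-donor immature fractions between
phenotypes by a Welch t-test on the donor fractions (raw p). With fewer
than two donors in a phenotype only the fractions are reported.
`mitosis_aging_rate()` divides inferred mitotic age by gestational week
and compares phenotypes per lineage by a two-sided Wilcoxon rank-sum test
(raw p). `proliferation_score()` records the convention of summing G2/M
and S phase scores into one cycling scalar.

The generator draws control latent times from the two-component truncated
normal mixture (truncation to [0, 1] by rejection, which biases the
juvenile component mean upward by about +0.006 — visible as recovered
means of ≈ 0.156 rather than 0.150), PE latent times from a single
intermediate component (mean 0.35, sd 0.08 — chosen between the two
printed means, since the source states only "intermediate"). CytoTRACE
is emulated as clip(1 − latent + N(0, 0.1)): the two scores are linked
only empirically in real data, and a noisy monotone inversion reproduces
that relationship. Because that proxy can never produce the joint
low-CytoTRACE/low-latent signature, the generator plants a genuinely
immature subpopulation (2% of control and 10% of PE trophoblasts: latent
at the juvenile mean, CytoTRACE near 0.1) — the PE excess is the study
condition the frequency test measures. True mitotic aging rates are 1.0
(control) and 0.6 (PE) age units per gestational week.

# Single-cell expression statistics

`wilcoxon_de()` tests genes whose expressed fraction reaches 10% in
either group by a two-sided rank-sum test on log-normalized expression
(library-size scaling to 10^4, log1p — the normalization default of the
cited toolchain). Fold changes use the log-normalized-mean convention
with pseudocount 1 and are stored on the natural-log scale
(`avg_logFC`) with a derived `log2_fc`; this reconciles the two
conventions in the source: the origin-marker criterion "avg_logFC > 1"
follows the natural-log convention of the cited tool version, while DE
significance is stated in log2 ("adjusted p < 0.05 and |log2FC| > 0.5",
Bonferroni over tested genes only).

Origin markers require all of: adjusted p < 0.001, avg_logFC > 1
(natural log, in magnitude), and an expressed-fraction difference
|pct1 − pct2| > 0.3. `module_score()` computes gene-set activity as set
mean minus the mean of expression-bin-matched control genes (24 bins,
100 controls per set gene, sampled with replacement and deterministic
given a seed; control pools are sorted so the score is invariant to gene
and cell order). `assign_origin()` labels each cell by the larger of its
maternal/fetal scores, with exact ties unassigned.
`imprint_direction_summary()` restricts a PE-vs-control DE table to
experimentally validated imprinted genes and tests the
{paternal, maternal} × {up, down} table by two-sided Fisher exact, using
the module's global significance rule for up/down since the source does
not state a separate cut.

# Cargo genes, allele tracing, and UTR motifs

A **cargo gene** is a transcript differentially present in receiver
endothelial cells whose locus is completely chromatin-inaccessible there.
"Completely inaccessible" is operationalized reproducibly as: no called
peak overlapping the gene region *and* a per-cell fragment-presence score
below 0.01 — replacing the manual track inspection of the source with a
deterministic rule. The expression criterion is the disjunction as
printed: |log2FC| > 0.5 *or* adjusted p < 0.01 (PE-specific mode requires
the positive direction, trophoblast upregulation, and accessible
trophoblast peaks). Each evaluated gene records which criteria fired, so
rejected candidates can be audited.

`trace_allele()` identifies the paternal-specific allele (carried by
father and progeny, absent from the mother; a trio without such an allele
errors as uninformative), counts bases per cell group, and calls a group
"fetal transcript" when the paternal fraction exceeds 0.95 — the source
reports 100%, and a strict 1.0 rule would be brittle to a single
sequencing error. The bundled trio configuration mirrors the reported
one: mother homozygous T/T, father and progeny heterozygous T/A.

`motif_discover()` substitutes a transparent, seeded k-mer method for the
stochastic discovery package used upstream (whose internals are not the
contract here): seed on the most frequent exact width-mer, collect all
windows within Hamming distance ⌊width/4⌋, and average base frequencies
with pseudocount 0.25. `motif_similarity_z()` scores two PWMs by the
maximum over alignment offsets (minimum overlap 4 columns) of the mean
column-wise Pearson correlation, and standardizes against a background
motif collection (≥ 20 motifs) as a Z-score. The printed similarity of
the real cargo UTR motif is not reproducible without the real UTR
sequences; the synthetic fixture verifies the machinery (planted shared
motifs score Z > 2 against shuffled backgrounds).

# Histone domains and overlap enrichment

Broad peaks are merged into domains when their gap is at most 5 kb
(inclusive — strictness is not stated in the source; the inclusive
reading is the natural one for "within ±5 kb"). Domain coverage is
normalized to RPKM (count / kb of domain / million mapped fragments), and
a domain is differential when |mean(PE) − mean(control)| divided by
(sd(PE) + sd(control)) exceeds 2 — the printed rule, applied verbatim;
when both sds vanish the statistic is infinite if the means differ
(flagged) and the domain is unchanged otherwise. At the planted
acceptance shift of 3·(sd_PE + sd_ctrl) with 3 vs 3 samples this rule has
intrinsic recall ≈ 0.93.

`fisher_region_enrichment()` cross-classifies universe *elements* (not
base pairs — matching the element-count usage in the source) by query
membership and ≥ 1 bp target overlap; the p-value comes from the exact
test and the odds ratio is the sample (a·d)/(b·c), not the conditional
MLE. `permutation_overlap_z()` relocates each query interval uniformly at
random, preserving length and (by default) chromosome — whether the
upstream permutation preserved chromosome is unstated, so it is the
default and configurable — and reports the overlap count's Z-score
against 1000 permutations plus an empirical one-sided p with the +1
correction. On null data the Z-scores are calibrated (mean ≈ 0, sd ≈ 1).

# Orchestration and reproducibility

`run_pipeline()` executes the stages in dependency order on a config
(list or YAML), writes all artifacts in standard text formats (TSV,
BED 0-based half-open, MatrixMarket + metadata TSVs, FASTA, JSON), and
records an MD5 manifest; the same config yields byte-identical artifacts.
One global seed drives everything: each generator derives a substream by
a stable polynomial hash of its name, so adding a generator never
perturbs another's draws. There is no shell entry point: this is an
analysis package driven from R, and the functions, the bundled demo
config (`inst/extdata/demo_config.yaml`), and this vignette are the
interface.

## Problem sizes

The shipped test and demo configurations use 5000 CpGs (10 vs 10
samples) for methylation, 5000 control trophoblasts for the mixture fit,
~2000 genes × 800 cells for the cargo fixture, 200 histone domains
(3 vs 3), and 100–1000 permutations depending on the stage — sizes at
which every planted effect is comfortably detectable and a full run
completes in a few minutes on a laptop. They are package defaults, not
limits; all sizes are config fields.

# What passing tests do and do not show

The generators emulate the *structure* of the real inputs — bimodal
latent-time mixtures, Beta-noise methylation with planted DMRs,
parent-of-origin expression shifts, RNA-present/chromatin-silent cargo
genes, planted UTR motifs, monoallelic paternal reads, group-shifted
domain coverage — under idealized noise (Beta/Gaussian/Poisson,
independence across loci, genes, and cells). They do not model linked
methylation along reads, cell-cell doublets, ambient RNA, batch effects,
mappability artifacts, or biological covariance between omic layers.
Recovery of planted truth therefore validates the statistical machinery
and its thresholds, not the biology of any particular dataset; the
printed genome-wide counts of the source study depend on controlled-
access data and are out of scope by design.

# Known limitations

* The CBS permutation reference assumes exchangeable per-CpG beta
  differences within a chromosome; long-range autocorrelation would make
  the splits anticonservative.
* The EM mixture fit assumes exactly two components; the PE
  "intermediate" population is deliberately not modeled as a third.
* Bonferroni over tested genes is conservative for dense DE tables.
* The element-level Fisher overlap test ignores interval lengths; the
  permutation Z is the length-aware complement.
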