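#' Simulation configuration for the synthetic multi-omic study
#'
#' One configuration object drives every synthetic generator in the package.
#' The defaults encode the study conditions the pipeline is designed around:
#' a bimodal latent-time mixture for control trophoblasts (juvenile mean
#' 0.15, adult mean 0.56, sd 0.08, equal weights) with PE cells drawn from a
#' single intermediate component (mean 0.35), planted differentially
#' methylated regions of effect size 0.3 on a Beta-noise background
#' (concentration 50) with 10 samples per group, monoallelic paternal
#' transcripts at a trio-informative SNP, RNA-present/chromatin-silent cargo
#' genes, a planted UTR motif, and group-shifted histone-domain coverage.
#'
#' The single `seed` fully determines all outputs; each generator derives
#' its own substream via a stable hash of the generator name, so generators
#' never perturb one another's draws.
#'
#' @param seed Integer global seed.
#' @param n_cpg Total number of CpG loci across all chromosomes.
#' @param n_samples_per_group Methylation samples per phenotype group
#'   (PE / nonPE); at least 2.
#' @param chroms Chromosome names over which CpGs are spread evenly.
#' @param planted_dmrs `data.frame(chrom, start, end, delta_beta)` of
#'   planted DMRs, 0-based half-open, `delta_beta` the signed PE-minus-nonPE
#'   group-mean methylation shift. Intervals must be disjoint.
#' @param beta_noise_conc Beta-distribution concentration `c`: a CpG with
#'   group mean `mu` draws betas from `Beta(mu*c, (1-mu)*c)`.
#' @param n_cells_per_type Named integer vector, cells per lineage *per
#'   phenotype* for the trophoblast-state generator.
#' @param n_donors_per_phenotype Donors per phenotype.
#' @param latent_mix List with `mean_juvenile`, `mean_adult`, `sd`,
#'   `weight_juvenile` describing the control latent-time mixture (means in
#'   `[0, 1]`).
#' @param pe_latent List with `mean`, `sd` for the single intermediate PE
#'   latent-time component.
#' @param immature_frac Named fractions (`control`, `PE`) of trophoblast
#'   cells planted as genuinely immature: juvenile latent time together
#'   with a low CytoTRACE score, the joint signature the immature-cell
#'   classifier looks for. PE carries the excess.
#' @param cytotrace_noise_sd Noise sd of the CytoTRACE proxy
#'   `clip(1 - latent + N(0, sd), 0, 1)`.
#' @param aging_rate True mitotic-age increase per gestational week, named
#'   by phenotype (PE reduced).
#' @param aging_noise_sd Per-cell sd of mitotic age around
#'   `rate * gestational_week`.
#' @param imprint_effects `data.frame(gene, expressed_allele, lfc)` of
#'   imprinted genes and their planted PE-vs-control log fold changes.
#' @param origin_effect Natural-log fold change separating fetal from
#'   maternal marker genes in the origin cohort.
#' @param cargo List controlling the cargo fixture: gene counts per class,
#'   expression means, cells per group.
#' @param motif List with `pwm` (4 x width probability matrix, rows ACGT) or
#'   `consensus` string, plus `n_utr` and `utr_len` for the UTR FASTA.
#' @param allele_cfg List: `snp` (label), `mother`, `father`, `progeny`
#'   genotypes (length-2 character vectors of alleles), `reads_per_group`
#'   named integer vector, `paternal_fraction` in `[0, 1]`.
#' @param domain_cfg List: `n_domains`, `n_samples_per_group`, `base_mean`
#'   and `base_sd` (RPKM), `n_gain`, `n_lost`, `shift` (RPKM added to PE
#'   means of gained domains / removed for lost ones).
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_cpg = 400, n_samples_per_group = 4)
#' cfg$latent_mix$mean_juvenile
#' @export
sim_config <- function(seed = 42L,
                       n_cpg = 5000L,
                       n_samples_per_group = 10L,
                       chroms = paste0("chr", 1:4),
                       planted_dmrs = data.frame(
                         chrom = c("chr1", "chr2"),
                         start = c(10000L, 20000L),
                         end = c(12000L, 22000L),
                         delta_beta = c(0.3, -0.3)
                       ),
                       beta_noise_conc = 100,
                       n_cells_per_type = c(VCTp = 150L, VCT = 400L,
                                            SCT = 400L, EVT = 300L,
                                            endothelial = 200L),
                       n_donors_per_phenotype = 4L,
                       latent_mix = list(mean_juvenile = 0.15,
                                         mean_adult = 0.56,
                                         sd = 0.08,
                                         weight_juvenile = 0.5),
                       pe_latent = list(mean = 0.35, sd = 0.08),
                       immature_frac = c(control = 0.02, PE = 0.10),
                       cytotrace_noise_sd = 0.1,
                       aging_rate = c(control = 1.0, PE = 0.6),
                       aging_noise_sd = 2,
                       imprint_effects = data.frame(
                         gene = c("PEG10", "MEST", "PLAGL1", "H19", "MEG3",
                                  "CDKN1C"),
                         expressed_allele = c("paternal", "paternal",
                                              "paternal", "maternal",
                                              "maternal", "maternal"),
                         lfc = c(1.0, 0.8, 0.8, -0.8, -0.8, -0.6)
                       ),
                       origin_effect = 1.0,
                       cargo = list(n_cargo = 5L, n_reject_de = 3L,
                                    n_reject_access = 3L,
                                    n_background = 2000L,
                                    cells_per_group = 200L,
                                    base_mean = 1, hi_mean = 8,
                                    troph_base = 2),
                       motif = list(consensus = "TGCATGCA", n_utr = 20L,
                                    utr_len = 300L),
                       allele_cfg = list(snp = "chr7:94665871",
                                         ref = "T", alt = "A",
                                         mother = c("T", "T"),
                                         father = c("T", "A"),
                                         progeny = c("T", "A"),
                                         reads_per_group = c(
                                           fetal_trophoblast = 60L,
                                           fetal_endothelial = 30L,
                                           maternal_endothelial = 25L,
                                           maternal_immune = 20L),
                                         paternal_fraction = 1.0),
                       domain_cfg = list(n_domains = 200L,
                                         n_samples_per_group = 3L,
                                         base_mean = 20, base_sd = 2,
                                         n_gain = 10L, n_lost = 10L,
                                         shift = 12)) {
  cfg <- list(seed = as.integer(seed), n_cpg = as.integer(n_cpg),
              n_samples_per_group = as.integer(n_samples_per_group),
              chroms = chroms, planted_dmrs = planted_dmrs,
              beta_noise_conc = beta_noise_conc,
              n_cells_per_type = n_cells_per_type,
              n_donors_per_phenotype = as.integer(n_donors_per_phenotype),
              latent_mix = latent_mix, pe_latent = pe_latent,
              immature_frac = immature_frac,
              cytotrace_noise_sd = cytotrace_noise_sd,
              aging_rate = aging_rate, aging_noise_sd = aging_noise_sd,
              imprint_effects = imprint_effects,
              origin_effect = origin_effect,
              cargo = cargo, motif = motif, allele_cfg = allele_cfg,
              domain_cfg = domain_cfg)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  check_that(length(cfg$seed) == 1L && !is.na(cfg$seed),
             "seed must be a single integer")
  check_that(cfg$n_samples_per_group >= 2L,
             "n_samples_per_group must be >= 2")
  pd <- cfg$planted_dmrs
  if (nrow(pd)) {
    check_that(all(pd$end > pd$start), "planted DMRs must have start < end")
    check_that(all(abs(pd$delta_beta) <= 1),
               "planted |delta_beta| must be <= 1")
    # disjointness within chromosome
    for (ch in unique(pd$chrom)) {
      p <- pd[pd$chrom == ch, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      if (nrow(p) > 1L)
        check_that(all(p$start[-1L] >= p$end[-nrow(p)]),
                   "planted DMR intervals must be disjoint")
    }
  }
  lm <- cfg$latent_mix
  check_that(lm$mean_juvenile >= 0 && lm$mean_juvenile <= 1 &&
               lm$mean_adult >= 0 && lm$mean_adult <= 1,
             "latent mixture means must lie in [0, 1]")
  check_that(lm$weight_juvenile >= 0 && lm$weight_juvenile <= 1,
             "weight_juvenile must lie in [0, 1]")
  check_that(lm$sd > 0 && cfg$pe_latent$sd > 0, "latent sds must be > 0")
  check_that(all(cfg$immature_frac >= 0 & cfg$immature_frac <= 1),
             "immature_frac values must lie in [0, 1]")
  pf <- cfg$allele_cfg$paternal_fraction
  check_that(pf >= 0 && pf <= 1, "paternal_fraction must lie in [0, 1]")
  check_that(cfg$domain_cfg$base_sd > 0, "domain base_sd must be > 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration (seed ", x$seed, ")\n", sep = "")
  cat("  methylation: ", x$n_cpg, " CpGs on ", length(x$chroms),
      " chromosomes, ", x$n_samples_per_group, " samples/group, ",
      nrow(x$planted_dmrs), " planted DMRs\n", sep = "")
  cat("  cells/lineage/phenotype: ",
      paste(names(x$n_cells_per_type), x$n_cells_per_type,
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  control latent mixture: means ", x$latent_mix$mean_juvenile, "/",
      x$latent_mix$mean_adult, ", sd ", x$latent_mix$sd, "\n", sep = "")
  cat("  domains: ", x$domain_cfg$n_domains, " (",
      x$domain_cfg$n_gain, " gain, ", x$domain_cfg$n_lost, " lost)\n",
      sep = "")
  invisible(x)
}
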