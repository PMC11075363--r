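# Truncated-normal draw by rejection; keeps the component a proper
# distribution on [lo, hi] instead of piling clipped mass at the bounds.
rnorm_trunc <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Simulate trophoblast (and supporting) cell metadata
#'
#' Control trophoblast latent times are drawn from a two-component truncated
#' normal mixture at the configured juvenile/adult means; PE trophoblasts
#' from a single intermediate component. The CytoTRACE proxy is
#' `clip(1 - latent + N(0, sd), 0, 1)` (noisily decreasing in latent time),
#' and mitotic age is `rate * gestational_week + N(0, sd)` with a reduced
#' true rate in PE. Endothelial cells receive latent/CytoTRACE values from
#' the same machinery but are not trophoblasts and are ignored by the
#' trophoblast-state analyses.
#'
#' @param cfg A [sim_config()].
#' @return A `data.frame` (one row per cell) with columns `cell_id`,
#'   `lineage`, `donor`, `phenotype`, `gestational_week`, `latent_time`,
#'   `cytotrace`, `mitotic_age`, `origin`, plus attributes
#'   `truth_component` (juvenile/adult/intermediate/immature per cell)
#'   and `truth_rate` (the generating aging rates).
#' @examples
#' cells <- gen_trophoblast_cells(sim_config(seed = 7))
#' table(cells$lineage, cells$phenotype)
#' @export
gen_trophoblast_cells <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(substream_seed(cfg$seed, "trophoblast"), {
    lineages <- rep(names(cfg$n_cells_per_type), cfg$n_cells_per_type)
    n_per_phen <- length(lineages)
    phen <- rep(c("control", "PE"), each = n_per_phen)
    lineage <- rep(lineages, 2L)
    n <- length(phen)

    nd <- cfg$n_donors_per_phenotype
    donor_pool <- c(paste0("C", seq_len(nd)), paste0("P", seq_len(nd)))
    donor <- ifelse(phen == "control",
                    sample(donor_pool[seq_len(nd)], n, replace = TRUE),
                    sample(donor_pool[nd + seq_len(nd)], n, replace = TRUE))
    gw_map <- setNames(sample(34:40, 2L * nd, replace = TRUE), donor_pool)
    gw <- gw_map[donor]

    lm <- cfg$latent_mix
    is_ctrl <- phen == "control"
    comp <- character(n)
    juv <- runif(n) < lm$weight_juvenile
    comp[is_ctrl & juv] <- "juvenile"
    comp[is_ctrl & !juv] <- "adult"
    comp[!is_ctrl] <- "intermediate"
    latent <- numeric(n)
    latent[comp == "juvenile"] <-
      rnorm_trunc(sum(comp == "juvenile"), lm$mean_juvenile, lm$sd)
    latent[comp == "adult"] <-
      rnorm_trunc(sum(comp == "adult"), lm$mean_adult, lm$sd)
    latent[comp == "intermediate"] <-
      rnorm_trunc(sum(comp == "intermediate"),
                  cfg$pe_latent$mean, cfg$pe_latent$sd)

    # planted immature subpopulation: juvenile latent + genuinely low
    # CytoTRACE (the proxy below cannot produce this joint signature)
    is_tro <- lineage %in% trophoblast_lineages()
    imm <- runif(n) < ifelse(is_ctrl, cfg$immature_frac[["control"]],
                             cfg$immature_frac[["PE"]]) & is_tro
    latent[imm] <- rnorm_trunc(sum(imm), lm$mean_juvenile, lm$sd)
    comp[imm] <- "immature"

    cyto <- pmin(pmax(1 - latent +
                        rnorm(n, 0, cfg$cytotrace_noise_sd), 0), 1)
    cyto[imm] <- rnorm_trunc(sum(imm), 0.1, 0.05)
    rate <- ifelse(is_ctrl, cfg$aging_rate[["control"]],
                   cfg$aging_rate[["PE"]])
    age <- rate * gw + rnorm(n, 0, cfg$aging_noise_sd)

    cells <- data.frame(
      cell_id = sprintf("cell%05d", seq_len(n)),
      lineage = lineage, donor = donor, phenotype = phen,
      gestational_week = as.numeric(gw), latent_time = latent,
      cytotrace = cyto, mitotic_age = age, origin = "fetal",
      stringsAsFactors = FALSE
    )
    rownames(cells) <- NULL
    attr(cells, "truth_component") <- comp
    attr(cells, "truth_rate") <- cfg$aging_rate
    cells
  })
}

#' Lineages counted as trophoblast
#' @return Character vector of trophoblast lineage names.
#' @export
trophoblast_lineages <- function() c("VCTp", "VCT", "SCT", "EVT")

#' Simulate an expression cohort with planted origin and imprinting effects
#'
#' Generates a sparse count matrix (genes x cells) of Poisson counts on a
#' log-normal baseline. Fetal-origin marker genes are up-shifted in fetal
#' cells and maternal markers in maternal cells (by `origin_effect` on the
#' natural-log scale); the configured imprinted genes receive their planted
#' PE-vs-control log fold change in fetal cells, emulating the
#' parent-of-origin dosage imbalance the imprint-direction analysis tests.
#'
#' @param cfg A [sim_config()].
#' @param n_genes Background gene count (markers and imprinted genes are
#'   added on top).
#' @param n_cells_per_class Cells per origin x phenotype class.
#' @param n_markers Fetal and maternal marker genes each.
#' @param base_mean Baseline Poisson mean.
#' @return List with `counts` (a `dgCMatrix`, genes x cells), `meta`
#'   (per-cell `data.frame` with `origin`, `phenotype`), `fetal_markers`,
#'   `maternal_markers`, and `imprint` (the planted imprint table).
#' @export
gen_expression_cohort <- function(cfg, n_genes = 200L,
                                  n_cells_per_class = 100L,
                                  n_markers = 20L, base_mean = 2) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(substream_seed(cfg$seed, "expression"), {
    imp <- cfg$imprint_effects
    fet_mark <- sprintf("FMK%02d", seq_len(n_markers))
    mat_mark <- sprintf("MMK%02d", seq_len(n_markers))
    bg <- sprintf("G%04d", seq_len(n_genes))
    genes <- c(fet_mark, mat_mark, imp$gene, bg)
    classes <- expand.grid(origin = c("fetal", "maternal"),
                           phenotype = c("control", "PE"),
                           stringsAsFactors = FALSE)
    meta <- classes[rep(seq_len(nrow(classes)), each = n_cells_per_class), ]
    meta$cell_id <- sprintf("c%05d", seq_len(nrow(meta)))
    rownames(meta) <- meta$cell_id
    lam0 <- exp(rnorm(length(genes), log(base_mean), 0.3))
    lam <- matrix(lam0, nrow = length(genes), ncol = nrow(meta))
    rownames(lam) <- genes
    # markers separate symmetrically: up by exp(eff) in their origin, down
    # by exp(-eff) in the other, emulating near-binary atlas markers
    eff <- cfg$origin_effect
    fet <- meta$origin == "fetal"
    lam[fet_mark, fet] <- lam[fet_mark, fet] * exp(eff)
    lam[fet_mark, !fet] <- lam[fet_mark, !fet] * exp(-eff)
    lam[mat_mark, !fet] <- lam[mat_mark, !fet] * exp(eff)
    lam[mat_mark, fet] <- lam[mat_mark, fet] * exp(-eff)
    fet_pe <- meta$origin == "fetal" & meta$phenotype == "PE"
    lam[imp$gene, fet_pe] <- lam[imp$gene, fet_pe] * exp(imp$lfc)
    counts <- matrix(rpois(length(lam), lam), nrow = nrow(lam),
                     dimnames = list(genes, meta$cell_id))
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         meta = meta[, c("cell_id", "origin", "phenotype")],
         fetal_markers = fet_mark, maternal_markers = mat_mark,
         imprint = imp)
  })
}
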