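# End-to-end orchestration of the synthetic study: simulate -> DMR / state /
# expression -> cargo / domains, with a hash-stable JSON manifest.

default_stages <- function() {
  c("simulate", "dmr", "state", "de", "cargo", "domains")
}

validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    check_that(file.exists(config),
               paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  check_that(is.list(config), "config must be a list or a YAML path")
  for (field in c("seed", "outdir"))
    check_that(!is.null(config[[field]]),
               paste0("config field missing: ", field))
  config$seed <- as.integer(config$seed)
  if (is.null(config$stages)) config$stages <- default_stages()
  config$stages <- unlist(config$stages)
  unknown <- setdiff(config$stages, default_stages())
  check_that(length(unknown) == 0L,
             paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  if (is.null(config$n_cpg)) config$n_cpg <- 2000L
  if (is.null(config$n_perm)) config$n_perm <- 200L
  if (is.null(config$k)) config$k <- 6L
  if (is.null(config$alpha)) config$alpha <- 0.01
  config
}

#' Run the full synthetic-study pipeline
#'
#' Executes the requested stages in dependency order on data generated
#' from the config seed, writes every artifact under the output
#' directory, and records an MD5-hashed manifest (JSON) of all outputs
#' together with the parameters and seeds used. A stage failure aborts
#' with an error after writing the partial manifest.
#'
#' @param config A list or YAML file path with at least `seed` and
#'   `outdir`; optional `stages` (subset of simulate, dmr, state, de,
#'   cargo, domains), `n_cpg`, `n_perm`, `k`, `alpha`.
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @examples
#' \donttest{
#' out <- tempfile("demo")
#' mf <- run_pipeline(list(seed = 1, outdir = out, n_cpg = 600,
#'                         n_perm = 100, stages = c("simulate", "dmr")))
#' names(mf$artifacts)
#' }
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  info <- function(...) if (!quiet) message("[pipeline] ", ...)
  artifacts <- list()
  note <- function(path) {
    artifacts[[length(artifacts) + 1L]] <<-
      list(path = path, md5 = unname(tools::md5sum(path)))
  }
  manifest_path <- file.path(outdir, "manifest.json")
  write_manifest <- function(status) {
    mf <- list(status = status,
               parameters = config[setdiff(names(config), "stages")],
               stages = config$stages, artifacts = artifacts)
    jsonlite::write_json(mf, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    mf
  }
  cfg <- sim_config(seed = config$seed, n_cpg = config$n_cpg)
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    info("stage ", name)
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      write_manifest(paste0("failed at stage ", name))
      stop("stage ", name, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    invisible(ok)
  }

  tab <- NULL; fixture <- NULL
  run_stage("simulate", function() {
    tab <<- gen_methylation_cohort(cfg)
    d <- file.path(outdir, "sim")
    dir.create(d, showWarnings = FALSE)
    write_beta_tsv(tab, file.path(d, "betas.tsv"),
                   file.path(d, "groups.yaml"))
    note(file.path(d, "betas.tsv")); note(file.path(d, "groups.yaml"))
    cells <- gen_trophoblast_cells(cfg)
    write.table(cells, file.path(d, "cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note(file.path(d, "cells.tsv"))
    fixture <<- gen_cargo_fixture(cfg)
    write_expression_dir(fixture$counts, file.path(d, "cargo_expr"),
                         fixture$meta)
    for (f in c("matrix.mtx", "genes.tsv", "cells.tsv"))
      note(file.path(d, "cargo_expr", f))
    Biostrings::writeXStringSet(fixture$utrs, file.path(d, "utrs.fasta"))
    note(file.path(d, "utrs.fasta"))
    hist <- gen_histone_coverage(cfg)
    write_bed(hist$domains, file.path(d, "domains.bed"))
    note(file.path(d, "domains.bed"))
    yaml::write_yaml(list(seed = cfg$seed), file.path(d, "config.yaml"))
    note(file.path(d, "config.yaml"))
  })

  run_stage("dmr", function() {
    if (is.null(tab)) tab <<- gen_methylation_cohort(cfg)
    res <- call_dmrs(tab, alpha = config$alpha, nperm = config$n_perm,
                     k = config$k, seed = config$seed)
    d <- file.path(outdir, "dmr")
    dir.create(d, showWarnings = FALSE)
    write.table(res$dml, file.path(d, "dml.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_dmr_bed(res$dmrs, file.path(d, "dmrs.bed"))
    recall <- dmr_recall(res$dmrs, attr(tab, "truth"))
    jsonlite::write_json(
      list(n_dml = nrow(res$dml), n_seeds = nrow(res$seeds),
           n_segments = nrow(res$segments), n_dmrs = nrow(res$dmrs),
           planted_recall = recall),
      file.path(d, "report.json"), auto_unbox = TRUE, digits = NA)
    note(file.path(d, "dml.tsv")); note(file.path(d, "dmrs.bed"))
    note(file.path(d, "report.json"))
  })

  run_stage("state", function() {
    cells <- gen_trophoblast_cells(cfg)
    tro <- cells[cells$lineage %in% trophoblast_lineages() &
                   cells$phenotype == "control", ]
    fit <- fit_bimodal_latent(tro$latent_time, seed = config$seed)
    freq <- immature_frequency_test(cells)
    aging <- mitosis_aging_rate(cells[cells$lineage %in%
                                        trophoblast_lineages(), ])
    d <- file.path(outdir, "state")
    dir.create(d, showWarnings = FALSE)
    jsonlite::write_json(
      list(mixture_means = fit$means, mixture_sds = fit$sds,
           mixture_weights = fit$weights,
           immature_p = freq$p_value,
           aging_tests = aging$tests),
      file.path(d, "state.json"), auto_unbox = TRUE, digits = NA)
    write.table(freq$fractions, file.path(d, "immature_fractions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note(file.path(d, "state.json"))
    note(file.path(d, "immature_fractions.tsv"))
  })

  run_stage("de", function() {
    ec <- gen_expression_cohort(cfg)
    norm <- log_normalize(ec$counts)
    ref <- ec$meta$phenotype == "control"
    de <- wilcoxon_de(ec$counts, ec$meta$cell_id[ref & ec$meta$origin ==
                                                   "fetal"],
                      ec$meta$cell_id[ref & ec$meta$origin == "maternal"],
                      norm = norm)
    markers <- select_origin_markers(de)
    sf <- module_score(norm, markers$fetal_markers, seed = config$seed)
    sm <- module_score(norm, markers$maternal_markers,
                       seed = config$seed + 1L)
    origin <- assign_origin(sm, sf)
    acc <- mean(origin == ec$meta$origin)
    fetal <- ec$meta$origin == "fetal"
    de_pe <- wilcoxon_de(ec$counts,
                         ec$meta$cell_id[fetal & ec$meta$phenotype == "PE"],
                         ec$meta$cell_id[fetal &
                                           ec$meta$phenotype == "control"],
                         norm = norm)
    imp <- imprint_direction_summary(
      de_pe, ec$imprint[c("gene", "expressed_allele")])
    d <- file.path(outdir, "de")
    dir.create(d, showWarnings = FALSE)
    write.table(de_pe, file.path(d, "de_pe_vs_control.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(markers = markers, origin_accuracy = acc,
           imprint_counts = as.data.frame(imp$counts),
           imprint_odds_ratio = imp$odds_ratio,
           imprint_p = imp$p_value),
      file.path(d, "origin_imprint.json"), auto_unbox = TRUE,
      digits = NA)
    note(file.path(d, "de_pe_vs_control.tsv"))
    note(file.path(d, "origin_imprint.json"))
  })

  run_stage("cargo", function() {
    if (is.null(fixture)) fixture <<- gen_cargo_fixture(cfg)
    meta <- fixture$meta
    norm <- log_normalize(fixture$counts)
    pick <- function(type, phen)
      meta$cell_id[meta$cell_type == type & meta$phenotype == phen]
    de_endo <- wilcoxon_de(fixture$counts, pick("endothelial", "PE"),
                           pick("endothelial", "control"), norm = norm)
    de_tro <- wilcoxon_de(fixture$counts, pick("trophoblast", "PE"),
                          pick("trophoblast", "control"), norm = norm)
    hits <- identify_cargo(de_endo, de_tro, fixture$acc,
                           mode = "pe_specific")
    bias <- utr_bias(fixture$utr_counts)
    allele <- trace_allele(fixture$allele)
    pwm <- motif_discover(fixture$utrs,
                          nchar(fixture$truth$motif))
    bg <- with_seed(substream_seed(config$seed, "motif_bg"), {
      lapply(seq_len(25L), function(i) {
        m <- matrix(stats::rgamma(4L * ncol(pwm), 1), nrow = 4L,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
        sweep(m, 2L, colSums(m), "/")
      })
    })
    simz <- motif_similarity_z(pwm, pwm, bg)
    d <- file.path(outdir, "cargo")
    dir.create(d, showWarnings = FALSE)
    write.table(hits, file.path(d, "cargo_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(paternal_allele = allele$paternal_allele,
           per_group = allele$per_group,
           utr_bias = bias[c("trophoblast_fraction",
                             "non_trophoblast_fraction", "p_value")],
           motif_consensus = attr(pwm, "consensus"),
           motif_self_similarity = simz$similarity,
           motif_z = simz$z),
      file.path(d, "cargo_report.json"), auto_unbox = TRUE, digits = NA)
    write_pfm(pwm, file.path(d, "motif.pfm"))
    note(file.path(d, "cargo_hits.tsv"))
    note(file.path(d, "cargo_report.json"))
    note(file.path(d, "motif.pfm"))
  })

  run_stage("domains", function() {
    hist <- gen_histone_coverage(cfg)
    rpkm <- domain_rpkm(hist$counts)
    diff <- differential_domains(rpkm)
    called <- hist$domains[diff$label != "unchanged", ]
    planted <- hist$domains[hist$domains$truth != "stable", ]
    fisher <- fisher_region_enrichment(called, planted, hist$domains)
    genome <- aggregate(list(length = hist$domains$end),
                        by = list(chrom = hist$domains$chrom), FUN = max)
    genome$length <- genome$length + 100000
    perm <- permutation_overlap_z(called, planted, genome,
                                  n_perm = config$n_perm,
                                  seed = config$seed)
    d <- file.path(outdir, "domains")
    dir.create(d, showWarnings = FALSE)
    out_bed <- data.frame(hist$domains[c("chrom", "start", "end")],
                          name = paste(hist$domains$domain_id,
                                       diff$label, sep = ";"))
    write_bed(out_bed, file.path(d, "domains.bed"))
    jsonlite::write_json(
      list(n_differential = sum(diff$label != "unchanged"),
           fisher_odds_ratio = fisher$odds_ratio,
           fisher_p = fisher$p_value,
           perm_z = perm$z, perm_p = perm$p_empirical),
      file.path(d, "enrichment.json"), auto_unbox = TRUE, digits = NA)
    note(file.path(d, "domains.bed"))
    note(file.path(d, "enrichment.json"))
  })

  mf <- write_manifest("ok")
  info("done: ", length(artifacts), " artifacts")
  invisible(mf)
}
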