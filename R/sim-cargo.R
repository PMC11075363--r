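#' Simulate the cargo-gene fixture: expression, accessibility, UTRs, alleles
#'
#' Builds every input of the cargo-transfer analyses with planted ground
#' truth:
#' * planted cargo genes are upregulated in PE endothelial cells (the
#'   receivers) while their loci are completely inaccessible in both PE and
#'   control endothelium, and expressed/accessible in trophoblast (the
#'   producers);
#' * each planted non-cargo control violates exactly one criterion — either
#'   no endothelial differential expression, or an accessible endothelial
#'   locus;
#' * UTR sequences carry the configured motif once each (optionally with
#'   per-base noise);
#' * per-cell 5'UTR/body/3'UTR read counts are 3'-biased in endothelium and
#'   5'-biased in trophoblast;
#' * allele-tagged reads at the trio SNP are drawn with the configured
#'   paternal fraction per cell group.
#'
#' @param cfg A [sim_config()].
#' @param motif_mutate_prob Per-base probability of mutating a planted motif
#'   position (0 = exact plant).
#' @return List with elements `counts` (genes x cells sparse matrix), `meta`
#'   (cell metadata: `cell_id`, `cell_type`, `phenotype`), `acc`
#'   (accessibility table), `utrs` ([Biostrings::DNAStringSet]), `utr_counts`
#'   (per-cell region read counts), `allele` (read-level allele table with a
#'   `trio` attribute), and `truth` (planted gene classes and motif).
#' @export
gen_cargo_fixture <- function(cfg, motif_mutate_prob = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(substream_seed(cfg$seed, "cargo"), {
    cg <- cfg$cargo
    cargo <- sprintf("CARGO%02d", seq_len(cg$n_cargo))
    rej_de <- sprintf("NODE%02d", seq_len(cg$n_reject_de))
    rej_acc <- sprintf("OPEN%02d", seq_len(cg$n_reject_access))
    bg <- sprintf("BG%02d", seq_len(cg$n_background))
    genes <- c(cargo, rej_de, rej_acc, bg)
    check_that(!anyDuplicated(genes), "cargo gene names must be unique")

    grp <- expand.grid(cell_type = c("trophoblast", "endothelial"),
                       phenotype = c("control", "PE"),
                       stringsAsFactors = FALSE)
    meta <- grp[rep(seq_len(nrow(grp)), each = cg$cells_per_group), ]
    meta$cell_id <- sprintf("cc%05d", seq_len(nrow(meta)))
    lam <- matrix(cg$base_mean, nrow = length(genes), ncol = nrow(meta),
                  dimnames = list(genes, meta$cell_id))
    endo_pe <- meta$cell_type == "endothelial" & meta$phenotype == "PE"
    tro <- meta$cell_type == "trophoblast"
    tro_pe <- tro & meta$phenotype == "PE"
    # cargo: up in PE endothelium, expressed in trophoblast, up in PE troph;
    # a large flat background keeps library-size composition shifts small
    lam[cargo, endo_pe] <- cg$hi_mean
    lam[cargo, tro] <- cg$troph_base
    lam[cargo, tro_pe] <- cg$hi_mean
    # rejected-for-accessibility controls: same expression pattern as cargo
    lam[rej_acc, endo_pe] <- cg$hi_mean
    lam[rej_acc, tro] <- cg$troph_base
    lam[rej_acc, tro_pe] <- cg$hi_mean
    counts <- matrix(rpois(length(lam), lam), nrow = nrow(lam),
                     dimnames = dimnames(lam))

    acc <- rbind(
      data.frame(gene = genes, cell_type = "trophoblast",
                 accessible = TRUE, score = 0.8),
      data.frame(gene = genes, cell_type = "endothelial_PE",
                 accessible = !(genes %in% c(cargo, rej_de)),
                 score = ifelse(genes %in% c(cargo, rej_de), 0, 0.5)),
      data.frame(gene = genes, cell_type = "endothelial_control",
                 accessible = !(genes %in% c(cargo, rej_de)),
                 score = ifelse(genes %in% c(cargo, rej_de), 0, 0.5))
    )
    rownames(acc) <- NULL

    mot <- cfg$motif
    motif_seq <- if (!is.null(mot$consensus)) mot$consensus else
      paste(c("A", "C", "G", "T")[apply(mot$pwm, 2, which.max)],
            collapse = "")
    w <- nchar(motif_seq)
    alphabet <- c("A", "C", "G", "T")
    utr_names <- if (mot$n_utr <= length(genes)) genes[seq_len(mot$n_utr)]
      else c(genes, sprintf("UTR%02d", seq_len(mot$n_utr - length(genes))))
    seqs <- vapply(seq_len(mot$n_utr), function(i) {
      s <- sample(alphabet, mot$utr_len, replace = TRUE)
      ins <- sample(seq_len(mot$utr_len - w + 1L), 1L)
      m <- strsplit(motif_seq, "")[[1L]]
      if (motif_mutate_prob > 0) {
        mut <- runif(w) < motif_mutate_prob
        m[mut] <- sample(alphabet, sum(mut), replace = TRUE)
      }
      s[ins:(ins + w - 1L)] <- m
      paste(s, collapse = "")
    }, character(1))
    utrs <- Biostrings::DNAStringSet(setNames(seqs, utr_names))

    # per-cell read distribution over UTR/body regions:
    # trophoblast 5'-biased, endothelium 3'-biased
    probs <- ifelse(meta$cell_type == "trophoblast", 1, 2)
    tot <- rpois(nrow(meta), 100) + 1L
    pm <- rbind(trophoblast = c(0.40, 0.45, 0.15),
                endothelial = c(0.20, 0.30, 0.50))
    reg <- t(vapply(seq_len(nrow(meta)), function(i) {
      as.integer(rmultinom(1L, tot[i], pm[meta$cell_type[i], ]))
    }, integer(3)))
    utr_counts <- data.frame(cell_id = meta$cell_id,
                             cell_group = meta$cell_type,
                             five_utr = reg[, 1L], body = reg[, 2L],
                             three_utr = reg[, 3L])

    ac <- cfg$allele_cfg
    pat_allele <- setdiff(intersect(ac$father, ac$progeny), ac$mother)
    mat_allele <- setdiff(ac$progeny, pat_allele)
    if (length(mat_allele) == 0L) mat_allele <- ac$progeny[1L]
    reads <- do.call(rbind, lapply(names(ac$reads_per_group), function(g) {
      nr <- ac$reads_per_group[[g]]
      pat <- runif(nr) < ac$paternal_fraction
      data.frame(read_id = paste0(g, "_r", seq_len(nr)),
                 cell_barcode = paste0(g, "_bc",
                                       sample(seq_len(max(2L, nr %/% 3L)),
                                              nr, replace = TRUE)),
                 cell_group = g,
                 base = ifelse(pat, pat_allele[1L], mat_allele[1L]))
    }))
    rownames(reads) <- NULL
    attr(reads, "trio") <- list(snp = ac$snp, mother = ac$mother,
                                father = ac$father, progeny = ac$progeny)

    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         meta = meta[, c("cell_id", "cell_type", "phenotype")],
         acc = acc, utrs = utrs, utr_counts = utr_counts, allele = reads,
         truth = list(cargo = cargo, reject_de = rej_de,
                      reject_access = rej_acc, background = bg,
                      motif = motif_seq))
  })
}
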