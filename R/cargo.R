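# VLP cargo-gene identification, 3'UTR read bias, allele-of-origin tracing,
# and UTR motif discovery / similarity.

#' Identify VLP cargo genes from DE and chromatin accessibility
#'
#' A cargo gene is a transcript present (differentially expressed) in the
#' receiver endothelial cells while its locus is completely inaccessible
#' there. In `mode = "all"`: `|log2FC| > lfc_cut` OR `p_adj < padj_cut` in
#' the endothelial DE, AND completely inaccessible (no called peak and
#' fragment-presence score below `eps`) in both PE and control
#' endothelium. In `mode = "pe_specific"` the expression arm must be
#' positive (`log2FC > lfc_cut` OR `p_adj < padj_cut`), the trophoblast DE
#' must also be up (`log2FC > lfc_cut` OR `p_adj < padj_cut`), and the
#' locus must carry accessible peaks in trophoblast. Genes missing from
#' the accessibility table are excluded with a message.
#'
#' @param de_endo DE table ([wilcoxon_de()]) for PE vs control receiver
#'   endothelial cells.
#' @param de_troph DE table for PE vs control trophoblast (used by
#'   `pe_specific` mode).
#' @param acc Accessibility table: `data.frame(gene, cell_type,
#'   accessible, score)` with endothelial cell types named
#'   `endothelial_PE` / `endothelial_control` and a `trophoblast` row.
#' @param mode `"all"` or `"pe_specific"`.
#' @param lfc_cut,padj_cut Thresholds of the expression criterion.
#' @param eps Inaccessibility score bound (a locus counts as completely
#'   inaccessible only when `!accessible` and `score < eps`).
#' @return `data.frame` with one row per evaluated gene, logical columns
#'   for each criterion (`crit_de_endo`, `crit_inaccessible_endo`, plus
#'   `crit_de_troph`, `crit_accessible_troph` in `pe_specific` mode) and
#'   `selected`. The selected gene names are attached as attribute
#'   `cargo_genes`.
#' @export
identify_cargo <- function(de_endo, de_troph = NULL, acc,
                           mode = c("all", "pe_specific"),
                           lfc_cut = 0.5, padj_cut = 0.01, eps = 0.01) {
  mode <- match.arg(mode)
  if (nrow(de_endo) == 0L) {
    out <- data.frame(gene = character(), crit_de_endo = logical(),
                      crit_inaccessible_endo = logical(),
                      selected = logical())
    attr(out, "cargo_genes") <- character(0)
    return(out)
  }
  endo_types <- unique(acc$cell_type[grepl("endothelial", acc$cell_type)])
  inaccessible <- vapply(de_endo$gene, function(g) {
    rows <- acc[acc$gene == g & acc$cell_type %in% endo_types, ]
    nrow(rows) == length(endo_types) &&
      all(!rows$accessible & rows$score < eps)
  }, logical(1))
  covered <- de_endo$gene %in% acc$gene
  if (any(!covered))
    message(sum(!covered), " gene(s) missing from accessibility table; ",
            "excluded")
  if (mode == "all") {
    crit_de <- abs(de_endo$log2_fc) > lfc_cut | de_endo$p_adj < padj_cut
    out <- data.frame(gene = de_endo$gene, crit_de_endo = crit_de,
                      crit_inaccessible_endo = inaccessible & covered)
    out$selected <- covered & out$crit_de_endo & out$crit_inaccessible_endo
  } else {
    check_that(!is.null(de_troph), "pe_specific mode needs de_troph")
    crit_de <- de_endo$log2_fc > lfc_cut | de_endo$p_adj < padj_cut
    tro <- de_troph[match(de_endo$gene, de_troph$gene), ]
    crit_tro <- !is.na(tro$gene) &
      (tro$log2_fc > lfc_cut | tro$p_adj < padj_cut)
    acc_tro <- vapply(de_endo$gene, function(g) {
      rows <- acc[acc$gene == g & acc$cell_type == "trophoblast", ]
      nrow(rows) > 0L && all(rows$accessible)
    }, logical(1))
    out <- data.frame(gene = de_endo$gene, crit_de_endo = crit_de,
                      crit_de_troph = crit_tro,
                      crit_accessible_troph = acc_tro,
                      crit_inaccessible_endo = inaccessible & covered)
    out$selected <- covered & crit_de & crit_tro & acc_tro &
      out$crit_inaccessible_endo
  }
  rownames(out) <- NULL
  attr(out, "cargo_genes") <- out$gene[out$selected]
  out
}

#' 3'UTR read-fraction bias between cell groups
#'
#' For each cell group the 3'UTR fraction is
#' `three_utr / (five_utr + body + three_utr)`. When per-cell counts are
#' given, trophoblast and non-trophoblast per-cell fractions are compared
#' by a two-sided rank-sum test. Groups with zero total reads get a
#' missing fraction.
#'
#' @param counts `data.frame` with columns `cell_group`, `five_utr`,
#'   `body`, `three_utr` (one row per cell, or one per group).
#' @param trophoblast_groups Values of `cell_group` counted as
#'   trophoblast.
#' @return List with `group_fractions` (`data.frame(cell_group,
#'   fraction)`), `trophoblast_fraction`, `non_trophoblast_fraction`, and
#'   `p_value` (`NA` when per-cell counts are unavailable).
#' @export
utr_bias <- function(counts, trophoblast_groups = "trophoblast") {
  check_that(all(counts$five_utr >= 0 & counts$body >= 0 &
                   counts$three_utr >= 0), "counts must be non-negative")
  tot_by <- function(rows) {
    tot <- sum(rows$five_utr + rows$body + rows$three_utr)
    if (tot == 0) NA_real_ else sum(rows$three_utr) / tot
  }
  groups <- unique(counts$cell_group)
  gf <- data.frame(cell_group = groups,
                   fraction = vapply(groups, function(g)
                     tot_by(counts[counts$cell_group == g, ]), numeric(1)),
                   row.names = NULL)
  is_tro <- counts$cell_group %in% trophoblast_groups
  tro_frac <- tot_by(counts[is_tro, ])
  non_frac <- tot_by(counts[!is_tro, ])
  cell_tot <- counts$five_utr + counts$body + counts$three_utr
  p <- NA_real_
  if (sum(is_tro) > 1L && sum(!is_tro) > 1L) {
    f <- counts$three_utr / cell_tot
    ok <- cell_tot > 0
    p <- suppressWarnings(
      wilcox.test(f[is_tro & ok], f[!is_tro & ok])$p.value)
  }
  list(group_fractions = gf, trophoblast_fraction = tro_frac,
       non_trophoblast_fraction = non_frac, p_value = p)
}

#' Trace the parental origin of transcripts at a trio-informative SNP
#'
#' The paternal-specific allele is the allele carried by the father and
#' the progeny but absent from the mother; if no such allele exists
#' (e.g. the mother is heterozygous for the candidate) the trio is
#' uninformative and an error is raised. Per cell group, reads matching
#' either progeny allele are informative; a group is called a fetal
#' transcript when its paternal-allele fraction exceeds `threshold`.
#'
#' @param reads `data.frame(read_id, cell_barcode, cell_group, base)`
#'   with a `trio` attribute (list with `mother`, `father`, `progeny`
#'   allele pairs), or pass `trio` explicitly.
#' @param trio Optional trio list overriding the attribute.
#' @param threshold Paternal fraction above which a group is called a
#'   fetal transcript (default 0.95).
#' @return List with `paternal_allele`, `maternal_allele`, and
#'   `per_group` (`data.frame(cell_group, n_reads, n_informative,
#'   n_paternal, paternal_fraction, fetal_call)`).
#' @export
trace_allele <- function(reads, trio = attr(reads, "trio"),
                         threshold = 0.95) {
  check_that(!is.null(trio), "trio genotypes required")
  pat <- setdiff(intersect(trio$father, trio$progeny), trio$mother)
  if (length(pat) == 0L)
    stop("uninformative trio: no paternal-specific allele ",
         "(the mother carries every candidate allele)", call. = FALSE)
  pat <- pat[1L]
  mat <- setdiff(trio$progeny, pat)
  if (length(mat) == 0L) mat <- trio$progeny[1L]
  groups <- unique(reads$cell_group)
  per_group <- do.call(rbind, lapply(groups, function(g) {
    b <- reads$base[reads$cell_group == g]
    inf <- b %in% trio$progeny
    npat <- sum(b == pat)
    frac <- if (sum(inf) == 0L) NA_real_ else npat / sum(inf)
    data.frame(cell_group = g, n_reads = length(b),
               n_informative = sum(inf), n_paternal = npat,
               paternal_fraction = frac,
               fetal_call = !is.na(frac) && frac > threshold)
  }))
  rownames(per_group) <- NULL
  list(paternal_allele = pat, maternal_allele = mat[1L],
       per_group = per_group)
}

seq_windows <- function(seqs, width) {
  unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < width) return(character(0))
    substring(s, seq_len(n - width + 1L), seq_len(n - width + 1L) + width - 1L)
  }), use.names = FALSE)
}

hamming <- function(a, b) {
  mapply(function(x, y) sum(strsplit(x, "")[[1L]] != y),
         a, MoreArgs = list(y = strsplit(b, "")[[1L]]), USE.NAMES = FALSE)
}

#' Discover the dominant UTR motif as a position weight matrix
#'
#' Seeds on the most frequent exact width-mer across the sequences, then
#' aligns every window within Hamming distance `floor(width / 4)` of the
#' seed and averages base frequencies with a pseudocount of 0.25 per
#' base per position.
#'
#' @param utrs Character vector or [Biostrings::DNAStringSet] of at least
#'   5 sequences, each at least `width` long.
#' @param width Motif width (>= 4).
#' @return A `motif_pwm`: 4 x width probability matrix (rows A, C, G, T;
#'   columns sum to 1) with attributes `consensus` and `n_occurrences`.
#' @export
motif_discover <- function(utrs, width = 8L) {
  seqs <- toupper(as.character(utrs))
  check_that(length(seqs) >= 5L, "need at least 5 sequences")
  check_that(all(nchar(seqs) >= width),
             "every sequence must be at least `width` long")
  check_that(width >= 4L, "width must be >= 4")
  win <- seq_windows(seqs, width)
  win <- win[!grepl("[^ACGT]", win)]
  tab <- sort(table(win), decreasing = TRUE)
  if (length(tab) == 0L || tab[1L] < 2L)
    stop("no width-mer occurring at least twice", call. = FALSE)
  seed <- names(tab)[1L]
  d_max <- floor(width / 4)
  hits <- win[hamming(win, seed) <= d_max]
  mat <- do.call(rbind, strsplit(hits, ""))
  pwm <- vapply(seq_len(width), function(j) {
    cnt <- table(factor(mat[, j], levels = c("A", "C", "G", "T"))) + 0.25
    as.numeric(cnt / sum(cnt))
  }, numeric(4))
  rownames(pwm) <- c("A", "C", "G", "T")
  structure(pwm, class = "motif_pwm",
            consensus = paste(rownames(pwm)[apply(pwm, 2, which.max)],
                              collapse = ""),
            n_occurrences = length(hits))
}

# Mean column-wise Pearson correlation at one alignment offset.
pwm_offset_sim <- function(a, b, offset, min_overlap) {
  wa <- ncol(a); wb <- ncol(b)
  ia <- max(1L, 1L + offset); ib <- max(1L, 1L - offset)
  len <- min(wa - ia + 1L, wb - ib + 1L)
  if (len < min_overlap) return(NA_real_)
  cols <- vapply(seq_len(len) - 1L, function(k) {
    x <- a[, ia + k]; y <- b[, ib + k]
    if (sd(x) == 0 || sd(y) == 0) 0 else cor(x, y)
  }, numeric(1))
  mean(cols)
}

#' Pearson similarity of two PWMs
#'
#' Maximum over alignment offsets (minimum overlap `min_overlap` columns)
#' of the mean column-wise Pearson correlation between overlapping
#' columns; a degenerate constant column contributes 0.
#'
#' @param pwm_a,pwm_b 4 x width probability matrices.
#' @param min_overlap Minimum aligned columns (default 4).
#' @return Similarity in `[-1, 1]`.
#' @export
pwm_similarity <- function(pwm_a, pwm_b, min_overlap = 4L) {
  offsets <- seq(-(ncol(pwm_b) - min_overlap), ncol(pwm_a) - min_overlap)
  sims <- vapply(offsets, function(o)
    pwm_offset_sim(pwm_a, pwm_b, o, min_overlap), numeric(1))
  max(sims, na.rm = TRUE)
}

#' Similarity of two motifs with a background Z-score
#'
#' The similarity of `pwm_a` and `pwm_b` ([pwm_similarity()]) is placed
#' against the distribution of similarities between `pwm_a` and a
#' background motif collection: `z = (sim - mean(bg)) / sd(bg)`.
#'
#' @param pwm_a,pwm_b 4 x width probability matrices.
#' @param background List of at least 20 background PWMs.
#' @param min_overlap Minimum aligned columns.
#' @return List with `similarity`, `z`, `background_mean`,
#'   `background_sd`.
#' @export
motif_similarity_z <- function(pwm_a, pwm_b, background,
                               min_overlap = 4L) {
  check_that(length(background) >= 20L,
             "background must contain at least 20 motifs")
  sim <- pwm_similarity(pwm_a, pwm_b, min_overlap)
  bg <- vapply(background, function(m)
    pwm_similarity(pwm_a, m, min_overlap), numeric(1))
  list(similarity = sim, z = (sim - mean(bg)) / sd(bg),
       background_mean = mean(bg), background_sd = sd(bg))
}

#' Cell-type correlation of cargo-gene expression profiles
#'
#' Pearson correlation between all cell types over the mean expression of
#' the cargo genes; one matrix per phenotype is obtained by calling this
#' on each phenotype's mean-expression matrix.
#'
#' @param mean_expr Cargo-gene x cell-type matrix of mean expression
#'   (>= 3 genes).
#' @return Symmetric correlation matrix with unit diagonal; correlations
#'   involving a constant column are `NA`.
#' @export
cargo_expression_correlation <- function(mean_expr) {
  check_that(nrow(mean_expr) >= 3L, "need at least 3 cargo genes")
  suppressWarnings(cc <- cor(as.matrix(mean_expr)))
  diag(cc) <- 1
  cc
}
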