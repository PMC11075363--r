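# Single-cell differential expression, module scoring, origin assignment,
# and imprinted-gene direction statistics.

#' Library-size log-normalization of a count matrix
#'
#' Counts are scaled to `scale_factor` per cell and log1p-transformed
#' (the standard single-cell "LogNormalize").
#'
#' @param counts Genes x cells matrix (dense or sparse).
#' @param scale_factor Per-cell target sum (default 1e4).
#' @return A sparse genes x cells matrix of normalized expression.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / cs)
  dimnames(norm) <- dimnames(counts)
  log1p(norm)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Genes whose expressed fraction reaches `min_pct` in either group are
#' tested by a two-sided rank-sum test on log-normalized expression.
#' Fold change follows the log-normalized mean convention:
#' `avg_logFC = log(mean(expm1(norm_a)) + 1) - log(mean(expm1(norm_b)) + 1)`
#' on the natural-log scale; `log2_fc` is the same quantity in base 2.
#' P-values are Bonferroni-adjusted over the tested genes only. The
#' conventional significance call is `p_adj < 0.05 & |log2FC| > 0.5`.
#'
#' @param counts Genes x cells count matrix.
#' @param cells_a,cells_b Column names (or indices) of the two groups.
#' @param min_pct Minimum expressed fraction in at least one group
#'   (default 0.1).
#' @param norm Optional pre-computed normalized matrix (from
#'   [log_normalize()]); computed from `counts` when `NULL`.
#' @return `data.frame(gene, avg_logFC, log2_fc, pct1, pct2, p_value,
#'   p_adj, significant)`, one row per tested gene.
#' @export
wilcoxon_de <- function(counts, cells_a, cells_b, min_pct = 0.1,
                        norm = NULL) {
  check_that(length(cells_a) > 0L && length(cells_b) > 0L,
             "both groups must be non-empty")
  if (is.null(norm)) norm <- log_normalize(counts)
  a <- as.matrix(norm[, cells_a, drop = FALSE])
  b <- as.matrix(norm[, cells_b, drop = FALSE])
  ca <- as.matrix(counts[, cells_a, drop = FALSE])
  cb <- as.matrix(counts[, cells_b, drop = FALSE])
  pct1 <- rowMeans(ca > 0)
  pct2 <- rowMeans(cb > 0)
  expressed <- pct1 > 0 | pct2 > 0
  tested <- expressed & pmax(pct1, pct2) >= min_pct
  genes <- rownames(counts)[tested]
  p <- vapply(which(tested), function(i) {
    suppressWarnings(wilcox.test(a[i, ], b[i, ])$p.value)
  }, numeric(1))
  lfc <- log(rowMeans(expm1(a[tested, , drop = FALSE])) + 1) -
    log(rowMeans(expm1(b[tested, , drop = FALSE])) + 1)
  p_adj <- pmin(p * length(p), 1)  # Bonferroni over tested genes
  out <- data.frame(gene = genes, avg_logFC = lfc, log2_fc = lfc / log(2),
                    pct1 = pct1[tested], pct2 = pct2[tested],
                    p_value = p, p_adj = p_adj)
  out$significant <- out$p_adj < 0.05 & abs(out$log2_fc) > 0.5
  rownames(out) <- NULL
  out
}

#' Select maternal/fetal origin marker genes from a DE table
#'
#' Markers must satisfy all three criteria: adjusted p below `p_cut`
#' (default 0.001), `|avg_logFC|` above `lfc_cut` (default 1, natural
#' log), and an expressed-fraction difference `|pct1 - pct2|` above
#' `dpct_cut` (default 0.3). The sign of the fold change decides the set:
#' positive fold changes mark the first (fetal) group.
#'
#' @param de DE table from [wilcoxon_de()] computed fetal vs maternal on
#'   reference-annotated cells.
#' @param p_cut,lfc_cut,dpct_cut The three criteria.
#' @return List with `fetal_markers` and `maternal_markers` (character
#'   vectors). A warning is raised when either set is empty.
#' @export
select_origin_markers <- function(de, p_cut = 0.001, lfc_cut = 1,
                                  dpct_cut = 0.3) {
  keep <- de$p_adj < p_cut & abs(de$avg_logFC) > lfc_cut &
    abs(de$pct1 - de$pct2) > dpct_cut
  fetal <- de$gene[keep & de$avg_logFC > 0]
  maternal <- de$gene[keep & de$avg_logFC < 0]
  if (length(fetal) == 0L || length(maternal) == 0L)
    warning("empty origin marker set; origin assignment will refuse to run")
  list(fetal_markers = fetal, maternal_markers = maternal)
}

#' Gene-set module score with expression-bin-matched controls
#'
#' Genes are binned into `n_bins` by their average normalized expression
#' across cells; for each set gene, `n_ctrl` control genes are sampled
#' from its bin (with replacement when the bin is small). The per-cell
#' score is the mean expression of the set minus the mean over the pooled
#' control draws. Deterministic given `seed`.
#'
#' @param norm Normalized genes x cells matrix ([log_normalize()]).
#' @param gene_set Character vector of set genes; genes absent from the
#'   matrix are dropped with a warning.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes sampled per set gene (default 100).
#' @param seed Integer seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(norm, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 42L) {
  check_that(length(gene_set) > 0L, "gene_set must be non-empty")
  missing <- setdiff(gene_set, rownames(norm))
  if (length(missing)) {
    warning("dropping ", length(missing), " set gene(s) absent from matrix")
    gene_set <- setdiff(gene_set, missing)
  }
  check_that(length(gene_set) > 0L, "no set gene present in matrix")
  avg <- Matrix::rowMeans(norm)
  brk <- quantile(avg, probs = seq(0, 1, length.out = n_bins + 1L),
                  names = FALSE)
  brk[1L] <- -Inf; brk[length(brk)] <- Inf
  bin <- cut(avg, breaks = unique(brk), labels = FALSE)
  ctrl <- with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      # sorted pool => draws depend only on bin membership, not row order
      pool <- sort(rownames(norm)[bin == bin[match(g, rownames(norm))]])
      sample(pool, n_ctrl, replace = TRUE)
    }), use.names = FALSE)
  })
  set_mean <- Matrix::colMeans(norm[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  setNames(as.numeric(set_mean - ctrl_mean), colnames(norm))
}

#' Assign maternal or fetal origin from module scores
#'
#' Each cell is labeled by the larger of its two scores; exact ties are
#' `"unassigned"`.
#'
#' @param score_maternal,score_fetal Per-cell module scores (same cells,
#'   same order).
#' @return Character vector in `{maternal, fetal, unassigned}`.
#' @export
assign_origin <- function(score_maternal, score_fetal) {
  check_that(length(score_maternal) == length(score_fetal),
             "scores must cover the same cells")
  ifelse(score_maternal > score_fetal, "maternal",
         ifelse(score_fetal > score_maternal, "fetal", "unassigned"))
}

#' Imprinted-gene up/down direction summary with Fisher's exact test
#'
#' Restricting a PE-vs-control DE table to annotated imprinted genes,
#' counts significantly up- and down-regulated genes per expressed-allele
#' class and tests the 2x2 {paternal, maternal} x {up, down} table by a
#' two-sided Fisher exact test. "Up"/"down" uses the module's global
#' significance rule (`p_adj < 0.05` and `|log2FC| > 0.5`).
#'
#' @param de DE table from [wilcoxon_de()] (PE vs control in one lineage).
#' @param ann `data.frame(gene, expressed_allele)` with
#'   `expressed_allele` in `{maternal, paternal}` (experimentally
#'   validated imprinted genes only).
#' @param p_cut,log2fc_cut Significance rule for up/down.
#' @return List with `counts` (2x2 matrix, rows paternal/maternal, cols
#'   up/down), `odds_ratio` (sample OR), and `p_value` (`NA` with a
#'   message when a class is empty).
#' @export
imprint_direction_summary <- function(de, ann, p_cut = 0.05,
                                      log2fc_cut = 0.5) {
  check_that(!anyDuplicated(ann$gene), "one annotation record per gene")
  m <- merge(de, ann, by = "gene")
  sig <- m$p_adj < p_cut & abs(m$log2_fc) > log2fc_cut
  m <- m[sig, , drop = FALSE]
  dir <- ifelse(m$log2_fc > 0, "up", "down")
  counts <- matrix(0L, 2L, 2L,
                   dimnames = list(c("paternal", "maternal"),
                                   c("up", "down")))
  tb <- table(factor(m$expressed_allele,
                     levels = c("paternal", "maternal")),
              factor(dir, levels = c("up", "down")))
  counts[] <- as.integer(tb)
  odds <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  if (any(rowSums(counts) == 0L) || any(colSums(counts) == 0L)) {
    message("empty class in imprint table; Fisher test undefined")
    return(list(counts = counts, odds_ratio = odds, p_value = NA_real_))
  }
  list(counts = counts, odds_ratio = odds,
       p_value = fisher.test(counts)$p.value)
}
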