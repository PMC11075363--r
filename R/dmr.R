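# Differentially methylated locus / region calling.
#
# The pipeline is: per-CpG Welch t-test (DML) -> merge nearby DMLs into
# candidates -> t-test on per-sample averaged betas (seeds) -> circular
# binary segmentation of the per-CpG beta-difference track -> k-means
# clustering of segment means -> finalize DMRs from clusters whose segments
# fully encompass a seed.

beta_group_matrices <- function(table) {
  list(pe = as.matrix(table[cpg_samples(table, "PE")]),
       ct = as.matrix(table[cpg_samples(table, "nonPE")]))
}

row_welch <- function(a, b) {
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- (rowSums(a^2, na.rm = TRUE) - na * ma^2) / pmax(na - 1, 1)
  vb <- (rowSums(b^2, na.rm = TRUE) - nb * mb^2) / pmax(nb - 1, 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  d <- ma - mb
  se2 <- va / na + vb / nb
  tt <- d / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * pmax(na - 1, 1)) +
                   vb^2 / (nb^2 * pmax(nb - 1, 1)))
  p <- 2 * pt(-abs(tt), df)
  # degenerate: zero variance in both groups
  zero <- se2 == 0
  p[zero & d == 0] <- 1
  p[zero & d != 0] <- 0
  list(delta = d, p = p, n_a = na, n_b = nb)
}

#' Call differentially methylated loci (DML)
#'
#' A CpG is a DML when the two-sided Welch t-test between PE and nonPE
#' betas gives p < `p_cut` and the group beta difference exceeds
#' `delta_cut` in absolute value. CpGs with fewer than 2 non-missing betas
#' in either group are skipped (the skipped count is attached as an
#' attribute and reported via a message).
#'
#' @param table A [cpg_table()].
#' @param p_cut P-value cut-off (default 0.01).
#' @param delta_cut Minimum absolute beta difference (default 0.1).
#' @return `data.frame(chrom, pos, delta_beta, p_value)` of DMLs, sorted by
#'   position, with attribute `n_skipped`.
#' @export
call_dml <- function(table, p_cut = 0.01, delta_cut = 0.1) {
  stopifnot(inherits(table, "cpg_table"))
  m <- beta_group_matrices(table)
  testable <- rowSums(!is.na(m$pe)) >= 2L & rowSums(!is.na(m$ct)) >= 2L
  n_skipped <- sum(!testable)
  if (n_skipped > 0L)
    message(n_skipped, " CpG(s) skipped: <2 non-missing betas in a group")
  w <- row_welch(m$pe[testable, , drop = FALSE],
                 m$ct[testable, , drop = FALSE])
  keep <- w$p < p_cut & abs(w$delta) > delta_cut
  out <- data.frame(chrom = table$chrom[testable][keep],
                    pos = table$pos[testable][keep],
                    delta_beta = w$delta[keep], p_value = w$p[keep])
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Merge nearby DMLs into candidate DMR intervals
#'
#' Maximal runs of DMLs whose successive gaps are at most `gap_bp` become
#' candidate intervals `[first_pos - 1, last_pos)` in 0-based half-open
#' coordinates; singletons are allowed.
#'
#' @param dmls Output of [call_dml()] (sorted by chrom, pos).
#' @param gap_bp Maximum gap between successive DMLs (default 100).
#' @return `data.frame(chrom, start, end, n_dml)`.
#' @export
merge_dml <- function(dmls, gap_bp = 100) {
  if (nrow(dmls) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_dml = integer()))
  stopifnot(!is.unsorted(order(dmls$chrom, dmls$pos)))
  new_run <- c(TRUE, dmls$chrom[-1L] != dmls$chrom[-nrow(dmls)] |
                 diff(dmls$pos) > gap_bp)
  run <- cumsum(new_run)
  out <- data.frame(
    chrom = tapply(dmls$chrom, run, `[`, 1L),
    start = as.integer(tapply(dmls$pos, run, min) - 1L),
    end = as.integer(tapply(dmls$pos, run, max)),
    n_dml = as.integer(tapply(dmls$pos, run, length))
  )
  rownames(out) <- NULL
  out
}

cpg_in_interval <- function(table, chrom, start, end) {
  which(table$chrom == chrom & (table$pos - 1L) >= start &
          (table$pos - 1L) < end)
}

#' Select seed DMRs from candidate intervals
#'
#' For each candidate, betas are averaged per sample over the encompassed
#' CpGs and the group averages compared by a two-sided Welch t-test;
#' candidates with p < `p_cut` are kept as seeds.
#'
#' @param candidates Output of [merge_dml()].
#' @param table The [cpg_table()] the candidates came from.
#' @param p_cut P-value cut-off (default 0.01).
#' @return The retained candidates with columns `p_value` and `seed_id`.
#' @export
seed_dmr <- function(candidates, table, p_cut = 0.01) {
  stopifnot(inherits(table, "cpg_table"))
  if (nrow(candidates) == 0L)
    return(cbind(candidates, p_value = numeric(), seed_id = character()))
  m <- beta_group_matrices(table)
  p <- vapply(seq_len(nrow(candidates)), function(i) {
    idx <- cpg_in_interval(table, candidates$chrom[i],
                           candidates$start[i], candidates$end[i])
    stopifnot(length(idx) >= 1L)  # impossible by construction
    welch_p(colMeans(m$pe[idx, , drop = FALSE], na.rm = TRUE),
            colMeans(m$ct[idx, , drop = FALSE], na.rm = TRUE))[["p"]]
  }, numeric(1))
  out <- candidates[p < p_cut, , drop = FALSE]
  out$p_value <- p[p < p_cut]
  if (nrow(out)) out$seed_id <- sprintf("seed%04d", seq_len(nrow(out)))
  else out$seed_id <- character(0)
  rownames(out) <- NULL
  out
}

cbs_recurse <- function(x, alpha, nperm, early_stop) {
  n <- length(x)
  if (n < 4L) return(list(c(1L, n)))
  scan <- .cbs_scan(x)
  if (scan$t <= 0 || scan$i < 0) return(list(c(1L, n)))
  count <- .cbs_perm_count(x, scan$t, nperm, early_stop)
  p <- (1 + count) / (nperm + 1)
  if (p > alpha) return(list(c(1L, n)))
  pieces <- list()
  bounds <- sort(unique(c(0L, scan$i, scan$j, n)))
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b] + 1L; hi <- bounds[b + 1L]
    sub <- cbs_recurse(x[lo:hi], alpha, nperm, early_stop)
    pieces <- c(pieces, lapply(sub, function(r) r + lo - 1L))
  }
  pieces
}

#' Segment the per-CpG beta-difference track by circular binary segmentation
#'
#' Per chromosome, the ordered per-CpG beta differences (mean PE minus mean
#' nonPE) are segmented recursively: the arc of the circularized track
#' maximizing the pooled-variance two-sample t statistic against its
#' complement is accepted as a changepoint pair when its permutation
#' p-value is at most `alpha`, and the resulting pieces are re-segmented.
#' Segments tile each chromosome from the first to the last CpG.
#'
#' @param table A [cpg_table()].
#' @param alpha Permutation significance level for accepting a split.
#' @param nperm Number of permutations per tested split.
#' @param seed Integer seed for the permutation reference.
#' @return `data.frame(chrom, start, end, mean_delta_beta, n_cpg,
#'   segment_id)`; coordinates 0-based half-open.
#' @export
segment_delta <- function(table, alpha = 0.01, nperm = 1000, seed = 42L) {
  stopifnot(inherits(table, "cpg_table"))
  m <- beta_group_matrices(table)
  delta <- rowMeans(m$pe, na.rm = TRUE) - rowMeans(m$ct, na.rm = TRUE)
  early_stop <- max(1L, floor(alpha * (nperm + 1)))
  res <- with_seed(seed, {
    do.call(rbind, lapply(unique(table$chrom), function(ch) {
      idx <- which(table$chrom == ch)
      x <- delta[idx]
      pos <- table$pos[idx]
      ranges <- if (length(idx) < 4L) list(c(1L, length(idx)))
        else cbs_recurse(x, alpha, nperm, early_stop)
      ranges <- ranges[order(vapply(ranges, `[`, integer(1), 1L))]
      n_seg <- length(ranges)
      starts <- vapply(ranges, `[`, integer(1), 1L)
      ends <- vapply(ranges, `[`, integer(1), 2L)
      # tiling bounds: each segment starts at its first CpG and runs to the
      # next segment's first CpG (last runs to the final CpG's end)
      g_start <- pos[starts] - 1L
      g_end <- c(pos[starts[-1L]] - 1L, pos[length(pos)])
      data.frame(chrom = ch, start = g_start, end = g_end,
                 mean_delta_beta = vapply(seq_len(n_seg), function(i)
                   mean(x[starts[i]:ends[i]]), numeric(1)),
                 n_cpg = ends - starts + 1L)
    }))
  })
  res$segment_id <- sprintf("seg%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Cluster segments by mean beta difference (1-D k-means)
#'
#' K-means on the scalar segment means with deterministic quantile-spread
#' initial centers, so the result is independent of segment order and of
#' the RNG state. Cluster ids are relabeled in ascending order of cluster
#' centroid.
#'
#' @param segments Output of [segment_delta()].
#' @param k Number of clusters (must not exceed the number of segments).
#' @param seed Kept for interface stability; the initialization is
#'   deterministic and does not consume randomness.
#' @return `segments` with an integer `cluster_id` column; cluster
#'   centroids attached as attribute `centers`.
#' @export
cluster_segments <- function(segments, k = 6L, seed = 42L) {
  x <- segments$mean_delta_beta
  if (k > nrow(segments))
    stop("k exceeds the number of segments", call. = FALSE)
  ux <- sort(unique(x))
  if (k == 1L) {
    cl <- rep(1L, length(x))
    centers <- mean(x)
  } else if (length(ux) <= k) {
    # fewer distinct values than clusters: each value its own cluster
    cl <- match(x, ux)
    centers <- ux
  } else {
    init <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE,
                     type = 7)
    init <- init + seq(0, 1e-9, length.out = k)  # break exact ties
    fit <- tryCatch(
      kmeans(x, centers = matrix(init, ncol = 1), iter.max = 100L),
      error = function(e)  # Hartigan-Wong rejects empty clusters on
        suppressWarnings(  # near-degenerate tracks; Lloyd tolerates them
          kmeans(x, centers = matrix(init, ncol = 1), iter.max = 100L,
                 algorithm = "Lloyd")))
    keep <- which(fit$size > 0L)
    ord <- keep[order(fit$centers[keep, 1L])]
    cl <- match(fit$cluster, ord)
    centers <- fit$centers[ord, 1L]
  }
  segments$cluster_id <- cl
  attr(segments, "centers") <- centers
  segments
}

#' Finalize DMRs from clustered segments and seed intervals
#'
#' Clusters containing at least one segment that fully encompasses a seed
#' interval are selected; within selected clusters every seed-encompassing
#' segment becomes one DMR. Direction is `hypo` when the segment mean beta
#' difference is negative (PE lower), `hyper` otherwise.
#'
#' @param segments Output of [cluster_segments()].
#' @param seeds Output of [seed_dmr()].
#' @return `data.frame(chrom, start, end, direction, mean_delta_beta,
#'   n_cpg, segment_id, cluster_id, seed_ids)`.
#' @export
finalize_dmr <- function(segments, seeds) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      mean_delta_beta = numeric(), n_cpg = integer(),
                      segment_id = character(), cluster_id = integer(),
                      seed_ids = character())
  if (nrow(segments) == 0L || nrow(seeds) == 0L) {
    warning("no seed encompassed by any segment; no DMRs")
    return(empty)
  }
  enc <- lapply(seq_len(nrow(segments)), function(i) {
    hit <- seeds$chrom == segments$chrom[i] &
      seeds$start >= segments$start[i] & seeds$end <= segments$end[i]
    seeds$seed_id[hit]
  })
  has_seed <- lengths(enc) > 0L
  if (!any(has_seed)) {
    warning("no seed encompassed by any segment; no DMRs")
    return(empty)
  }
  selected_clusters <- unique(segments$cluster_id[has_seed])
  take <- has_seed & segments$cluster_id %in% selected_clusters
  out <- segments[take, c("chrom", "start", "end", "mean_delta_beta",
                          "n_cpg", "segment_id", "cluster_id")]
  out$direction <- ifelse(out$mean_delta_beta < 0, "hypo", "hyper")
  out$seed_ids <- vapply(enc[take], paste, character(1), collapse = ",")
  out <- out[, names(empty)]
  rownames(out) <- NULL
  out
}

#' Bisulfite conversion QC by unmethylated-CHH fraction
#'
#' A sample passes when its unmethylated-CHH fraction strictly exceeds
#' 0.99; a missing value fails with a reason.
#'
#' @param chh_fraction Named numeric vector of per-sample fractions in
#'   `[0, 1]` (NA allowed).
#' @return `data.frame(sample, fraction, pass, reason)`.
#' @export
conversion_qc <- function(chh_fraction) {
  check_that(all(is.na(chh_fraction) |
                   (chh_fraction >= 0 & chh_fraction <= 1)),
             "fractions must lie in [0, 1]")
  nm <- names(chh_fraction)
  if (is.null(nm)) nm <- paste0("sample", seq_along(chh_fraction))
  pass <- !is.na(chh_fraction) & chh_fraction > 0.99
  reason <- ifelse(is.na(chh_fraction), "missing value",
                   ifelse(pass, "", "CHH fraction <= 0.99"))
  data.frame(sample = nm, fraction = as.numeric(chh_fraction),
             pass = pass, reason = reason, row.names = NULL)
}

#' Run the full DMR-calling pipeline
#'
#' @param table A [cpg_table()].
#' @param gap_bp DML merge gap (default 100).
#' @param alpha Significance level used both for the DML/seed t-tests and
#'   the segmentation permutation test (default 0.01).
#' @param nperm Permutations per segmentation split.
#' @param k Number of k-means clusters of segment means; capped at the
#'   number of segments.
#' @param seed Seed for the segmentation permutation reference.
#' @return List with `dml`, `candidates`, `seeds`, `segments`, `dmrs`.
#' @examples
#' \donttest{
#' tab <- gen_methylation_cohort(sim_config(seed = 11, n_cpg = 800,
#'                                          chroms = "chr1"))
#' res <- call_dmrs(tab, nperm = 200, seed = 11)
#' res$dmrs
#' }
#' @export
call_dmrs <- function(table, gap_bp = 100, alpha = 0.01, nperm = 1000,
                      k = 6L, seed = 42L) {
  dml <- call_dml(table, p_cut = alpha)
  candidates <- merge_dml(dml, gap_bp = gap_bp)
  seeds <- seed_dmr(candidates, table, p_cut = alpha)
  if (nrow(seeds) == 0L) {
    # no seed can be encompassed, so no DMR can be finalized;
    # segmentation would not change the (empty) result
    segments <- data.frame(chrom = character(), start = integer(),
                           end = integer(), mean_delta_beta = numeric(),
                           n_cpg = integer(), segment_id = character(),
                           cluster_id = integer())
    dmrs <- suppressWarnings(finalize_dmr(segments, seeds))
  } else {
    segments <- segment_delta(table, alpha = alpha, nperm = nperm,
                              seed = seed)
    segments <- cluster_segments(segments, k = min(k, nrow(segments)),
                                 seed = seed)
    dmrs <- finalize_dmr(segments, seeds)
  }
  list(dml = dml, candidates = candidates, seeds = seeds,
       segments = segments, dmrs = dmrs)
}

#' Base-pair recall of planted DMR intervals
#'
#' Fraction of planted DMR base pairs covered by called DMR intervals.
#'
#' @param dmrs `data.frame(chrom, start, end)` of called DMRs.
#' @param planted `data.frame(chrom, start, end)` of planted truth.
#' @return A number in `[0, 1]`.
#' @export
dmr_recall <- function(dmrs, planted) {
  if (nrow(planted) == 0L) return(NA_real_)
  if (nrow(dmrs) == 0L) return(0)
  gr_d <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1L,
                                                  dmrs$end))
  gr_p <- GenomicRanges::GRanges(planted$chrom,
                                 IRanges::IRanges(planted$start + 1L,
                                                  planted$end))
  cov <- sum(IRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(gr_d), GenomicRanges::reduce(gr_p))))
  cov / sum(IRanges::width(GenomicRanges::reduce(gr_p)))
}
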