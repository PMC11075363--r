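# Broad histone-domain construction, RPKM quantification, the
# differential-domain rule, and region-overlap enrichment statistics.

# 0-based half-open data.frame -> GRanges (1-based closed) and back.
region_gr <- function(regions) {
  check_that(all(regions$start < regions$end), "regions need start < end")
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}

gr_region <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Merge peaks within a gap into broad domains
#'
#' Intervals whose gap is at most `gap_bp` (inclusive) are unioned; the
#' output is disjoint and sorted. Idempotent.
#'
#' @param peaks `data.frame(chrom, start, end)`, 0-based half-open.
#' @param gap_bp Maximum merge gap in bp (default 5000).
#' @return Merged `data.frame(chrom, start, end)`.
#' @export
merge_domains <- function(peaks, gap_bp = 5000) {
  if (nrow(peaks) == 0L) return(peaks[c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(region_gr(peaks),
                              min.gapwidth = gap_bp + 1L)
  out <- gr_region(gr)
  # lexicographic sort, independent of the seqlevel order of the input
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' RPKM normalization of domain read counts
#'
#' `rpkm = count / (length / 1000) / (lib_size / 1e6)` — reads per
#' kilobase of domain per million mapped library fragments.
#'
#' @param counts A [domain_count_table()].
#' @return Numeric matrix of RPKM, domains x samples, with the group
#'   labels attached as attribute `groups`.
#' @export
domain_rpkm <- function(counts) {
  stopifnot(inherits(counts, "domain_count_table"))
  rpkm <- counts$counts / (counts$lengths / 1000) /
    rep(counts$lib_sizes / 1e6, each = nrow(counts$counts))
  attr(rpkm, "groups") <- counts$groups
  rpkm
}

#' Differential-domain labels by the mean-shift-over-pooled-sd rule
#'
#' The statistic is `s = |mean(PE) - mean(control)| / (sd(PE) +
#' sd(control))`; a domain is differential when `s > cut` (default 2),
#' with direction by the sign of the mean difference. When both group sds
#' are zero the statistic is infinite if the means differ (flagged
#' differential) and the domain is `unchanged` otherwise.
#'
#' @param rpkm RPKM matrix from [domain_rpkm()] (or any matrix with a
#'   `groups` attribute / explicit `groups`).
#' @param groups Named character vector sample -> `"PE"` / `"control"`;
#'   defaults to the matrix's `groups` attribute.
#' @param cut Statistic threshold (default 2).
#' @return `data.frame(domain_id, mean_PE, mean_control, sd_PE,
#'   sd_control, statistic, label)` with `label` in
#'   `{PE_gain, PE_lost, unchanged}`.
#' @export
differential_domains <- function(rpkm, groups = attr(rpkm, "groups"),
                                 cut = 2) {
  check_that(!is.null(groups), "sample group labels required")
  pe <- rpkm[, names(groups)[groups == "PE"], drop = FALSE]
  ct <- rpkm[, names(groups)[groups == "control"], drop = FALSE]
  check_that(ncol(pe) >= 2L && ncol(ct) >= 2L,
             "need >= 2 samples per group")
  m_pe <- rowMeans(pe); m_ct <- rowMeans(ct)
  sd_pe <- apply(pe, 1L, sd); sd_ct <- apply(ct, 1L, sd)
  d <- m_pe - m_ct
  denom <- sd_pe + sd_ct
  s <- ifelse(denom == 0, ifelse(d == 0, 0, Inf), abs(d) / denom)
  label <- ifelse(s > cut, ifelse(d > 0, "PE_gain", "PE_lost"),
                  "unchanged")
  ids <- rownames(rpkm)
  if (is.null(ids)) ids <- sprintf("dom%04d", seq_len(nrow(rpkm)))
  data.frame(domain_id = ids, mean_PE = m_pe, mean_control = m_ct,
             sd_PE = sd_pe, sd_control = sd_ct, statistic = s,
             label = label, row.names = NULL)
}

#' Fisher's exact test of region-overlap enrichment
#'
#' Universe elements are cross-classified as {in query} x {overlapping
#' the target by >= 1 bp}; the 2x2 table is tested two-sided and the
#' sample odds ratio `(a*d)/(b*c)` reported.
#'
#' @param query `data.frame(chrom, start, end)` — a subset of the
#'   universe's elements.
#' @param target Target region set.
#' @param universe Universe region set (non-empty).
#' @return List with `table` (2x2), `odds_ratio` (sample OR), `p_value`.
#' @export
fisher_region_enrichment <- function(query, target, universe) {
  check_that(nrow(universe) > 0L, "universe must be non-empty")
  u <- region_gr(universe)
  hit_target <- GenomicRanges::countOverlaps(u, region_gr(target)) > 0L
  key <- function(r) paste(r$chrom, r$start, r$end)
  in_query <- key(universe) %in% key(query)
  tab <- matrix(c(sum(in_query & hit_target),
                  sum(in_query & !hit_target),
                  sum(!in_query & hit_target),
                  sum(!in_query & !hit_target)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("query", "not_query"),
                                c("overlap", "no_overlap")))
  odds <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, odds_ratio = odds,
       p_value = fisher.test(tab)$p.value)
}

#' Permutation test of query-target region overlap with a Z-score
#'
#' The observed statistic is the number of query intervals overlapping
#' the target by >= 1 bp. Each permutation relocates every query interval
#' uniformly at random within the genome space, preserving its length
#' and, by default, its chromosome (set `per_chromosome = FALSE` to
#' redraw chromosomes weighted by their length).
#' `z = (observed - mean_perm) / sd_perm`;
#' `p = (1 + #{perm >= observed}) / (n_perm + 1)` (greater-than
#' alternative). When the permutation sd is zero, `z` is `NA` and only
#' the empirical p is meaningful.
#'
#' @param query,target Region sets (`data.frame(chrom, start, end)`).
#' @param genome_space `data.frame(chrom, length)` of placeable space;
#'   every chromosome must fit its longest query interval.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param per_chromosome Keep each interval on its own chromosome.
#' @return List with `observed`, `perm_mean`, `perm_sd`, `z`,
#'   `p_empirical`.
#' @export
permutation_overlap_z <- function(query, target, genome_space,
                                  n_perm = 1000, seed = 42L,
                                  per_chromosome = TRUE) {
  glen <- setNames(as.numeric(genome_space$length), genome_space$chrom)
  widths <- query$end - query$start
  check_that(all(query$chrom %in% names(glen)),
             "every query chromosome must be in genome_space")
  check_that(all(widths <= glen[query$chrom]),
             "genome_space lengths must fit every query interval")
  # pre-merge the target once; a query interval [s, e) overlaps iff the
  # merged target interval at or before s extends past s, or the next one
  # starts before e — O(log n) per interval via findInterval
  tgt <- merge_domains(target, gap_bp = 0)
  tgt_by <- split(tgt[c("start", "end")], tgt$chrom)
  count_overlap <- function(chrom, start, end) {
    hits <- 0L
    for (ch in unique(chrom)) {
      t <- tgt_by[[ch]]
      sel <- chrom == ch
      if (is.null(t)) next
      idx <- findInterval(start[sel], t$start)
      left <- idx >= 1L & ifelse(idx >= 1L, t$end[pmax(idx, 1L)], 0) >
        start[sel]
      nxt <- pmin(idx + 1L, nrow(t))
      right <- idx < nrow(t) & t$start[nxt] < end[sel]
      hits <- hits + sum(left | right)
    }
    hits
  }
  observed <- count_overlap(query$chrom, query$start, query$end)
  nq <- nrow(query)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      chrom <- if (per_chromosome) query$chrom
        else sample(names(glen), nq, replace = TRUE, prob = glen)
      start <- floor(runif(nq, 0, glen[chrom] - widths + 1))
      count_overlap(chrom, start, start + widths)
    }, numeric(1))
  })
  sd_p <- sd(perm)
  list(observed = observed, perm_mean = mean(perm), perm_sd = sd_p,
       z = if (sd_p == 0) NA_real_ else (observed - mean(perm)) / sd_p,
       p_empirical = (1 + sum(perm >= observed)) / (n_perm + 1))
}
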