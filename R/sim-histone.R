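#' Construct a domain-by-sample read-count table
#'
#' @param counts Integer matrix, domains x samples (rownames = domain ids).
#' @param lengths Domain lengths in bp (> 0), one per row of `counts`.
#' @param lib_sizes Mapped-fragment library sizes, one per column.
#' @param groups Named character vector mapping sample names to
#'   `"PE"` / `"control"`.
#' @return A `domain_count_table` (a validated list).
#' @export
domain_count_table <- function(counts, lengths, lib_sizes, groups) {
  counts <- as.matrix(counts)
  check_that(all(counts >= 0), "counts must be >= 0")
  check_that(length(lengths) == nrow(counts) && all(lengths > 0),
             "lengths must be positive, one per domain")
  check_that(length(lib_sizes) == ncol(counts) && all(lib_sizes > 0),
             "lib_sizes must be positive, one per sample")
  check_that(all(colnames(counts) %in% names(groups)),
             "every sample needs a group label")
  structure(list(counts = counts, lengths = lengths,
                 lib_sizes = setNames(as.numeric(lib_sizes),
                                      colnames(counts)),
                 groups = groups[colnames(counts)]),
            class = "domain_count_table")
}

#' Simulate histone-domain coverage with planted differential domains
#'
#' Lays out non-overlapping broad domains, assigns each a baseline RPKM
#' mean, and plants `n_gain` PE-gained and `n_lost` PE-lost domains whose PE
#' group mean is shifted by `+/- shift` RPKM. Per-sample RPKM is drawn
#' normal (truncated at 0) around the group mean with sd `base_sd`, then
#' converted to read counts via each sample's library size.
#'
#' @param cfg A [sim_config()].
#' @return List with `domains` (a `data.frame` of 0-based half-open
#'   intervals with `domain_id` and the planted `truth` label in
#'   `{gain, lost, stable}`) and `counts` (a [domain_count_table()]).
#' @export
gen_histone_coverage <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dc <- cfg$domain_cfg
  check_that(dc$base_sd > 0, "group sds must be > 0")
  with_seed(substream_seed(cfg$seed, "histone"), {
    nd <- dc$n_domains
    n <- dc$n_samples_per_group
    chrom <- sample(cfg$chroms, nd, replace = TRUE)
    len <- sample(5000:50000, nd, replace = TRUE)
    start <- integer(nd)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      gaps <- sample(10000:100000, length(i), replace = TRUE)
      start[i] <- cumsum(gaps) + cumsum(c(0L, len[i][-length(i)]))
    }
    ord <- order(chrom, start)
    chrom <- chrom[ord]; start <- start[ord]; len <- len[ord]
    truth <- rep("stable", nd)
    planted <- sample(nd, dc$n_gain + dc$n_lost)
    truth[planted[seq_len(dc$n_gain)]] <- "gain"
    truth[planted[dc$n_gain + seq_len(dc$n_lost)]] <- "lost"

    mean_ctrl <- rep(dc$base_mean, nd)
    mean_pe <- mean_ctrl + ifelse(truth == "gain", dc$shift,
                                  ifelse(truth == "lost", -dc$shift, 0))
    mean_pe <- pmax(mean_pe, 0.5)
    draw_rpkm <- function(mu) {
      pmax(matrix(rnorm(nd * n, mu, dc$base_sd), nrow = nd), 0)
    }
    rpkm <- cbind(draw_rpkm(mean_pe), draw_rpkm(mean_ctrl))
    lib <- round(runif(2L * n, 2e7, 3e7))
    counts <- round(rpkm * (len / 1000) * rep(lib / 1e6, each = nd))
    s_pe <- sprintf("PE_%d", seq_len(n))
    s_ct <- sprintf("CTRL_%d", seq_len(n))
    ids <- sprintf("dom%04d", seq_len(nd))
    dimnames(counts) <- list(ids, c(s_pe, s_ct))
    groups <- setNames(rep(c("PE", "control"), each = n), c(s_pe, s_ct))
    list(domains = data.frame(chrom = chrom, start = start,
                              end = start + len, domain_id = ids,
                              truth = truth),
         counts = domain_count_table(counts, len, lib, groups))
  })
}
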