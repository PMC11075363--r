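#' Construct a per-CpG methylation beta table
#'
#' @param betas `data.frame` with columns `chrom`, `pos` (1-based CpG
#'   coordinate) and one numeric beta column per sample (values in `[0, 1]`
#'   or `NA`).
#' @param groups Named character vector mapping sample column names to
#'   `"PE"` / `"nonPE"`.
#' @return A `cpg_table`: the data frame with a `groups` attribute.
#' @export
cpg_table <- function(betas, groups) {
  check_that(all(c("chrom", "pos") %in% names(betas)),
             "betas must have chrom and pos columns")
  samples <- setdiff(names(betas), c("chrom", "pos"))
  check_that(length(samples) >= 4L, "need at least 2 samples per group")
  check_that(all(samples %in% names(groups)),
             "every sample column needs a group label")
  groups <- groups[samples]
  check_that(all(groups %in% c("PE", "nonPE")),
             "groups must be 'PE' or 'nonPE'")
  check_that(all(table(groups) >= 2L), "need >= 2 samples in each group")
  vals <- as.matrix(betas[samples])
  check_that(all(is.na(vals) | (vals >= 0 & vals <= 1)),
             "betas must lie in [0, 1] or be NA")
  ord <- order(betas$chrom, betas$pos)
  betas <- betas[ord, , drop = FALSE]
  for (ch in unique(betas$chrom)) {
    p <- betas$pos[betas$chrom == ch]
    check_that(all(diff(p) > 0),
               "positions must be strictly increasing within a chromosome")
  }
  rownames(betas) <- NULL
  structure(betas, groups = groups, class = c("cpg_table", "data.frame"))
}

#' Samples of a CpG table belonging to one group
#' @param x A `cpg_table`.
#' @param group `"PE"` or `"nonPE"`.
#' @return Character vector of sample names.
#' @export
cpg_samples <- function(x, group = c("PE", "nonPE")) {
  group <- match.arg(group)
  g <- attr(x, "groups")
  names(g)[g == group]
}

#' Simulate a methylation cohort with planted DMRs
#'
#' Betas are drawn per CpG per sample from Beta distributions: a CpG with
#' group mean `mu` and concentration `c` draws from `Beta(mu*c, (1-mu)*c)`.
#' Outside planted DMRs both groups share the baseline mean (drawn uniform
#' on `[0.35, 0.65]`); inside a planted DMR the PE mean is shifted by the
#' planted signed `delta_beta`. CpG positions are laid down with random
#' 20-80 bp gaps so that loci within a region merge under the 100 bp DML
#' merging rule.
#'
#' @param cfg A [sim_config()].
#' @return A [cpg_table()] with attribute `truth` (the planted DMR table).
#' @examples
#' tab <- gen_methylation_cohort(sim_config(seed = 1, n_cpg = 400))
#' attr(tab, "truth")
#' @export
gen_methylation_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(substream_seed(cfg$seed, "methylation"), {
    n_chrom <- length(cfg$chroms)
    per <- diff(round(seq(0, cfg$n_cpg, length.out = n_chrom + 1L)))
    chrom <- rep(cfg$chroms, per)
    pos <- unlist(lapply(per, function(n) {
      1000L + cumsum(sample(20:80, n, replace = TRUE))
    }), use.names = FALSE)
    mu <- runif(cfg$n_cpg, 0.35, 0.65)
    delta <- numeric(cfg$n_cpg)
    pd <- cfg$planted_dmrs
    if (nrow(pd)) {
      for (i in seq_len(nrow(pd))) {
        hit <- chrom == pd$chrom[i] &
          (pos - 1L) >= pd$start[i] & (pos - 1L) < pd$end[i]
        delta[hit] <- pd$delta_beta[i]
      }
    }
    mu_pe <- mu + delta
    if (any(mu_pe <= 0 | mu_pe >= 1))
      stop("invalid config: planted effect pushes a group mean outside (0,1)",
           call. = FALSE)
    n <- cfg$n_samples_per_group
    conc <- cfg$beta_noise_conc
    draw <- function(m) {
      matrix(rbeta(length(m) * n, rep(m * conc, n),
                   rep((1 - m) * conc, n)),
             ncol = n)
    }
    pe <- draw(mu_pe)
    ctl <- draw(mu)
    betas <- data.frame(chrom = chrom, pos = pos, pe, ctl)
    s_pe <- sprintf("PE%02d", seq_len(n))
    s_ct <- sprintf("N%02d", seq_len(n))
    names(betas) <- c("chrom", "pos", s_pe, s_ct)
    groups <- setNames(rep(c("PE", "nonPE"), each = n), c(s_pe, s_ct))
    out <- cpg_table(betas, groups)
    attr(out, "truth") <- pd
    out
  })
}
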