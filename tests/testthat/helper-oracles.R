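# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately re-derive results from first principles (base-R
# loops, closed forms) and never call the package functions they check.

# Per-CpG Welch t-test DML calling by explicit loop over rows.
oracle_call_dml <- function(table, p_cut = 0.01, delta_cut = 0.1) {
  pe_s <- names(attr(table, "groups"))[attr(table, "groups") == "PE"]
  ct_s <- names(attr(table, "groups"))[attr(table, "groups") == "nonPE"]
  rows <- lapply(seq_len(nrow(table)), function(i) {
    a <- as.numeric(table[i, pe_s]); b <- as.numeric(table[i, ct_s])
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    d <- mean(a) - mean(b)
    p <- if (var(a) == 0 && var(b) == 0) {
      if (d == 0) 1 else 0
    } else t.test(a, b)$p.value
    if (p < p_cut && abs(d) > delta_cut)
      data.frame(chrom = table$chrom[i], pos = table$pos[i],
                 delta_beta = d, p_value = p)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(),
                      delta_beta = numeric(), p_value = numeric())
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# Rank-sum p-value by explicit U statistic with tie correction and
# continuity correction (normal approximation).
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma <- sqrt(n1 * n2 / 12 *
                  ((n1 + n2 + 1) - sum(ties^3 - ties) /
                     ((n1 + n2) * (n1 + n2 - 1))))
  mu <- n1 * n2 / 2
  z <- u - mu
  z <- sign(z) * max(abs(z) - 0.5, 0)
  2 * min(pnorm(z / sigma), pnorm(-z / sigma), 0.5)
}

# Exact 1-D k-means by dynamic programming on sorted values: minimal total
# within-cluster sum of squares over contiguous partitions.
oracle_kmeans_1d_ss <- function(x, k) {
  x <- sort(x); n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssq <- function(i, j) {  # within-SS of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    q <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    q - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  for (j in seq_len(n)) dp[1, j] <- ssq(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n)
    dp[m, j] <- min(vapply((m - 1):(j - 1), function(t)
      dp[m - 1, t] + ssq(t + 1, j), numeric(1)))
  dp[k, n]
}

# Exhaustive single linear split maximizing the pooled-variance two-sample
# t statistic; returns the split index (last element of the left part).
oracle_best_split <- function(x) {
  n <- length(x)
  best_t <- -Inf; best_k <- NA_integer_
  for (k in 2:(n - 2)) {
    a <- x[1:k]; b <- x[(k + 1):n]
    sp <- sqrt(((k - 1) * var(a) + (n - k - 1) * var(b)) / (n - 2))
    tt <- abs(mean(a) - mean(b)) / (sp * sqrt(1 / k + 1 / (n - k)))
    if (is.finite(tt) && tt > best_t) { best_t <- tt; best_k <- k }
  }
  best_k
}

# Module score by direct restatement: bin genes by average expression,
# sample n_ctrl controls per set gene from its (sorted) bin, subtract.
oracle_module_score <- function(norm, gene_set, n_bins, n_ctrl, seed) {
  avg <- Matrix::rowMeans(norm)
  brk <- quantile(avg, probs = seq(0, 1, length.out = n_bins + 1),
                  names = FALSE)
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  bin <- cut(avg, breaks = unique(brk), labels = FALSE)
  set.seed(seed)
  ctrl <- unlist(lapply(gene_set, function(g) {
    pool <- sort(rownames(norm)[bin == bin[match(g, rownames(norm))]])
    sample(pool, n_ctrl, replace = TRUE)
  }))
  as.numeric(Matrix::colMeans(norm[gene_set, , drop = FALSE]) -
               Matrix::colMeans(norm[ctrl, , drop = FALSE]))
}

# Tiny deterministic CpG table builder: betas given as per-group mean plus
# a fixed perturbation pattern so tests control exact values.
make_cpg_table <- function(pos, mu_pe, mu_ct, n = 5, eps = 0.01,
                           chrom = "chr1") {
  pert <- seq(-eps, eps, length.out = n)
  pe <- outer(mu_pe, pert, `+`)
  ct <- outer(mu_ct, pert, `+`)
  df <- data.frame(chrom = chrom, pos = pos, pe, ct)
  names(df) <- c("chrom", "pos", paste0("PE", 1:n), paste0("N", 1:n))
  cpg_table(df, setNames(rep(c("PE", "nonPE"), each = n),
                         c(paste0("PE", 1:n), paste0("N", 1:n))))
}

# Cell metadata with exact per-donor immature fractions.
make_fraction_cells <- function(pe_fracs, ct_fracs, cells_per_donor = 20) {
  mk <- function(fracs, phen, prefix) {
    do.call(rbind, lapply(seq_along(fracs), function(i) {
      n_imm <- round(fracs[i] * cells_per_donor)
      data.frame(cell_id = paste0(prefix, i, "_", seq_len(cells_per_donor)),
                 lineage = "VCT", donor = paste0(prefix, i),
                 phenotype = phen, gestational_week = 38,
                 latent_time = c(rep(0.1, n_imm),
                                 rep(0.8, cells_per_donor - n_imm)),
                 cytotrace = c(rep(0.1, n_imm),
                               rep(0.8, cells_per_donor - n_imm)),
                 mitotic_age = 30, origin = "fetal")
    }))
  }
  rbind(mk(pe_fracs, "PE", "P"), mk(ct_fracs, "control", "C"))
}

random_pwm <- function(width = 8) {
  m <- matrix(rgamma(4 * width, 1), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2, colSums(m), "/")
}
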