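# DML calling, merging, seeding, segmentation, clustering, finalization.

test_that("call_dml matches a brute-force per-CpG Welch loop", {
  cfg <- sim_config(seed = 13, n_cpg = 200, chroms = "chr1",
                    n_samples_per_group = 5, beta_noise_conc = 20,
                    planted_dmrs = data.frame(chrom = "chr1",
                                              start = 3000L, end = 5000L,
                                              delta_beta = 0.25))
  tab <- gen_methylation_cohort(cfg)
  got <- call_dml(tab)
  want <- oracle_call_dml(tab)
  expect_gt(nrow(want), 0)
  expect_equal(got$pos, want$pos)
  expect_equal(got$delta_beta, want$delta_beta, tolerance = 1e-12)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
})

test_that("call_dml applies both thresholds and degenerate rules", {
  # identical groups: empty result
  tab <- make_cpg_table(pos = c(100L, 200L), mu_pe = c(0.5, 0.4),
                        mu_ct = c(0.5, 0.4))
  expect_equal(nrow(call_dml(tab)), 0)

  # small delta with tiny p is excluded; large delta with large p too
  tab2 <- make_cpg_table(pos = c(100L, 200L),
                         mu_pe = c(0.55, 0.5), mu_ct = c(0.50, 0.5),
                         eps = 0.001)
  # second CpG: delta 0.3 but within-group spread so wide p is large
  df <- as.data.frame(tab2)
  df[2, paste0("PE", 1:5)] <- c(0.05, 0.95, 0.1, 0.9, 0.9)
  df[2, paste0("N", 1:5)] <- c(0.9, 0.1, 0.9, 0.1, 0.1)
  tab2 <- cpg_table(df, attr(tab2, "groups"))
  out <- call_dml(tab2)
  expect_equal(nrow(out), 0)  # one fails delta rule, one fails p rule
  expect_true(abs(mean(as.numeric(df[2, paste0("PE", 1:5)])) -
                    mean(as.numeric(df[2, paste0("N", 1:5)]))) > 0.1)

  # all-missing CpG is skipped with a logged count
  df3 <- as.data.frame(make_cpg_table(pos = c(100L, 200L),
                                      mu_pe = c(0.8, 0.5),
                                      mu_ct = c(0.4, 0.5)))
  df3[2, paste0("PE", 1:5)] <- NA
  tab3 <- cpg_table(df3, attr(tab2, "groups"))
  expect_message(out3 <- call_dml(tab3), "skipped")
  expect_equal(attr(out3, "n_skipped"), 1L)
  expect_equal(out3$pos, 100L)
})

test_that("merge_dml groups runs by gap and handles edge cases", {
  dmls <- data.frame(chrom = "chr1", pos = c(100L, 150L, 500L),
                     delta_beta = 0.2, p_value = 1e-4)
  got <- merge_dml(dmls, gap_bp = 100)
  expect_equal(got$start, c(99L, 499L))
  expect_equal(got$end, c(150L, 500L))
  expect_equal(got$n_dml, c(2L, 1L))

  expect_equal(nrow(merge_dml(dmls[0, ])), 0)
  # zero gap: every DML its own candidate
  expect_equal(nrow(merge_dml(dmls, gap_bp = 0)), 3)
  # chromosome boundaries never merge
  dmls2 <- data.frame(chrom = c("chr1", "chr2"), pos = c(100L, 150L),
                      delta_beta = 0.2, p_value = 1e-4)
  expect_equal(nrow(merge_dml(dmls2)), 2)
})

test_that("seed_dmr tests averaged betas per candidate", {
  # consistent shift across CpGs: retained
  tab <- make_cpg_table(pos = seq(100L, 190L, by = 30L),
                        mu_pe = rep(0.7, 4), mu_ct = rep(0.4, 4))
  cand <- data.frame(chrom = "chr1", start = 99L, end = 190L, n_dml = 4L)
  expect_equal(nrow(seed_dmr(cand, tab)), 1)

  # alternating-sign deltas cancel on averaging: rejected
  tab2 <- make_cpg_table(pos = seq(100L, 190L, by = 30L),
                         mu_pe = c(0.7, 0.1, 0.7, 0.1),
                         mu_ct = c(0.1, 0.7, 0.1, 0.7))
  expect_equal(nrow(seed_dmr(cand, tab2)), 0)

  # single-CpG candidate reproduces the per-CpG p exactly
  tab3 <- make_cpg_table(pos = 100L, mu_pe = 0.7, mu_ct = 0.4)
  cand3 <- data.frame(chrom = "chr1", start = 99L, end = 100L, n_dml = 1L)
  s <- seed_dmr(cand3, tab3)
  expect_equal(s$p_value, oracle_call_dml(tab3)$p_value, tolerance = 1e-12)
})

test_that("segmentation finds planted changepoints and is deterministic", {
  # constant track: one segment per chromosome
  tab <- make_cpg_table(pos = seq(100L, 2100L, by = 40L),
                        mu_pe = rep(0.5, 51), mu_ct = rep(0.5, 51))
  seg <- segment_delta(tab, nperm = 200, seed = 1)
  expect_equal(nrow(seg), 1)

  # step track: 100 CpGs at 0 then 100 at +0.4, noise sd 0.05
  set.seed(99)
  mu <- rep(0.3, 200)
  pos <- seq(100L, by = 40L, length.out = 200L)
  delta <- c(rep(0, 100), rep(0.4, 100))
  pe <- outer(mu + delta, rep(0, 10), `+`) +
    matrix(rnorm(2000, 0, 0.05), 200)
  ct <- outer(mu, rep(0, 10), `+`) + matrix(rnorm(2000, 0, 0.05), 200)
  df <- data.frame(chrom = "chr1", pos = pos,
                   pmin(pmax(cbind(pe, ct), 0), 1))
  names(df) <- c("chrom", "pos", paste0("PE", 1:10), paste0("N", 1:10))
  tab2 <- cpg_table(df, setNames(rep(c("PE", "nonPE"), each = 10),
                                 names(df)[-(1:2)]))
  seg2 <- segment_delta(tab2, nperm = 300, seed = 2)
  expect_gte(nrow(seg2), 2)
  # the first changepoint boundary lies within +/-3 CpGs of index 100,
  # and agrees with the exhaustive single-split t oracle
  d <- rowMeans(as.matrix(df[paste0("PE", 1:10)])) -
    rowMeans(as.matrix(df[paste0("N", 1:10)]))
  k_oracle <- oracle_best_split(d)
  expect_lte(abs(k_oracle - 100), 3)
  cp_pos <- seg2$start[-1L]  # internal boundaries (0-based)
  expect_true(any(abs(cp_pos - (pos[k_oracle + 1] - 1)) <= 3 * 40))

  expect_identical(seg2, segment_delta(tab2, nperm = 300, seed = 2))
})

test_that("cluster_segments is exact on separated groups and order-invariant", {
  set.seed(8)
  means <- c(rnorm(10, -0.3, 0.005), rnorm(10, 0, 0.005),
             rnorm(10, 0.3, 0.005))
  segs <- data.frame(chrom = "chr1",
                     start = seq(0, by = 1000, length.out = 30),
                     end = seq(500, by = 1000, length.out = 30),
                     mean_delta_beta = means, n_cpg = 5L,
                     segment_id = sprintf("s%02d", 1:30))
  got <- cluster_segments(segs, k = 3)
  expect_equal(got$cluster_id, rep(1:3, each = 10))
  # optimal in total within-SS (exact 1-D dynamic-programming oracle)
  ss <- sum(vapply(1:3, function(c)
    sum((means[got$cluster_id == c] -
           mean(means[got$cluster_id == c]))^2), numeric(1)))
  expect_equal(ss, oracle_kmeans_1d_ss(means, 3), tolerance = 1e-10)

  # k = 1: single cluster; k > n: error
  expect_true(all(cluster_segments(segs, k = 1)$cluster_id == 1))
  expect_error(cluster_segments(segs, k = 31), "exceeds")

  # permuting rows leaves each segment's assignment unchanged
  perm <- sample(30)
  got_p <- cluster_segments(segs[perm, ], k = 3)
  expect_equal(got_p$cluster_id[order(perm)], got$cluster_id)
})

test_that("finalize_dmr requires full encompassment", {
  segs <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                     end = c(1000L, 2000L),
                     mean_delta_beta = c(0.3, -0.2), n_cpg = c(10L, 10L),
                     segment_id = c("s1", "s2"), cluster_id = c(1L, 2L))
  seeds <- data.frame(chrom = "chr1", start = 100L, end = 300L,
                      n_dml = 3L, p_value = 1e-5, seed_id = "seed1")
  got <- finalize_dmr(segs, seeds)
  expect_equal(nrow(got), 1)
  expect_equal(got$direction, "hyper")
  expect_equal(got$segment_id, "s1")
  expect_equal(got$seed_ids, "seed1")

  # seed straddling two segments: fully encompassed by neither -> no DMR
  straddle <- data.frame(chrom = "chr1", start = 900L, end = 1100L,
                         n_dml = 3L, p_value = 1e-5, seed_id = "seed2")
  expect_warning(none <- finalize_dmr(segs, straddle), "no seed")
  expect_equal(nrow(none), 0)

  # hypo direction from negative mean delta
  seeds2 <- data.frame(chrom = "chr1", start = 1200L, end = 1300L,
                       n_dml = 2L, p_value = 1e-4, seed_id = "seed3")
  expect_equal(finalize_dmr(segs, seeds2)$direction, "hypo")
})

test_that("planted DMRs are recovered and recovery grows with effect size", {
  cfg <- sim_config(seed = 21, n_cpg = 1500, chroms = c("chr1", "chr2"))
  tab <- gen_methylation_cohort(cfg)
  res <- call_dmrs(tab, nperm = 300, seed = 21)
  expect_gte(dmr_recall(res$dmrs, attr(tab, "truth")), 0.9)
  expect_true(all(res$dmrs$direction[res$dmrs$chrom == "chr1"] == "hyper"))
  expect_true(all(res$dmrs$direction[res$dmrs$chrom == "chr2"] == "hypo"))

  # monotonicity: recall never drops as |delta beta| rises
  recall_at <- function(effect) {
    mean(vapply(1:4, function(s) {
      cfg <- sim_config(seed = 100 + s, n_cpg = 800, chroms = "chr1",
                        planted_dmrs = data.frame(chrom = "chr1",
                                                  start = 8000L,
                                                  end = 10000L,
                                                  delta_beta = effect))
      tb <- gen_methylation_cohort(cfg)
      r <- suppressWarnings(call_dmrs(tb, nperm = 200, seed = s))
      dmr_recall(r$dmrs, attr(tb, "truth"))
    }, numeric(1)))
  }
  rec <- vapply(c(0.1, 0.2, 0.3), recall_at, numeric(1))
  expect_true(all(diff(rec) >= -0.02))
  expect_gte(rec[3], 0.9)
})

test_that("conversion QC uses a strict 99% rule", {
  got <- conversion_qc(c(a = 0.995, b = 0.99, c = 0.5, d = NA))
  expect_equal(got$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(got$reason[4], "missing")
})

test_that("DMR BED round-trips coordinates and direction", {
  dmrs <- data.frame(chrom = c("chr1", "chr2"), start = c(100L, 5000L),
                     end = c(900L, 5400L), direction = c("hyper", "hypo"),
                     mean_delta_beta = c(0.31, -0.22), n_cpg = c(12L, 5L),
                     segment_id = c("s1", "s9"), cluster_id = c(2L, 1L),
                     seed_ids = c("seed1", "seed2"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, path)
  back <- read_bed(path)
  expect_equal(back$chrom, dmrs$chrom)
  expect_equal(back$start, dmrs$start)
  expect_equal(back$end, dmrs$end)
  expect_equal(sub(";.*", "", back$name), dmrs$direction)
  expect_equal(back$score, floor(1000 * abs(dmrs$mean_delta_beta)))
})
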