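# Domain merging, RPKM, the differential rule, and overlap enrichment.

test_that("merge_domains uses an inclusive gap and is idempotent", {
  peaks <- data.frame(chrom = "chr1", start = c(100L, 5200L),
                      end = c(200L, 5300L))
  expect_equal(nrow(merge_domains(peaks, 5000)), 1)  # gap 5000: merged
  peaks2 <- data.frame(chrom = "chr1", start = c(100L, 5201L),
                       end = c(200L, 5300L))
  expect_equal(nrow(merge_domains(peaks2, 5000)), 2)  # gap 5001: not

  set.seed(4)
  rnd <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                    start = sample.int(1e6, 50))
  rnd$end <- rnd$start + sample.int(2e4, 50)
  m1 <- merge_domains(rnd)
  expect_identical(merge_domains(m1), m1)               # fixpoint
  expect_identical(merge_domains(rnd[sample(50), ]), m1) # order-invariant
  covered <- function(r) sum(r$end - r$start)
  expect_gte(covered(m1), covered(merge_domains(rnd, gap_bp = 0)))
})

test_that("RPKM arithmetic matches its definition", {
  tab <- domain_count_table(
    counts = matrix(c(100, 50), 1, 2, dimnames = list("d1", c("s1", "s2"))),
    lengths = 1000, lib_sizes = c(1e6, 1e6),
    groups = c(s1 = "PE", s2 = "control"))
  expect_equal(as.numeric(domain_rpkm(tab)), c(100, 50))

  set.seed(5)
  counts <- matrix(rpois(40, 500), 10, 4,
                   dimnames = list(sprintf("d%02d", 1:10),
                                   sprintf("s%d", 1:4)))
  lens <- sample(1000:50000, 10)
  libs <- runif(4, 1e7, 3e7)
  tab2 <- domain_count_table(counts, lens, libs,
                             setNames(rep(c("PE", "control"), 2),
                                      sprintf("s%d", 1:4)))
  got <- domain_rpkm(tab2)
  for (i in 1:10) for (j in 1:4)
    expect_equal(got[i, j], counts[i, j] / (lens[i] / 1000) /
                   (libs[j] / 1e6), tolerance = 1e-12)
})

test_that("differential rule, degenerate sds, and scale equivariance", {
  rpkm <- rbind(d1 = c(9, 10, 11, 3, 4, 5),    # s = 6/2 = 3 -> gain
                d2 = c(5, 6, 7, 5, 6, 7),      # equal means -> unchanged
                d3 = c(4, 4, 4, 8, 8, 8))      # sds zero, means differ
  colnames(rpkm) <- sprintf("s%d", 1:6)
  groups <- setNames(rep(c("PE", "control"), each = 3), colnames(rpkm))
  got <- differential_domains(rpkm, groups)
  expect_equal(got$label, c("PE_gain", "unchanged", "PE_lost"))
  expect_equal(got$statistic[1], 3)
  expect_equal(got$statistic[2], 0)
  expect_true(is.infinite(got$statistic[3]))

  got10 <- differential_domains(rpkm * 10, groups)
  expect_equal(got10$label, got$label)
})

test_that("planted differential domains are recovered at high shift", {
  # recall of the s > 2 rule at planted shift 3*(sd_PE + sd_ctrl), 3v3
  set.seed(42)
  n <- 200
  pe <- matrix(rnorm(3 * n, 12, 2), n)
  ct <- matrix(rnorm(3 * n, 0, 2), n)
  rpkm <- pmax(cbind(pe, ct), 0)
  colnames(rpkm) <- sprintf("s%d", 1:6)
  got <- differential_domains(rpkm,
                              setNames(rep(c("PE", "control"), each = 3),
                                       colnames(rpkm)))
  expect_gte(mean(got$label == "PE_gain"), 0.9)

  # generator end-to-end: planted gain/lost labels mostly recovered
  hc <- gen_histone_coverage(sim_config(seed = 10))
  dd <- differential_domains(domain_rpkm(hc$counts))
  tab <- table(truth = hc$domains$truth, called = dd$label)
  expect_gte(tab["gain", "PE_gain"] / sum(hc$domains$truth == "gain"), 0.7)
  expect_gte(tab["lost", "PE_lost"] / sum(hc$domains$truth == "lost"), 0.7)
})

test_that("Fisher enrichment matches hand-built contingency tables", {
  # universe of 40 elements; query = the 20 overlapping target
  universe <- data.frame(chrom = "chr1",
                         start = seq(0L, by = 1000L, length.out = 40))
  universe$end <- universe$start + 500L
  target <- data.frame(chrom = "chr1", start = universe$start[1:20],
                       end = universe$end[1:20])
  query <- universe[1:20, ]
  got <- fisher_region_enrichment(query, target, universe)
  expect_true(is.infinite(got$odds_ratio))
  expect_equal(got$p_value,
               fisher.test(matrix(c(20, 0, 0, 20), 2))$p.value,
               tolerance = 1e-12)

  # balanced 10/10/10/10 table: no association
  query2 <- universe[c(1:10, 21:30), ]
  got2 <- fisher_region_enrichment(query2, target, universe)
  expect_equal(got2$table, matrix(c(10L, 10L, 10L, 10L), 2,
                                  dimnames = dimnames(got2$table)))
  expect_equal(got2$odds_ratio, 1)
  expect_equal(got2$p_value, 1)

  # random subset: sample odds ratio near 1, p from fisher.test
  set.seed(11)
  query3 <- universe[sample(40, 20), ]
  got3 <- fisher_region_enrichment(query3, target, universe)
  a <- sum(query3$start < 20000)
  tab <- matrix(c(a, 20 - a, 20 - a, 20 - (20 - a)), 2, byrow = TRUE)
  expect_equal(got3$p_value, fisher.test(tab)$p.value, tolerance = 1e-12)
  expect_error(fisher_region_enrichment(query, target, universe[0, ]),
               "non-empty")
})

test_that("permutation overlap z: signal, calibration, planted enrichment", {
  genome <- data.frame(chrom = c("chr1", "chr2"),
                       length = c(2e6, 1.5e6))
  set.seed(21)
  target <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE))
  target$start <- floor(runif(40, 0, 1.2e6))
  target$end <- target$start + sample(5000:20000, 40, TRUE)

  # query = target: maximal observed count, strongly positive z
  got <- permutation_overlap_z(target, target, genome, n_perm = 200,
                               seed = 1)
  expect_equal(got$observed, 40)
  expect_gt(got$z, 3)
  expect_lt(got$p_empirical, 0.01)

  # planted enrichment: queries drawn 5x more often inside the target
  set.seed(42)
  inside <- sample(40, 25, replace = TRUE)
  q_in <- data.frame(chrom = target$chrom[inside],
                     start = target$start[inside])
  q_in$end <- q_in$start + 3000
  ch <- sample(c("chr1", "chr2"), 5, TRUE)
  q_out <- data.frame(chrom = ch,
                      start = floor(runif(5, 0, 1.9e6 - 3000)))
  q_out$end <- q_out$start + 3000
  got2 <- permutation_overlap_z(rbind(q_in, q_out), target, genome,
                                n_perm = 300, seed = 42)
  expect_gt(got2$z, 3)

  # degenerate: empty target -> sd 0, z undefined
  empty_t <- data.frame(chrom = "chr1", start = 1L, end = 2L)
  got3 <- permutation_overlap_z(q_out, empty_t, genome, n_perm = 50,
                                seed = 3)
  expect_true(is.na(got3$z) || is.finite(got3$z))
})
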