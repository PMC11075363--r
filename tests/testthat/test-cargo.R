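# Cargo filter, UTR bias, allele tracing, motif discovery and similarity.

fixture_de <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- gen_cargo_fixture(sim_config(seed = 42))
      meta <- fx$meta
      norm <- log_normalize(fx$counts)
      pick <- function(ty, ph)
        meta$cell_id[meta$cell_type == ty & meta$phenotype == ph]
      cache <<- list(
        fx = fx,
        de_endo = wilcoxon_de(fx$counts, pick("endothelial", "PE"),
                              pick("endothelial", "control"), norm = norm),
        de_tro = wilcoxon_de(fx$counts, pick("trophoblast", "PE"),
                             pick("trophoblast", "control"), norm = norm))
    }
    cache
  }
})

test_that("cargo filter is exact on the noiseless fixture (both modes)", {
  d <- fixture_de()
  truth <- d$fx$truth
  for (mode in c("all", "pe_specific")) {
    hits <- identify_cargo(d$de_endo, d$de_tro, d$fx$acc, mode = mode)
    expect_setequal(attr(hits, "cargo_genes"), truth$cargo)
  }
})

test_that("rejected controls report exactly the violated criterion", {
  d <- fixture_de()
  truth <- d$fx$truth
  hits <- identify_cargo(d$de_endo, d$de_tro, d$fx$acc, mode = "all")
  node <- hits[hits$gene %in% truth$reject_de, ]
  expect_true(all(!node$crit_de_endo))          # only the DE arm fails
  expect_true(all(node$crit_inaccessible_endo))
  open <- hits[hits$gene %in% truth$reject_access, ]
  expect_true(all(open$crit_de_endo))           # only accessibility fails
  expect_true(all(!open$crit_inaccessible_endo))

  # a gene up in endothelium but with an endothelial peak is rejected
  expect_false(any(truth$reject_access %in% attr(hits, "cargo_genes")))

  # empty DE: empty result
  empty <- identify_cargo(d$de_endo[0, ], d$de_tro, d$fx$acc)
  expect_equal(nrow(empty), 0)
})

test_that("3'UTR bias fractions and group comparison", {
  one <- data.frame(cell_group = "trophoblast", five_utr = 50,
                    body = 30, three_utr = 20)
  expect_equal(utr_bias(one)$group_fractions$fraction, 0.2)
  all3 <- data.frame(cell_group = "endothelial", five_utr = 0,
                     body = 0, three_utr = 10)
  expect_equal(utr_bias(all3)$group_fractions$fraction, 1)
  zero <- data.frame(cell_group = "endothelial", five_utr = 0,
                     body = 0, three_utr = 0)
  expect_true(is.na(utr_bias(zero)$group_fractions$fraction))

  d <- fixture_de()
  got <- utr_bias(d$fx$utr_counts)
  expect_gt(got$non_trophoblast_fraction, got$trophoblast_fraction)
  expect_lt(got$p_value, 1e-6)
})

test_that("allele tracing on the trio fixture is exact and order-invariant", {
  d <- fixture_de()
  res <- trace_allele(d$fx$allele)
  expect_equal(res$paternal_allele, "A")
  expect_true(all(res$per_group$paternal_fraction == 1))
  expect_true(all(res$per_group$fetal_call))

  # read order and barcode relabeling do not change fractions
  shuf <- d$fx$allele[sample(nrow(d$fx$allele)), ]
  shuf$cell_barcode <- rev(shuf$cell_barcode)
  attr(shuf, "trio") <- attr(d$fx$allele, "trio")
  res2 <- trace_allele(shuf)
  m <- match(res$per_group$cell_group, res2$per_group$cell_group)
  expect_equal(res2$per_group$paternal_fraction[m],
               res$per_group$paternal_fraction)

  # half/half reads: fraction 0.5, no fetal call
  half <- data.frame(read_id = paste0("r", 1:20), cell_barcode = "bc1",
                     cell_group = "g", base = rep(c("T", "A"), 10))
  trio <- list(mother = c("T", "T"), father = c("T", "A"),
               progeny = c("T", "A"))
  r <- trace_allele(half, trio = trio)
  expect_equal(r$per_group$paternal_fraction, 0.5)
  expect_false(r$per_group$fetal_call)

  # heterozygous mother: uninformative trio
  trio_bad <- list(mother = c("T", "A"), father = c("T", "A"),
                   progeny = c("T", "A"))
  expect_error(trace_allele(half, trio = trio_bad), "uninformative")
})

test_that("motif discovery recovers the planted consensus", {
  d <- fixture_de()
  pwm <- motif_discover(d$fx$utrs, width = 8)
  expect_equal(attr(pwm, "consensus"), d$fx$truth$motif)
  expect_equal(colSums(pwm), rep(1, 8), ignore_attr = TRUE)

  # 10% per-base noise: at least 7/8 consensus positions recovered
  fx_noisy <- gen_cargo_fixture(sim_config(seed = 42),
                                motif_mutate_prob = 0.1)
  pwm_n <- motif_discover(fx_noisy$utrs, width = 8)
  match_pos <- sum(strsplit(attr(pwm_n, "consensus"), "")[[1]] ==
                     strsplit(fx_noisy$truth$motif, "")[[1]])
  expect_gte(match_pos, 7)

  # random sequences: runs and returns a valid PWM (smoke)
  set.seed(1)
  rnd <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
    character(1))
  pwm_r <- motif_discover(rnd, width = 8)
  expect_equal(dim(pwm_r), c(4L, 8L))

  expect_error(motif_discover(rnd[1:3], 8), "at least 5")
})

test_that("motif similarity and background Z behave as expected", {
  set.seed(2)
  bg <- replicate(25, random_pwm(8), simplify = FALSE)
  d <- fixture_de()
  pwm <- motif_discover(d$fx$utrs, width = 8)
  expect_equal(pwm_similarity(pwm, pwm), 1.0, tolerance = 1e-12)

  # two independently generated UTR sets sharing the planted motif
  fx2 <- gen_cargo_fixture(sim_config(seed = 1))
  pwm2 <- motif_discover(fx2$utrs, width = 8)
  shared <- motif_similarity_z(pwm, pwm2, bg)
  expect_gt(shared$z, 2)

  # self-similarity dominates similarity to any background motif
  self_z <- motif_similarity_z(pwm, pwm, bg)$z
  others <- vapply(bg[1:5], function(b)
    motif_similarity_z(pwm, b, bg)$z, numeric(1))
  expect_true(all(self_z >= others))

  expect_error(motif_similarity_z(pwm, pwm2, bg[1:5]), "at least 20")
})

test_that("cargo expression correlation matrices", {
  set.seed(9)
  m <- matrix(rnorm(1000 * 4), 1000,
              dimnames = list(NULL, c("troph", "endo", "immune", "stroma")))
  m <- cbind(m, troph_copy = m[, "troph"])
  cc <- cargo_expression_correlation(m)
  expect_equal(cc["troph", "troph_copy"], 1, tolerance = 1e-12)
  off <- abs(cc[upper.tri(cc)])
  expect_lt(max(off[off < 0.99]), 0.1)  # independent columns near 0

  # planted shared trophoblast/endothelial profile is the max off-diagonal
  base <- rnorm(500)
  m2 <- cbind(troph = base + rnorm(500, 0, 0.2),
              endo = base + rnorm(500, 0, 0.2),
              immune = rnorm(500), stroma = rnorm(500))
  cc2 <- cargo_expression_correlation(m2)
  off2 <- cc2; diag(off2) <- NA
  expect_equal(max(off2, na.rm = TRUE), cc2["troph", "endo"])

  expect_error(cargo_expression_correlation(m2[1:2, ]), "at least 3")
  const <- cbind(a = rep(1, 10), b = rnorm(10), c = rnorm(10))
  ccc <- cargo_expression_correlation(const)
  expect_true(is.na(ccc["a", "b"]))
})
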