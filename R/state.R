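# Trophoblast developmental-state classification and aging-rate tests.

loglik_mix <- function(x, p) {
  sum(log(p$weights[1L] * dnorm(x, p$means[1L], p$sds[1L]) +
            p$weights[2L] * dnorm(x, p$means[2L], p$sds[2L]) + 1e-300))
}

em_once <- function(x, init, tol = 1e-8, max_iter = 500L) {
  p <- init
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d1 <- p$weights[1L] * dnorm(x, p$means[1L], p$sds[1L])
    d2 <- p$weights[2L] * dnorm(x, p$means[2L], p$sds[2L])
    tot <- d1 + d2 + 1e-300
    r <- d1 / tot
    n1 <- sum(r); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)  # component collapsed
    p$means <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    p$sds <- sqrt(c(sum(r * (x - p$means[1L])^2) / n1,
                    sum((1 - r) * (x - p$means[2L])^2) / n2))
    if (any(p$sds < 1e-6)) return(NULL)  # degenerate sd
    p$weights <- c(n1, n2) / length(x)
    ll <- loglik_mix(x, p)
    ll_trace <- c(ll_trace, ll)
    if (ll - ll_old < tol && it > 1L) break
    ll_old <- ll
  }
  p$responsibility <- r
  p$loglik <- ll_trace
  p
}

# k-means++-style 1-D init: first center uniform, second proportional to
# squared distance from the first.
kmpp_init_1d <- function(x) {
  c1 <- x[sample.int(length(x), 1L)]
  d2 <- (x - c1)^2
  if (sum(d2) == 0) c2 <- c1 + sd(x) + 1e-3
  else c2 <- x[sample.int(length(x), 1L, prob = d2)]
  sort(c(c1, c2))
}

#' Fit a two-component Gaussian mixture to latent times by EM
#'
#' Components are reported in ascending order of mean. Initialization is
#' k-means++ on the 1-D values under the given seed; EM iterates until the
#' log-likelihood gain falls below `tol` or 500 iterations. A degenerate
#' fit (a collapsing component sd) triggers a jittered restart, up to
#' `max_restarts`, after which an error is raised. Identical input values
#' are flagged degenerate (both means equal that value).
#'
#' @param latent_times Numeric vector, at least 50 values.
#' @param seed Integer seed for initialization.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_restarts Maximum jittered restarts on degeneracy.
#' @return Object of class `mixture_fit`: list with `means`, `sds`,
#'   `weights` (ascending by mean), `responsibility` (posterior of the
#'   lower component per value), `loglik` (per-iteration trace,
#'   non-decreasing), and `degenerate`.
#' @examples
#' x <- c(rnorm(300, 0.15, 0.08), rnorm(300, 0.56, 0.08))
#' fit <- fit_bimodal_latent(x, seed = 1)
#' fit$means
#' @export
fit_bimodal_latent <- function(latent_times, seed = 42L, tol = 1e-8,
                               max_restarts = 10L) {
  x <- latent_times[!is.na(latent_times)]
  check_that(length(x) >= 50L, "need at least 50 latent-time values")
  if (diff(range(x)) < 1e-12) {
    return(structure(list(means = c(x[1L], x[1L]), sds = c(0, 0),
                          weights = c(0.5, 0.5),
                          responsibility = rep(0.5, length(x)),
                          loglik = numeric(0), degenerate = TRUE),
                     class = "mixture_fit"))
  }
  with_seed(seed, {
    fit <- NULL
    for (r in seq_len(max_restarts)) {
      ctrs <- kmpp_init_1d(x)
      if (r > 1L) ctrs <- ctrs + rnorm(2L, 0, sd(x) / 4)
      init <- list(means = sort(ctrs), sds = rep(max(sd(x) / 2, 1e-3), 2L),
                   weights = c(0.5, 0.5))
      fit <- em_once(x, init, tol = tol)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop("EM degenerate after ", max_restarts, " restarts",
           call. = FALSE)
    ord <- order(fit$means)
    structure(list(means = fit$means[ord], sds = fit$sds[ord],
                   weights = fit$weights[ord],
                   responsibility = if (ord[1L] == 1L) fit$responsibility
                     else 1 - fit$responsibility,
                   loglik = fit$loglik, degenerate = FALSE),
              class = "mixture_fit")
  })
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture fit\n")
  cat(sprintf("  means:   %.4f / %.4f\n", x$means[1L], x$means[2L]))
  cat(sprintf("  sds:     %.4f / %.4f\n", x$sds[1L], x$sds[2L]))
  cat(sprintf("  weights: %.3f / %.3f\n", x$weights[1L], x$weights[2L]))
  if (x$degenerate) cat("  (degenerate fit)\n")
  invisible(x)
}

#' Flag immature trophoblasts by CytoTRACE and latent-time thresholds
#'
#' A cell is immature when its CytoTRACE score is strictly below
#' `cyto_thr` AND its latent time strictly below `latent_thr` (defaults
#' 0.2 / 0.4). Cells with a missing score are unclassified (`NA`).
#'
#' @param cells Cell metadata `data.frame` with `cytotrace` and
#'   `latent_time` columns (e.g. from [gen_trophoblast_cells()]).
#' @param cyto_thr CytoTRACE threshold.
#' @param latent_thr Latent-time threshold.
#' @return Logical vector (`NA` where a score is missing).
#' @export
classify_immature <- function(cells, cyto_thr = 0.2, latent_thr = 0.4) {
  check_that(all(c("cytotrace", "latent_time") %in% names(cells)),
             "cells must have cytotrace and latent_time columns")
  out <- cells$cytotrace < cyto_thr & cells$latent_time < latent_thr
  out[is.na(cells$cytotrace) | is.na(cells$latent_time)] <- NA
  out
}

#' Per-donor immature-trophoblast frequency and PE-vs-control t-test
#'
#' The immature fraction (immature trophoblasts over all trophoblasts, per
#' donor) is compared between phenotypes by a two-sided Welch t-test on
#' the donor fractions. With fewer than 2 donors in a phenotype the
#' fractions are still reported but the p-value is `NA`.
#'
#' @param cells Cell metadata with `lineage`, `donor`, `phenotype`,
#'   `cytotrace`, `latent_time`.
#' @param cyto_thr,latent_thr Passed to [classify_immature()].
#' @param lineages Lineages counted as trophoblast.
#' @return List with `fractions` (`data.frame(donor, phenotype, fraction,
#'   n_cells)`) and `p_value`.
#' @export
immature_frequency_test <- function(cells, cyto_thr = 0.2,
                                    latent_thr = 0.4,
                                    lineages = trophoblast_lineages()) {
  tro <- cells[cells$lineage %in% lineages, , drop = FALSE]
  check_that(nrow(tro) > 0L, "no trophoblast cells")
  imm <- classify_immature(tro, cyto_thr, latent_thr)
  fractions <- aggregate(list(fraction = imm),
                         by = list(donor = tro$donor,
                                   phenotype = tro$phenotype),
                         FUN = function(z) mean(z, na.rm = TRUE))
  n_cells <- aggregate(list(n_cells = imm),
                       by = list(donor = tro$donor,
                                 phenotype = tro$phenotype),
                       FUN = length)
  fractions <- merge(fractions, n_cells, by = c("donor", "phenotype"))
  pe <- fractions$fraction[fractions$phenotype == "PE"]
  ct <- fractions$fraction[fractions$phenotype == "control"]
  p <- if (length(pe) >= 2L && length(ct) >= 2L)
    welch_p(pe, ct)[["p"]] else NA_real_
  list(fractions = fractions, p_value = p)
}

#' Mitosis aging rate and per-lineage PE-vs-control rank-sum tests
#'
#' The per-cell rate is inferred mitotic age divided by gestational week.
#' Per lineage, PE and control rates are compared by a two-sided Wilcoxon
#' rank-sum test (raw p-values, no multiplicity adjustment).
#'
#' @param cells Cell metadata with `mitotic_age`, `gestational_week`,
#'   `lineage`, `phenotype`.
#' @return List with `rates` (the input plus an `aging_rate` column) and
#'   `tests` (`data.frame(lineage, n_PE, n_control, median_PE,
#'   median_control, p_value)`).
#' @export
mitosis_aging_rate <- function(cells) {
  check_that(all(cells$gestational_week > 0),
             "gestational_week must be > 0")
  cells$aging_rate <- cells$mitotic_age / cells$gestational_week
  tests <- do.call(rbind, lapply(unique(cells$lineage), function(ln) {
    z <- cells[cells$lineage == ln, ]
    pe <- z$aging_rate[z$phenotype == "PE"]
    ct <- z$aging_rate[z$phenotype == "control"]
    p <- if (length(pe) && length(ct))
      suppressWarnings(wilcox.test(pe, ct)$p.value) else NA_real_
    data.frame(lineage = ln, n_PE = length(pe), n_control = length(ct),
               median_PE = stats::median(pe),
               median_control = stats::median(ct), p_value = p)
  }))
  rownames(tests) <- NULL
  list(rates = cells, tests = tests)
}

#' Combined proliferation score from cell-cycle phase scores
#'
#' Convention used for visualizing cycling activity: the G2/M and S phase
#' scores of a cell are added into one scalar.
#'
#' @param g2m_score,s_score Numeric vectors of per-cell phase scores.
#' @return Numeric vector `g2m_score + s_score`.
#' @export
proliferation_score <- function(g2m_score, s_score) g2m_score + s_score
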