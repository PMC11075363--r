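# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a global seed and a stream name
#'
#' One global seed drives every generator; per-generator substreams are
#' derived by a stable polynomial hash of the stream name so that adding or
#' reordering generators never perturbs another generator's draws.
#'
#' @param seed Integer global seed.
#' @param name Character stream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit integer seed
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stop with a consistent message when a config/argument check fails.
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Welch two-sample t-test returning c(estimate_diff, p); handles the
# degenerate zero-variance cases the pipeline documents.
welch_p <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  d <- mean(a) - mean(b)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    p <- if (d == 0) 1 else 0
    return(c(diff = d, p = p))
  }
  se2 <- va / length(a) + vb / length(b)
  tstat <- d / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  c(diff = d, p = 2 * pt(-abs(tstat), df))
}
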