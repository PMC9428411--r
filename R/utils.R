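# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so generators are reproducible without clobbering the
#' session seed.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1103L + as.integer(offset) * 7919L) %% 2147483629L
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Row-wise variance of a numeric matrix without apply() overhead.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) stopf("need at least 2 columns to compute variances")
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

# Format numerics to 15 significant digits for bit-stable TSV round trips.
fmt_num <- function(x) sprintf("%.15g", x)

# Adjusted Rand index between two label vectors (used by the pipeline's own
# reporting; tests cross-check against mclust).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}
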