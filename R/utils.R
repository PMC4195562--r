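#' @keywords internal
"_PACKAGE"

## Internal helpers shared across stages.

#' Row-wise Pearson correlation between two matrices
#'
#' Correlates row i of `x` with row i of `y`. Rows with zero variance (or
#' fewer than 2 usable columns) yield `NA`.
#'
#' @param x,y numeric matrices of identical dimension.
#' @return numeric vector, one correlation per row.
#' @keywords internal
#' @noRd
rowwise_pcc <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sxx <- rowSums(xc^2)
  syy <- rowSums(yc^2)
  sxy <- rowSums(xc * yc)
  den <- sqrt(sxx * syy)
  r <- ifelse(den > 0, sxy / den, NA_real_)
  # numerical safety: clamp tiny overshoots
  pmin(pmax(r, -1), 1)
}

#' Row-wise Pearson correlation with pairwise NA exclusion
#'
#' Like [rowwise_pcc()] but tolerates NA entries: for each row, columns where
#' either matrix is NA are dropped. Rows with fewer than `min_n` usable
#' columns, or zero variance, yield NA.
#' @keywords internal
#' @noRd
rowwise_pcc_na <- function(x, y, min_n = 3L) {
  ok <- !(is.na(x) | is.na(y))
  x0 <- ifelse(ok, x, 0)
  y0 <- ifelse(ok, y, 0)
  n <- rowSums(ok)
  mx <- rowSums(x0) / n
  my <- rowSums(y0) / n
  xc <- (x0 - mx) * ok
  yc <- (y0 - my) * ok
  sxx <- rowSums(xc^2)
  syy <- rowSums(yc^2)
  sxy <- rowSums(xc * yc)
  den <- sqrt(sxx * syy)
  r <- ifelse(n >= min_n & den > 0, sxy / den, NA_real_)
  pmin(pmax(r, -1), 1)
}

## Derive independent per-stage seeds from one master seed, so that
## stage-level reruns reproduce full-run results. Values stay below 2^31.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
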