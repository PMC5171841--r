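# Internal helpers: seeded substreams and Spearman machinery.

# Derive a reproducible sub-seed < 2^31 from a base seed and a stream name, so
# that draws for one pipeline stage do not perturb another's.
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 32768L
  as.integer((abs(as.integer(seed)) %% 60000L) * 32768L + h)
}

withSubstream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substreamSeed(seed, name))
  expr
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes the Spearman correlation between two vectors over pairwise-complete
#' observations, using average ranks for ties, with the two-sided p-value from
#' the t-distribution approximation `t = rho * sqrt((n-2) / (1-rho^2))`.
#'
#' @param x,y Numeric vectors of equal length; `NA`s allowed.
#' @return A list with elements `rho`, `p` and `n` (pairwise-complete count).
#'   Degenerate inputs (fewer than 3 complete pairs, or a constant vector)
#'   yield `rho = NA`, `p = NA`.
#' @export
spearmanRho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  p <- .spearmanP(rho, n)
  list(rho = rho, p = p, n = n)
}

.spearmanP <- function(rho, n) {
  # two-sided p from the t approximation; |rho| = 1 maps to the smallest
  # representable positive p so that -log10(p) stays finite
  p <- ifelse(
    abs(rho) >= 1, .Machine$double.xmin,
    2 * stats::pt(abs(rho) * sqrt((n - 2) / (1 - rho^2)), df = n - 2,
                  lower.tail = FALSE)
  )
  pmax(p, .Machine$double.xmin)
}

# Spearman rho/p of each column of X against each column of Y, assuming no
# missing values (fast path: rank once, then Pearson via crossprod).
spearmanMatrix <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  rX <- apply(X, 2L, rank, ties.method = "average")
  rY <- apply(Y, 2L, rank, ties.method = "average")
  rho <- suppressWarnings(stats::cor(rX, rY))
  p <- .spearmanP(rho, n)
  dim(p) <- dim(rho); dimnames(p) <- dimnames(rho)
  list(rho = rho, p = p, n = n)
}
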