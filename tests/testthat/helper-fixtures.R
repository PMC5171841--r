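# Shared fixtures, built in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

# small simulated cohort reused across test files
smallSim <- function() {
  if (is.null(.fixture_env$smallSim)) {
    cfg <- simulationConfig(n_samples = 80L, n_probes = 1200L,
                            n_background_genes = 250L, seed = 42L)
    .fixture_env$smallSim <- simulateCohort(cfg)
  }
  .fixture_env$smallSim
}

# brute-force Spearman oracle: explicit rank formula + t-approximation,
# written independently of the package's vectorised path
bruteSpearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  rk <- function(v) {
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    out
  }
  rx <- rk(x); ry <- rk(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tt <- abs(rho) * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) .Machine$double.xmin else 2 * pt(tt, n - 2, lower.tail = FALSE)
  list(rho = rho, p = max(p, .Machine$double.xmin), n = n)
}

# enumerate all permutations of 1..m (m small)
allPermutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(m - 1L)
  out <- matrix(0L, nrow(sub) * m, m)
  r <- 0L
  for (i in seq_len(nrow(sub))) for (k in seq_len(m)) {
    row <- append(sub[i, ], m, after = k - 1L)
    r <- r + 1L
    out[r, ] <- row
  }
  out
}

permCache <- function(m) {
  key <- paste0("perm", m)
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- allPermutations(m)
  .fixture_env[[key]]
}

# exhaustive probability that position i of a random ordering is a strict
# extremum flanked by monotone runs of lengths l1 (left) and l2 (right)
enumTurnProb <- function(m, i, l1, l2) {
  P <- permCache(m)
  iL <- (i - l1):i
  iR <- i:(i + l2)
  rising <- function(idx) {
    rowSums(P[, idx[-1], drop = FALSE] >
              P[, idx[-length(idx)], drop = FALSE]) == length(idx) - 1L
  }
  falling <- function(idx) {
    rowSums(P[, idx[-1], drop = FALSE] <
              P[, idx[-length(idx)], drop = FALSE]) == length(idx) - 1L
  }
  mean((rising(iL) & falling(iR)) | (falling(iL) & rising(iR)))
}
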