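# Shared fixtures and independent oracles for the test suite.

# Random heterogeneous network built directly from matrices (no files).
rand_hetero <- function(seed, n = NULL, m = NULL, dens = 0.25) {
  set.seed(seed)
  if (is.null(n)) n <- sample(8:40, 1)
  if (is.null(m)) m <- sample(3:15, 1)
  A <- Matrix::rsparsematrix(n, n, dens, rand.x = stats::runif)
  A <- abs(A + Matrix::t(A)) / 2
  diag(A) <- 0
  A <- Matrix::drop0(A)
  B <- (Matrix::rsparsematrix(n, m, 0.3,
                              rand.x = function(k) rep(1, k)) != 0) * 1
  C <- Matrix::rsparsematrix(m, m, 0.4, rand.x = stats::runif)
  C <- abs(C + Matrix::t(C)) / 2
  diag(C) <- 0
  C <- Matrix::drop0(C)
  hetero_network(A, B, C, sprintf("p%02d", seq_len(n)),
                 sprintf("a%02d", seq_len(m)))
}

# Tiny 3-node instance: one PPI edge p1-p2 (w 0.8), one relation p1-a1,
# a single isolated-similarity ADR.
toy3 <- function() {
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 0.8, dims = c(2, 2))
  B <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(2, 1))
  C <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(1, 1))
  hetero_network(A, B, C, c("p1", "p2"), "a1")
}

# Closed-form stable probability: p = r (I - (1-r) M't)^{-1} p0 with
# dangling rows of M replaced by the restart distribution, matching the
# iterative redistribution rule.
dense_rwr <- function(model, p0, r) {
  Md <- as.matrix(model$M)
  if (any(model$dangling))
    Md[model$dangling, ] <- matrix(as.numeric(p0), sum(model$dangling),
                                   length(p0), byrow = TRUE)
  solve(diag(length(p0)) - (1 - r) * t(Md), r * as.numeric(p0))
}

# Independent Mann-Whitney AUC: per-fold fraction of candidates the test
# protein beat (midranks handle ties), averaged over folds.
mw_auc <- function(rank, size) mean((size - rank) / (size - 1))

# Exhaustive hypergeometric upper tail: enumerate every s-subset of 1..N
# and count overlaps with the special set 1..K.
enum_hyper_tail <- function(k, K, s, N) {
  if (s == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, s)
  ov <- if (s == 1L) as.numeric(draws <= K) else colSums(draws <= K)
  mean(ov >= k)
}

# Exhaustive threshold-sweep AUC oracle over normalized ranks: step
# integral of the empirical CDF on a fine enumeration of thresholds.
enum_auc <- function(nr) {
  th <- sort(unique(c(nr, 1)))
  prev <- 0
  area <- 0
  for (t in th) {
    area <- area + mean(nr <= prev) * (t - prev)
    prev <- t
  }
  area
}
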