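test_that("hypergeometric upper tail handles boundary configurations", {
  expect_equal(hypergeom_pvalue(0, 3, 5, 10), 1)
  expect_equal(hypergeom_pvalue(4, 4, 4, 4), 1)
  expect_error(hypergeom_pvalue(4, 3, 5, 10), "impossible")
  expect_error(hypergeom_pvalue(1, 5, 3, 4), "N")
})

test_that("p-values match exhaustive enumeration on small populations", {
  for (N in c(5, 8)) {
    for (K in 0:N) {
      for (s in 0:N) {
        for (k in 0:min(K, s)) {
          expect_equal(hypergeom_pvalue(k, K, s, N),
                       enum_hyper_tail(k, K, s, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the tail probability is non-increasing in the overlap", {
  for (cfg in list(c(5, 4, 12), c(3, 3, 10), c(8, 6, 20))) {
    K <- cfg[1]; s <- cfg[2]; N <- cfg[3]
    pv <- hypergeom_pvalue(0:min(K, s), K, s, N)
    expect_true(all(diff(pv) <= 1e-15))
  }
})

test_that("enrichment ranks neighbors of known proteins first", {
  # hub1 adjacent to all three known proteins, loner adjacent to none
  ii <- c(1, 1, 1, 5)
  jj <- c(2, 3, 4, 6)
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                            dims = c(6, 6))
  B <- Matrix::sparseMatrix(i = 2:4, j = rep(1, 3), x = 1, dims = c(6, 2))
  C <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(2, 2))
  net <- hetero_network(A, B, C, c("hub1", "k1", "k2", "k3", "loner", "far"),
                        c("a1", "a2"))
  res <- rank_by_enrichment(net, "a1")
  expect_identical(res$protein[1], "hub1")
  expect_lt(res$p_value[res$protein == "hub1"],
            res$p_value[res$protein == "loner"])
})

test_that("candidates with identical neighborhood statistics tie", {
  # p1 and p2 each adjacent only to the known protein p3
  A <- Matrix::sparseMatrix(i = c(1, 3, 2, 3), j = c(3, 1, 3, 2), x = 1,
                            dims = c(4, 4))
  B <- Matrix::sparseMatrix(i = 3, j = 1, x = 1, dims = c(4, 1))
  C <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(1, 1))
  net <- hetero_network(A, B, C, c("p1", "p2", "p3", "p4"), "a1")
  res <- rank_by_enrichment(net, "a1")
  expect_equal(res$rank[match(c("p1", "p2"), res$protein)], c(1.5, 1.5))
})

test_that("enrichment ranking equals the brute-force p-value table", {
  net <- rand_hetero(61, n = 12, m = 3)
  adr <- net$adrs[which.max(Matrix::colSums(net$B))]
  known <- known_proteins(net, adr)
  res <- rank_by_enrichment(net, adr)
  for (p in res$protein) {
    i <- match(p, net$proteins)
    nb <- which(net$A[i, ] != 0)
    k <- length(intersect(net$proteins[nb], known))
    s <- length(nb)
    want <- enum_hyper_tail(k, length(known), s, net$n)
    expect_equal(res$p_value[res$protein == p], want, tolerance = 1e-10)
  }
})

test_that("enrichment ranking is invariant to protein index permutation", {
  net <- rand_hetero(71, n = 10, m = 3)
  set.seed(1)
  perm <- sample(net$n)
  net2 <- hetero_network(net$A[perm, perm], net$B[perm, ],
                         net$C, net$proteins[perm], net$adrs)
  adr <- net$adrs[which.max(Matrix::colSums(net$B))]
  r1 <- rank_by_enrichment(net, adr)
  r2 <- rank_by_enrichment(net2, adr)
  m <- match(r1$protein, r2$protein)
  expect_equal(r1$rank, r2$rank[m])
  expect_equal(r1$p_value, r2$p_value[m])
})

test_that("PPI-only walk from a star hub scores all leaves equally", {
  n <- 6
  A <- Matrix::sparseMatrix(i = c(rep(1, n - 1), 2:n),
                            j = c(2:n, rep(1, n - 1)), x = 1, dims = c(n, n))
  B <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(n, 1))
  C <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(1, 1))
  net <- hetero_network(A, B, C, c("hub", sprintf("leaf%d", 1:(n - 1))), "a1")
  res <- rwr_ppi(net, "a1", seed_proteins = "hub")
  expect_lt(diff(range(res$score)), 1e-12)
  expect_true(all(res$rank == mean(seq_len(n - 1))))
})

test_that("PPI-only walk matches the dense solve and conserves probability", {
  net <- rand_hetero(81, n = 30, m = 4)
  adr <- net$adrs[which.max(Matrix::colSums(net$B))]
  seeds <- known_proteins(net, adr)
  res <- rwr_ppi(net, adr, r = 0.7, tol = 1e-12, exclude = character(0))
  # reconstruct the protein-only model for the oracle
  deg <- Matrix::rowSums(net$A)
  Mp <- Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0)) %*% net$A
  model <- list(M = Mp, dangling = deg == 0)
  p0 <- numeric(net$n)
  p0[match(seeds, net$proteins)] <- 1 / length(seeds)
  want <- dense_rwr(model, p0, 0.7)
  got <- res$score[match(net$proteins, res$protein)]
  expect_lt(max(abs(got - want)), 1e-8)
  expect_equal(sum(got), 1, tolerance = 1e-9)
})

test_that("the integrated walk with lambda = 0, eta = 0 reduces to the PPI-only walk", {
  net <- rand_hetero(91, n = 25, m = 6)
  adr <- net$adrs[which.max(Matrix::colSums(net$B))]
  seeds <- known_proteins(net, adr)
  expect_gte(length(seeds), 1)
  a <- inpadr_rank(net, adr, lambda = 0, eta = 0, tol = 1e-12)
  b <- rwr_ppi(net, adr, tol = 1e-12)
  m <- match(a$protein, b$protein)
  expect_lt(max(abs(a$score - b$score[m])), 1e-10)
  expect_identical(a$rank, b$rank[m])
})

test_that("gold-standard filtering keeps ADRs with at least two proteins", {
  rel <- data.frame(protein = c("p1", "p1", "p2", "p1", "p2", "p3"),
                    adr = c("a1", "a2", "a2", "a3", "a3", "a3"))
  out <- filter_gold_for_rwr(rel)
  expect_equal(nrow(out), 5L)
  expect_false("a1" %in% out$adr)
  expect_setequal(unique(out$adr), c("a2", "a3"))
})
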