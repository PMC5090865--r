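test_that("initial probability splits mass (1 - eta)/eta over seeds and ADR", {
  net <- rand_hetero(4, n = 10, m = 3)
  spec <- seed_spec("a01", c("p01", "p02"), eta = 0.5)
  p0 <- initial_probability(spec, net)
  expect_equal(unname(p0[c("p01", "p02")]), c(0.25, 0.25))
  expect_equal(unname(p0["a01"]), 0.5)
  expect_equal(sum(p0), 1)

  p1 <- initial_probability(seed_spec("a01", c("p01", "p02"), eta = 1), net)
  expect_equal(unname(p1["a01"]), 1)
  expect_equal(sum(p1 != 0), 1)

  expect_warning(
    p2 <- initial_probability(seed_spec("a02", character(), eta = 0.5), net),
    "no seed proteins")
  expect_equal(unname(p2["a02"]), 1)

  expect_error(initial_probability(seed_spec("zz"), net), "focus ADR")
  expect_error(initial_probability(seed_spec("a01", "nope"), net),
               "seed protein")
})

test_that("restart probability 1 returns the seed distribution immediately", {
  net <- rand_hetero(8, n = 12, m = 4)
  model <- build_transition(net, 0.5)
  p0 <- suppressWarnings(
    initial_probability(seed_spec("a01", known_proteins(net, "a01")), net))
  w <- rwr_walk(model, p0, r = 1)
  expect_equal(w$iterations, 1L)
  expect_true(w$converged)
  expect_equal(unname(w$p), unname(as.numeric(p0)))
})

test_that("the converged vector satisfies the fixed-point equation", {
  net <- rand_hetero(15, n = 20, m = 6)
  model <- build_transition(net, 0.5)
  p0 <- suppressWarnings(
    initial_probability(seed_spec("a02", known_proteins(net, "a02")), net))
  tol <- 1e-10
  w <- rwr_walk(model, p0, r = 0.7, tol = tol)
  lost <- sum(w$p[model$dangling])
  resid <- (1 - 0.7) * (as.numeric(Matrix::crossprod(model$M, w$p)) +
                          lost * as.numeric(p0)) + 0.7 * as.numeric(p0) - w$p
  expect_lt(sum(abs(resid)), 10 * tol)
})

test_that("the iterative walk matches the dense closed-form solve", {
  net <- rand_hetero(21, n = 18, m = 7)
  model <- build_transition(net, 0.5)
  p0 <- suppressWarnings(
    initial_probability(seed_spec("a03", known_proteins(net, "a03")), net))
  w <- rwr_walk(model, p0, r = 0.7, tol = 1e-12)
  expect_lt(max(abs(w$p - dense_rwr(model, p0, 0.7))), 1e-8)
})

test_that("probability is conserved at every step, isolated nodes included", {
  # network with an isolated protein (p4) and an isolated ADR (a2)
  A <- Matrix::sparseMatrix(i = c(1, 2, 2, 3), j = c(2, 1, 3, 2), x = 0.7,
                            dims = c(4, 4))
  B <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(4, 3))
  C <- Matrix::sparseMatrix(i = c(1, 3), j = c(3, 1), x = 0.4, dims = c(3, 3))
  net <- hetero_network(A, B, C, sprintf("p%d", 1:4), sprintf("a%d", 1:3))
  model <- build_transition(net, 0.5)
  expect_gt(sum(model$dangling), 0)  # p4 and a2 are fully isolated
  p0 <- initial_probability(seed_spec("a2", "p4", eta = 0.5), net)
  for (k in 1:8) {
    pk <- suppressWarnings(rwr_walk(model, p0, r = 0.7, tol = 0,
                                    max_iter = k))$p
    expect_equal(sum(pk), 1, tolerance = 1e-9)
  }
})

test_that("non-convergence returns the last iterate with a warning", {
  net <- rand_hetero(6, n = 10, m = 4)
  model <- build_transition(net, 0.5)
  p0 <- suppressWarnings(
    initial_probability(seed_spec("a01", known_proteins(net, "a01")), net))
  expect_warning(w <- rwr_walk(model, p0, r = 0.1, tol = 1e-16,
                               max_iter = 3L),
                 "did not converge")
  expect_false(w$converged)
  expect_equal(w$iterations, 3L)
})

test_that("stable probability decays with distance from the seed on a chain", {
  n <- 10
  A <- Matrix::sparseMatrix(i = c(1:(n - 1), 2:n), j = c(2:n, 1:(n - 1)),
                            x = 1, dims = c(n, n))
  B <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, 1))
  C <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(1, 1))
  net <- hetero_network(A, B, C, sprintf("p%02d", 1:n), "a1")
  model <- build_transition(net, 0)
  p0 <- initial_probability(seed_spec("a1", "p01", eta = 0), net)
  w <- rwr_walk(model, p0, r = 0.7)
  scores <- w$p[seq_len(n)]
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("candidates are ranked descending with midrank ties", {
  net <- rand_hetero(2, n = 5, m = 2)
  stable <- c(p01 = 0.3, p02 = 0.2, p03 = 0.1, p04 = 0.2, p05 = 0,
              a01 = 0.1, a02 = 0.1)
  res <- rank_candidates(stable, net, "a01", exclude = "p01")
  expect_identical(res$protein[1:2], c("p02", "p04"))  # tie broken by id
  expect_equal(res$rank[1:2], c(1.5, 1.5))
  expect_equal(sort(res$rank), sort(rank(-res$score, ties.method = "average")))
  expect_equal(attr(res, "n_candidates"), 4L)

  expect_warning(empty <- rank_candidates(stable, net, "a01",
                                          exclude = net$proteins),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("top_k truncates at the candidate count and keeps k = 1 argmax", {
  net <- rand_hetero(12, n = 30, m = 5)
  res <- suppressWarnings(inpadr_rank(net, "a01"))
  expect_equal(nrow(top_k(res, 50)), nrow(res))  # fewer candidates than 50
  expect_identical(top_k(res, 1)$protein, res$protein[which.max(res$score)])
  expect_equal(nrow(top_k(res, 5)), 5)
})

test_that("identical queries yield identical rankings", {
  net <- rand_hetero(19, n = 25, m = 6)
  r1 <- suppressWarnings(inpadr_rank(net, "a02"))
  r2 <- suppressWarnings(inpadr_rank(net, "a02"))
  expect_identical(r1$protein, r2$protein)
  expect_identical(r1$score, r2$score)
  expect_identical(r1$rank, r2$rank)
})
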