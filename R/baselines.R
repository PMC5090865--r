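# Comparison methods: hypergeometric enrichment and the PPI-only walk.

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `k` members of a `K`-element special
#' set in a draw of `s` items from a population of `N` (over-representation
#' test). Vectorized over `k`, `K`, `s` with scalar recycling.
#'
#' @param k Observed overlap.
#' @param K Size of the special set (e.g. an ADR's known proteins).
#' @param s Size of the draw (e.g. a protein's PPI neighborhood).
#' @param N Population size.
#' @return `P(X >= k)` with `X ~ Hypergeometric(N, K, s)`; 1 when `k = 0`.
#' @export
hypergeom_pvalue <- function(k, K, s, N) {
  ln <- max(length(k), length(K), length(s), length(N))
  k <- rep_len(k, ln); K <- rep_len(K, ln)
  s <- rep_len(s, ln); N <- rep_len(N, ln)
  if (any(k < 0 | K < 0 | s < 0 | N < 0) || any(K > N) || any(s > N))
    stop("need 0 <= K <= N and 0 <= s <= N", call. = FALSE)
  if (any(k > pmin(K, s)))
    stop("impossible configuration: k exceeds min(K, s)", call. = FALSE)
  phyper(k - 1, K, N - K, s, lower.tail = FALSE)
}

#' Rank candidates by hypergeometric enrichment of their PPI neighborhood
#'
#' Network-based enrichment baseline: each candidate protein is scored by
#' the over-representation of the focus ADR's known proteins among its PPI
#' neighbors. For candidate `p` with neighborhood size `s`, overlap `k`
#' with the `K` known proteins, and `N` indexed proteins, the score is the
#' upper-tail hypergeometric p-value; candidates are ranked by ascending
#' p-value with midrank ties. This contingency construction (PPI
#' neighborhood against ADR protein set) is one concrete reading of a
#' network-based enrichment test; see the methods vignette.
#'
#' @param net A [hetero_network()] (with any held-out edge already removed).
#' @param focus_adr Query ADR id.
#' @param exclude Candidate exclusions; defaults to the ADR's known
#'   proteins. An ADR with no known proteins yields a degenerate all-ties
#'   ranking with a warning.
#' @return A `rank_result` with additional column `p_value`; `score` is
#'   `-log10(p_value)`.
#' @export
rank_by_enrichment <- function(net, focus_adr, exclude = NULL) {
  stopifnot(inherits(net, "hetero_network"))
  j <- match(focus_adr, net$adrs)
  if (is.na(j)) stop("unknown ADR: ", focus_adr, call. = FALSE)
  known <- which(net$B[, j] != 0)
  K <- length(known)
  if (is.null(exclude)) exclude <- net$proteins[known]
  Apat <- net$A
  if (length(Apat@x)) Apat@x <- rep(1, length(Apat@x))
  deg <- rowSums(Apat)
  if (K == 0L) {
    warning("ADR '", focus_adr, "' has no known proteins; ",
            "enrichment ranking is degenerate (all ties)", call. = FALSE)
    pv <- rep(1, net$n)
  } else {
    ind <- numeric(net$n); ind[known] <- 1
    kvec <- as.numeric(Apat %*% ind)
    pv <- hypergeom_pvalue(kvec, K, deg, net$n)
  }
  cand <- setdiff(net$proteins, exclude)
  if (length(cand) == 0L) {
    warning("candidate set is empty for ADR '", focus_adr, "'", call. = FALSE)
    return(.make_rank_result(numeric(0), character(0), focus_adr))
  }
  ci <- match(cand, net$proteins)
  # rank ascending p-value == descending -log10(p)
  .make_rank_result(-log10(pv[ci]), cand, focus_adr,
                    extra = data.frame(p_value = pv[ci]))
}

#' Random walk with restart on the PPI network alone
#'
#' The single-layer comparison method: seeds are the ADR's (remaining)
#' known proteins with a uniform initial distribution, the walk runs on the
#' row-normalized PPI weight matrix only, and candidates are ranked by
#' stable probability. Needs at least one seed protein (so, under
#' leave-one-out, ADRs with at least two known proteins; see
#' [filter_gold_for_rwr()]).
#'
#' @param net A [hetero_network()].
#' @param focus_adr Query ADR id.
#' @param seed_proteins Seeds; default the ADR's known proteins in `net`.
#' @param r Restart probability.
#' @param tol,max_iter Convergence controls for [rwr_walk()].
#' @param exclude Candidate exclusions; defaults to the seed proteins.
#' @return A `rank_result` over the candidate proteins.
#' @export
rwr_ppi <- function(net, focus_adr, seed_proteins = NULL, r = 0.7,
                    tol = 1e-10, max_iter = 1000L, exclude = NULL) {
  stopifnot(inherits(net, "hetero_network"))
  j <- match(focus_adr, net$adrs)
  if (is.na(j)) stop("unknown ADR: ", focus_adr, call. = FALSE)
  if (is.null(seed_proteins)) seed_proteins <- known_proteins(net, focus_adr)
  if (length(seed_proteins) == 0L)
    stop("the PPI-only walk needs at least one seed protein for ADR '",
         focus_adr, "'", call. = FALSE)
  deg <- rowSums(net$A)
  coef <- ifelse(deg > 0, 1 / deg, 0)
  Mp <- as(as(as(Diagonal(x = coef) %*% net$A, "CsparseMatrix"),
              "generalMatrix"), "dMatrix")
  dimnames(Mp) <- list(net$proteins, net$proteins)
  model <- structure(list(M = Mp, lambda = NA_real_, proteins = net$proteins,
                          adrs = character(0), n = net$n, m = 0L,
                          dangling = deg == 0),
                     class = "transition_model")
  p0 <- numeric(net$n)
  names(p0) <- net$proteins
  p0[match(seed_proteins, net$proteins)] <- 1 / length(seed_proteins)
  w <- rwr_walk(model, p0, r = r, tol = tol, max_iter = max_iter)
  if (is.null(exclude)) exclude <- seed_proteins
  cand <- setdiff(net$proteins, exclude)
  if (length(cand) == 0L) {
    warning("candidate set is empty for ADR '", focus_adr, "'", call. = FALSE)
    return(.make_rank_result(numeric(0), character(0), focus_adr))
  }
  res <- .make_rank_result(as.numeric(w$p[match(cand, net$proteins)]), cand,
                           focus_adr)
  attr(res, "iterations") <- w$iterations
  attr(res, "converged") <- w$converged
  res
}

#' Restrict gold-standard relations to ADRs with at least two proteins
#'
#' The PPI-only walk cannot be evaluated by leave-one-out on an ADR with a
#' single known protein (no seed would remain), so its gold standard keeps
#' only relations whose ADR has two or more related proteins.
#'
#' @param relations Data frame whose first two columns are protein and ADR
#'   ids.
#' @return The subset of rows whose ADR has >= 2 related proteins.
#' @export
filter_gold_for_rwr <- function(relations) {
  df <- .as_pairs(relations, c("protein", "adr"), "relations")
  counts <- table(df$adr)
  df[df$adr %in% names(counts)[counts >= 2L], , drop = FALSE]
}
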