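# Random walk with restart on the integrated network.
#
# Update rule: p_{t+1} = (1 - r) * t(M) %*% p_t + r * p0, iterated until the
# L1 change drops below tol. Mass that falls into dangling (all-zero) rows
# of M is redistributed proportionally to p0 before the restart term, so the
# iterate remains a probability vector on every step.

#' Specify a query: one focus ADR plus its known proteins
#'
#' @param focus_adr ADR id of interest.
#' @param seed_proteins Character vector of proteins known to relate to the
#'   focus ADR (may be empty).
#' @param eta Weight in `[0, 1]` splitting initial probability between the
#'   protein seeds (`1 - eta`) and the focus ADR (`eta`); at `0.5` the two
#'   layers carry equal importance.
#' @param r Restart probability in `(0, 1]`.
#' @return Object of class `seed_spec`.
#' @export
seed_spec <- function(focus_adr, seed_proteins = character(), eta = 0.5,
                      r = 0.7) {
  stopifnot(is.character(focus_adr) || is.factor(focus_adr),
            length(focus_adr) == 1L)
  .check_prob(eta, "eta")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0 || r > 1)
    stop("'r' must be a single number in (0, 1]", call. = FALSE)
  structure(list(focus_adr = as.character(focus_adr),
                 seed_proteins = unique(as.character(seed_proteins)),
                 eta = eta, r = r),
            class = "seed_spec")
}

#' Initial probability vector for a query
#'
#' Places `(1 - eta)` of the mass uniformly over the seed proteins and `eta`
#' on the focus ADR, over the proteins-then-ADRs node ordering. When the
#' query has no seed proteins (an ADR whose only known relation was held
#' out), all mass goes to the ADR node with a warning — this is what keeps
#' the integrated walk applicable where a PPI-only walk is not.
#'
#' @param spec A [seed_spec()].
#' @param net A [hetero_network()].
#' @return Named numeric vector of length `n + m` summing to 1.
#' @export
initial_probability <- function(spec, net) {
  stopifnot(inherits(spec, "seed_spec"), inherits(net, "hetero_network"))
  i_adr <- match(spec$focus_adr, net$adrs)
  if (is.na(i_adr))
    stop("focus ADR not in the ADR index: ", spec$focus_adr, call. = FALSE)
  unknown <- setdiff(spec$seed_proteins, net$proteins)
  if (length(unknown))
    stop("seed protein(s) not in the protein index: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  p <- numeric(net$n + net$m)
  names(p) <- c(net$proteins, net$adrs)
  k <- length(spec$seed_proteins)
  if (k == 0L) {
    warning("no seed proteins for ADR '", spec$focus_adr,
            "'; all initial mass placed on the ADR node", call. = FALSE)
    p[net$n + i_adr] <- 1
  } else {
    p[match(spec$seed_proteins, net$proteins)] <- (1 - spec$eta) / k
    p[net$n + i_adr] <- spec$eta
  }
  p
}

#' Iterate the random walk with restart to its stable probability
#'
#' Runs `p_{t+1} = (1 - r) * (t(M) %*% p_t + lost_t * p0) + r * p0`, where
#' `lost_t` is the probability mass sitting on dangling rows at step `t`
#' (redistributed proportionally to `p0`), until the L1 difference between
#' successive iterates falls below `tol` or `max_iter` is reached.
#'
#' @param model A [build_transition()] model (or any list with a sparse
#'   row-stochastic `M` and logical `dangling`).
#' @param p0 Initial probability vector (must sum to 1).
#' @param r Restart probability in `(0, 1]`.
#' @param tol L1 convergence tolerance (default `1e-10`).
#' @param max_iter Maximum number of iterations (default 1000). On
#'   non-convergence the last iterate is returned with `converged = FALSE`
#'   and a warning, not an error.
#' @return List with `p` (stable probability, named), `iterations`, and
#'   `converged`.
#' @export
rwr_walk <- function(model, p0, r = 0.7, tol = 1e-10, max_iter = 1000L) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1)
    stop("'r' must be a single number in (0, 1]", call. = FALSE)
  if (abs(sum(p0) - 1) > 1e-9)
    stop("'p0' must sum to 1", call. = FALSE)
  if (length(p0) != nrow(model$M))
    stop("'p0' length does not match the transition matrix", call. = FALSE)
  Mt <- t(model$M)
  dang <- which(model$dangling)
  p <- as.numeric(p0)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    lost <- if (length(dang)) sum(p[dang]) else 0
    p_new <- as.numeric((1 - r) * (Mt %*% p + lost * p0) + r * p0)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      names(p) <- names(p0)
      return(list(p = p, iterations = it, converged = TRUE))
    }
  }
  warning("random walk did not converge in ", max_iter,
          " iterations (L1 change ", signif(delta, 3), ")", call. = FALSE)
  names(p) <- names(p0)
  list(p = p, iterations = max_iter, converged = FALSE)
}

# Shared ranking: stable scores over a candidate set, midrank ties, rows
# ordered by rank then id so identical inputs give identical output.
.make_rank_result <- function(scores, candidates, focus_adr, extra = NULL) {
  rk <- rank(-scores, ties.method = "average")
  o <- order(rk, candidates, method = "radix")
  res <- data.frame(protein = candidates[o], score = scores[o], rank = rk[o],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(extra)) res <- cbind(res, extra[o, , drop = FALSE])
  attr(res, "focus_adr") <- focus_adr
  attr(res, "n_candidates") <- length(candidates)
  class(res) <- c("rank_result", "data.frame")
  res
}

#' Rank candidate proteins by stable probability
#'
#' The candidate set is every indexed protein except `exclude` (by default
#' the proteins already known to relate to the focus ADR, i.e. the seeds).
#' Candidates are ranked by descending stable probability; ties receive
#' their average rank (the Mann-Whitney-consistent midrank).
#'
#' @param stable Stable probability vector from [rwr_walk()] over
#'   proteins-then-ADRs.
#' @param net The [hetero_network()] the walk was run on.
#' @param focus_adr The query ADR id.
#' @param exclude Protein ids excluded from the candidate set; defaults to
#'   the known proteins of `focus_adr` in `net`.
#' @return Object of class `rank_result`: a data frame with columns
#'   `protein`, `score`, `rank`, sorted by rank, with attributes
#'   `focus_adr` and `n_candidates`.
#' @export
rank_candidates <- function(stable, net, focus_adr, exclude = NULL) {
  stopifnot(inherits(net, "hetero_network"))
  j <- match(focus_adr, net$adrs)
  if (is.na(j)) stop("unknown ADR: ", focus_adr, call. = FALSE)
  if (is.null(exclude)) exclude <- known_proteins(net, focus_adr)
  cand <- setdiff(net$proteins, exclude)
  if (length(cand) == 0L) {
    warning("candidate set is empty for ADR '", focus_adr, "'", call. = FALSE)
    return(.make_rank_result(numeric(0), character(0), focus_adr))
  }
  sc <- as.numeric(stable[match(cand, net$proteins)])
  .make_rank_result(sc, cand, focus_adr)
}

#' @export
print.rank_result <- function(x, n = 10L, ...) {
  cat(sprintf("Protein ranking for ADR '%s' (%d candidates)\n",
              attr(x, "focus_adr"), attr(x, "n_candidates")))
  print.data.frame(head(x, n))
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more\n")
  invisible(x)
}

#' Top-k proteins of a ranking
#'
#' @param result A `rank_result`.
#' @param k Number of proteins to keep (default 50); if fewer candidates
#'   exist, all are returned.
#' @return The first `min(k, n)` rows of the ranking.
#' @export
top_k <- function(result, k = 50L) {
  stopifnot(k >= 1)
  out <- result[seq_len(min(k, nrow(result))), , drop = FALSE]
  attr(out, "focus_adr") <- attr(result, "focus_adr")
  attr(out, "n_candidates") <- attr(result, "n_candidates")
  class(out) <- class(result)
  out
}

#' Rank candidate proteins for an ADR on the integrated network
#'
#' Convenience pipeline: build (or reuse) the transition model, construct
#' the seed distribution from the ADR's known proteins, run the walk, and
#' rank the candidates. Defaults: restart 0.7, jumping probability 0.5,
#' seed-split 0.5.
#'
#' @param net A [hetero_network()].
#' @param adr Query ADR id.
#' @param seed_proteins Seed proteins; defaults to [known_proteins()] of the
#'   ADR in `net`.
#' @param r,lambda,eta Walk parameters (restart, jumping, seed-split).
#' @param tol,max_iter Convergence controls for [rwr_walk()].
#' @param exclude Candidate exclusions; defaults to the seed proteins.
#' @param model Optional precomputed [build_transition()] model for `net`
#'   at `lambda` (rebuilt when `NULL`).
#' @return A `rank_result` with attributes `iterations` and `converged`.
#' @export
#' @examples
#' truth <- generate_synthetic(synthetic_config(n_proteins = 60, n_adrs = 8,
#'                                              n_drugs = 30, seed = 7))
#' net <- build_network(truth$ppi, truth$relations, truth$drug_adr)
#' top_k(inpadr_rank(net, net$adrs[1]), 5)
inpadr_rank <- function(net, adr, seed_proteins = NULL, r = 0.7,
                        lambda = 0.5, eta = 0.5, tol = 1e-10,
                        max_iter = 1000L, exclude = NULL, model = NULL) {
  if (is.null(seed_proteins)) seed_proteins <- known_proteins(net, adr)
  if (is.null(model)) model <- build_transition(net, lambda)
  spec <- seed_spec(adr, seed_proteins, eta = eta, r = r)
  p0 <- initial_probability(spec, net)
  w <- rwr_walk(model, p0, r = r, tol = tol, max_iter = max_iter)
  if (is.null(exclude)) exclude <- seed_proteins
  res <- rank_candidates(w$p, net, adr, exclude = exclude)
  attr(res, "iterations") <- w$iterations
  attr(res, "converged") <- w$converged
  res
}
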