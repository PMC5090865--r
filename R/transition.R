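# Row-stochastic block transition model for the integrated network.
#
# M = [[M_PP, M_PA], [M_AP, M_AA]] with rows normalized within each block
# and the cross-layer mass controlled by the jumping probability lambda:
# a node holding links in both its own layer and the bipartite layer
# distributes 1 - lambda over its intra-layer neighbors (weighted by edge
# weight) and lambda over its bipartite neighbors. A node with no bipartite
# links keeps all its mass in its own layer regardless of lambda. A node
# whose only links are bipartite sends all mass across when lambda > 0; at
# lambda = 0 the walker never crosses layers, so such a row is dangling.
# Dangling (all-zero) rows are not patched here: the walk redistributes
# their mass onto the restart vector, which conserves total probability
# without inventing edges.

# Per-row scale factors for one side of the network.
.block_coefs <- function(rs_intra, rs_cross, lambda) {
  intra <- numeric(length(rs_intra))
  cross <- numeric(length(rs_cross))
  both <- rs_intra > 0 & rs_cross > 0
  intra[both] <- (1 - lambda) / rs_intra[both]
  cross[both] <- lambda / rs_cross[both]
  only_intra <- rs_intra > 0 & rs_cross == 0
  intra[only_intra] <- 1 / rs_intra[only_intra]
  only_cross <- rs_intra == 0 & rs_cross > 0
  if (lambda > 0) cross[only_cross] <- 1 / rs_cross[only_cross]
  list(intra = intra, cross = cross)
}

#' Build the block transition matrix of the integrated network
#'
#' Assembles the `(n+m) x (n+m)` row-stochastic transition matrix over
#' proteins-then-ADRs. Intra-layer transitions are weighted by edge weight
#' (PPI confidence, Jaccard similarity); cross-layer transitions are uniform
#' over bipartite neighbors. For a protein `i` with at least one known ADR
#' link and at least one PPI edge,
#' `M_PP[i, j] = (1 - lambda) * A[i, j] / sum_k A[i, k]` and
#' `M_PA[i, j] = lambda * B[i, j] / sum_k B[i, k]`; a protein without ADR
#' links walks only in the PPI layer. ADR rows are built symmetrically from
#' `C` and `t(B)`. Rows of isolated nodes are left all-zero (dangling) and
#' handled by [rwr_walk()].
#'
#' @param net A [hetero_network()].
#' @param lambda Jumping probability in `[0, 1]`: per-step probability of
#'   crossing between the protein and ADR layers via bipartite links.
#' @return An object of class `transition_model`: list with the sparse
#'   matrix `M`, `lambda`, the two indices, block sizes `n`, `m`, and a
#'   logical `dangling` marking all-zero rows.
#' @export
build_transition <- function(net, lambda = 0.5) {
  stopifnot(inherits(net, "hetero_network"))
  .check_prob(lambda, "lambda")
  rsA <- rowSums(net$A); rsB <- rowSums(net$B)
  rsC <- rowSums(net$C); csB <- colSums(net$B)
  cp <- .block_coefs(rsA, rsB, lambda)
  ca <- .block_coefs(rsC, csB, lambda)
  M <- rbind(
    cbind(Diagonal(x = cp$intra) %*% net$A, Diagonal(x = cp$cross) %*% net$B),
    cbind(Diagonal(x = ca$cross) %*% t(net$B), Diagonal(x = ca$intra) %*% net$C))
  M <- as(as(as(M, "CsparseMatrix"), "generalMatrix"), "dMatrix")
  nodes <- c(net$proteins, net$adrs)
  dimnames(M) <- list(nodes, nodes)
  structure(list(M = M, lambda = lambda, proteins = net$proteins,
                 adrs = net$adrs, n = net$n, m = net$m,
                 dangling = rowSums(M) == 0),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("Transition model: %d proteins + %d ADRs, lambda = %g, %d dangling row(s)\n",
              x$n, x$m, x$lambda, sum(x$dangling)))
  invisible(x)
}

#' Check row-stochasticity of a transition model
#'
#' Reports rows whose sum deviates from 1 by more than `tol` and rows that
#' sum to zero (dangling rows of isolated nodes, whose mass the walk
#' redistributes onto the restart vector).
#'
#' @param model A `transition_model`.
#' @param tol Allowed deviation of a row sum from 1 (default `1e-9`).
#' @return Object of class `stochastic_report`: list with `deviant` (data
#'   frame of node id and row sum), `dangling` (node ids), and `tol`.
#' @export
validate_stochastic <- function(model, tol = 1e-9) {
  rs <- rowSums(model$M)
  nodes <- rownames(model$M)
  dang <- rs == 0
  dev <- !dang & abs(rs - 1) > tol
  structure(list(deviant = data.frame(node = nodes[dev], row_sum = rs[dev],
                                      row.names = NULL),
                 dangling = nodes[dang], tol = tol,
                 n_rows = length(rs)),
            class = "stochastic_report")
}

#' @export
print.stochastic_report <- function(x, ...) {
  cat(sprintf("Row-stochasticity check over %d rows (tol %g):\n", x$n_rows,
              x$tol))
  cat(sprintf("  deviant rows:  %d\n", nrow(x$deviant)))
  if (nrow(x$deviant)) print(head(x$deviant, 10L))
  cat(sprintf("  dangling rows: %d\n", length(x$dangling)))
  invisible(x)
}

#' Write a transition matrix as coordinate triplets
#'
#' Serializes `M` as a TSV of `row<TAB>col<TAB>prob` node-id triplets, for
#' inspection or interchange.
#'
#' @param model A `transition_model`.
#' @param path Output path (gzipped if it ends in `.gz`).
#' @export
write_transition <- function(model, path) {
  Tm <- as(model$M, "TsparseMatrix")
  nodes <- rownames(model$M)
  o <- order(Tm@i, Tm@j)
  df <- data.frame(row = nodes[Tm@i[o] + 1L], col = nodes[Tm@j[o] + 1L],
                   prob = Tm@x[o])
  con <- .out_con(path)
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
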