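# TSV writers mirroring the readers (paths ending in .gz are compressed).

.write_tsv <- function(df, path) {
  con <- .out_con(path)
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Upper-triangle edge triplets of a symmetric sparse matrix.
.sym_edges <- function(M, ids, cols) {
  Tm <- as(M, "TsparseMatrix")
  keep <- Tm@i < Tm@j
  o <- order(Tm@i[keep], Tm@j[keep])
  df <- data.frame(ids[Tm@i[keep][o] + 1L], ids[Tm@j[keep][o] + 1L],
                   Tm@x[keep][o], stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' Write a PPI weight matrix as an edge-list TSV
#'
#' Inverse of [read_ppi()] up to edge ordering and duplicate collapse: one
#' row per undirected edge, columns `protein_a`, `protein_b`, `weight`.
#'
#' @param x A [hetero_network()] or a list with `proteins` and `A`.
#' @param path Output path (`.gz` compresses).
#' @export
write_ppi <- function(x, path) {
  .write_tsv(.sym_edges(x$A, x$proteins,
                        c("protein_a", "protein_b", "weight")), path)
}

#' Write protein-ADR relations as a 2-column TSV
#'
#' @param x A [hetero_network()] (its bipartite layer is written) or a data
#'   frame of `(protein, adr)` pairs.
#' @param path Output path.
#' @export
write_relations <- function(x, path) {
  df <- if (inherits(x, "hetero_network")) gold_relations(x)
        else .as_pairs(x, c("protein", "adr"), "relations")
  .write_tsv(df, path)
}

#' Write an ADR similarity matrix as an edge-list TSV
#'
#' @param x A [hetero_network()] or a list with `adrs` and `C`.
#' @param path Output path.
#' @export
write_adr_similarity <- function(x, path) {
  .write_tsv(.sym_edges(x$C, x$adrs, c("adr_a", "adr_b", "similarity")),
             path)
}
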