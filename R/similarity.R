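# ADR-ADR similarity from drug co-occurrence.
#
# Two ADRs are similar when they are caused by overlapping drug sets; the
# similarity is the Jaccard index |Di intersect Dj| / |Di union Dj| of the
# drug sets, and a pair is linked in the ADR layer iff its index is > 0.

#' Jaccard similarity of two drug sets
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @return `|a intersect b| / |a union b|`, in `[0, 1]`. Defined as long as
#'   at least one set is nonempty; two empty sets are an error.
#' @export
#' @examples
#' jaccard(c("d1", "d2", "d3"), c("d2", "d3", "d4"))  # 0.5
jaccard <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(set_a) == 0L && length(set_b) == 0L)
    stop("Jaccard similarity is undefined for two empty sets", call. = FALSE)
  length(intersect(set_a, set_b)) / length(union(set_a, set_b))
}

#' ADR similarity matrix from a drug-ADR table
#'
#' Computes the full pairwise Jaccard similarity matrix over ADRs from their
#' drug sets. `C[i, j]` is the Jaccard index of the drug sets of ADR `i` and
#' ADR `j` for `i != j` (stored only when positive); the diagonal is zero
#' because self-similarity is never an edge of the ADR layer.
#'
#' An ADR present in `adrs` but absent from the table (possible when the
#' ranking universe is aligned to a gold standard) becomes an isolated node
#' with a zero row, reported once via a warning.
#'
#' @param drug_adr Path to a 2-column TSV (`drug<TAB>adr`) or a data frame
#'   whose first two columns are drug and ADR ids.
#' @param adrs Optional character ADR index; defaults to the sorted unique
#'   ADRs of the table. ADRs in the table but not in `adrs` are ignored.
#' @return Symmetric sparse `dgCMatrix` with zero diagonal.
#' @export
adr_similarity <- function(drug_adr, adrs = NULL) {
  pairs <- .as_pairs(drug_adr, c("drug", "adr"), "drug-ADR table")
  if (is.null(adrs)) adrs <- .sort_ids(pairs$adr)
  absent <- setdiff(adrs, pairs$adr)
  if (length(absent))
    warning(length(absent), " ADR(s) absent from the drug-ADR table have ",
            "zero similarity rows: ", paste(head(absent, 5L), collapse = ", "),
            if (length(absent) > 5L) ", ..." else "", call. = FALSE)
  pairs <- pairs[pairs$adr %in% adrs, , drop = FALSE]
  m <- length(adrs)
  drugs <- .sort_ids(pairs$drug)
  if (nrow(pairs) == 0L || m < 2L)
    return(sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                        dims = c(m, m), dimnames = list(adrs, adrs)))
  X <- sparseMatrix(i = match(pairs$adr, adrs), j = match(pairs$drug, drugs),
                    x = rep(1, nrow(pairs)), dims = c(m, length(drugs)))
  # |Di intersect Dj| on the support; general storage so both triangles
  # carry explicit triplets
  inter <- as(as(tcrossprod(X), "generalMatrix"), "TsparseMatrix")
  sizes <- rowSums(X)
  keep <- inter@i != inter@j
  i <- inter@i[keep] + 1L
  j <- inter@j[keep] + 1L
  ov <- inter@x[keep]
  sim <- ov / (sizes[i] + sizes[j] - ov)
  drop0(sparseMatrix(i = i, j = j, x = sim, dims = c(m, m),
                     dimnames = list(adrs, adrs)))
}
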