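# Readers, validators and the integrated-network container.
#
# The integrated network joins three layers over a protein index (size n)
# and an ADR index (size m):
#   A  n x n  symmetric PPI confidence weights in [0, 1], zero diagonal
#   B  n x m  binary known protein-ADR relations
#   C  m x m  symmetric ADR Jaccard similarities in [0, 1], zero diagonal
# Its adjacency is the block matrix W = [[A, B], [B', C]]; all vectors in
# the package order nodes proteins-first, then ADRs.

# Split a TSV (possibly gzipped, '#' comments ignored) into a character
# matrix with n_cols columns. Blank lines are skipped.
.read_tsv_records <- function(path, n_cols, what) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("no records found in ", what, " file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != n_cols
  if (any(bad))
    stop(what, " file ", path, ": expected ", n_cols,
         " tab-separated columns (first bad line: ",
         lines[which(bad)[1L]], ")", call. = FALSE)
  matrix(trimws(unlist(parts)), ncol = n_cols, byrow = TRUE)
}

# Drop an optional header row: for 3-column files when the third field is
# non-numeric, for 2-column files when both fields look like column names.
.drop_header <- function(rec, what, path) {
  if (ncol(rec) == 3L) {
    if (is.na(suppressWarnings(as.numeric(rec[1L, 3L])))) rec <- rec[-1L, , drop = FALSE]
  } else {
    nm <- tolower(rec[1L, ])
    if (all(nm %in% c("protein", "protein_a", "protein_b", "drug", "adr",
                      "adr_a", "adr_b", "weight", "similarity")))
      rec <- rec[-1L, , drop = FALSE]
  }
  if (nrow(rec) == 0L)
    stop(what, " file ", path, " contains a header but no records", call. = FALSE)
  rec
}

# Core PPI assembly shared by read_ppi() and build_network(): collapse
# duplicate undirected edges by maximum weight, drop self-loops (warning),
# drop zero-weight records (a zero confidence score is a non-edge).
.build_ppi <- function(a, b, w, weight_scale, nodes = NULL) {
  if (anyNA(w))
    stop("non-numeric PPI edge weight(s)", call. = FALSE)
  if (any(w < 0))
    stop("negative PPI edge weight(s)", call. = FALSE)
  if (weight_scale == "string_0_999") w <- w / 1000
  if (any(w > 1))
    stop("PPI edge weights above 1 after scaling; check 'weight_scale'",
         call. = FALSE)
  loops <- a == b
  if (any(loops))
    warning(sum(loops), " self-loop(s) dropped from PPI edge list", call. = FALSE)
  ids <- .sort_ids(c(a, b, nodes))
  keep <- !loops & w > 0
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  n <- length(ids)
  A <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                    dims = c(n, n), dimnames = list(ids, ids))
  if (length(w)) {
    ia <- match(a, ids); ib <- match(b, ids)
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    mx <- aggregate(w ~ lo + hi, data = data.frame(lo, hi, w), FUN = max)
    A <- sparseMatrix(i = c(mx$lo, mx$hi), j = c(mx$hi, mx$lo),
                      x = rep(mx$w, 2L), dims = c(n, n),
                      dimnames = list(ids, ids))
  }
  list(proteins = ids, A = A)
}

#' Read a weighted protein-protein interaction edge list
#'
#' Reads a 3-column TSV (`protein_a`, `protein_b`, `weight`; header optional,
#' `#` comment lines ignored, gzip transparently supported) into a protein
#' index and a symmetric sparse weight matrix. Duplicate undirected edges are
#' collapsed by maximum weight; self-loops are dropped with a warning (the
#' protein stays indexed); records with weight zero are dropped (a zero
#' confidence score means no edge).
#'
#' @param path Path to the edge list (may be gzip-compressed).
#' @param weight_scale `"raw01"` for confidence scores already in `[0, 1]`,
#'   or `"string_0_999"` for STRING-style integer scores, which are divided
#'   by 1000 into `(0, 1]`.
#' @param nodes Optional character vector of additional protein ids to index
#'   even if they appear in no edge (isolated nodes are permitted; the walk
#'   handles their dangling rows).
#' @return A list with `proteins` (sorted character index) and `A`
#'   (symmetric `dgCMatrix` of weights with zero diagonal).
#' @seealso [build_network()], [write_ppi()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("p1\tp2\t0.9", "p2\tp3\t0.5"), tf)
#' ppi <- read_ppi(tf)
#' ppi$A["p1", "p2"]
read_ppi <- function(path, weight_scale = c("raw01", "string_0_999"),
                     nodes = NULL) {
  weight_scale <- match.arg(weight_scale)
  rec <- .read_tsv_records(path, 3L, "PPI edge list")
  rec <- .drop_header(rec, "PPI edge list", path)
  .build_ppi(rec[, 1L], rec[, 2L], suppressWarnings(as.numeric(rec[, 3L])),
             weight_scale, nodes)
}

# Normalize a 2-column input (path or data.frame) into a unique pair
# data.frame with the given column names.
.as_pairs <- function(x, cols, what) {
  if (is.character(x) && length(x) == 1L) {
    rec <- .read_tsv_records(x, 2L, what)
    rec <- .drop_header(rec, what, x)
    df <- data.frame(rec[, 1L], rec[, 2L], stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop(what, " needs two columns", call. = FALSE)
    df <- data.frame(as.character(x[[1L]]), as.character(x[[2L]]),
                     stringsAsFactors = FALSE)
  } else {
    stop(what, " must be a file path or a data frame", call. = FALSE)
  }
  names(df) <- cols
  unique(df)
}

#' Read known protein-ADR relations into a bipartite matrix
#'
#' Builds the binary relation matrix `B` (`n x m`, proteins by ADRs) from a
#' 2-column TSV or data frame of `(protein, adr)` pairs. Duplicate pairs are
#' collapsed. Relations naming a protein absent from the PPI index cannot be
#' ranked and are, by default, dropped with one warning.
#'
#' @param x Path to a 2-column TSV (`protein<TAB>adr`) or a data frame whose
#'   first two columns are protein and ADR ids.
#' @param proteins Character protein index (typically from [read_ppi()]).
#' @param adrs Optional character ADR index; defaults to the sorted unique
#'   ADRs present in `x`.
#' @param on_missing `"drop"` (default) drops relations whose protein or ADR
#'   is absent from the given indices, with a warning; `"error"` stops.
#' @return Binary sparse `dgCMatrix` with `dimnames` `(proteins, adrs)`.
#' @export
read_relations <- function(x, proteins, adrs = NULL,
                           on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  df <- .as_pairs(x, c("protein", "adr"), "relations")
  if (is.null(adrs)) adrs <- .sort_ids(df$adr)
  miss <- !(df$protein %in% proteins) | !(df$adr %in% adrs)
  if (any(miss)) {
    msg <- paste0(sum(miss), " relation(s) reference ids outside the ",
                  "protein/ADR indices")
    if (on_missing == "error") stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    df <- df[!miss, , drop = FALSE]
  }
  sparseMatrix(i = match(df$protein, proteins), j = match(df$adr, adrs),
               x = rep(1, nrow(df)), dims = c(length(proteins), length(adrs)),
               dimnames = list(proteins, adrs))
}

#' Read a precomputed ADR-ADR similarity edge list
#'
#' @param x Path to a 3-column TSV (`adr_a<TAB>adr_b<TAB>similarity`) or a
#'   data frame with those columns.
#' @param adrs Character ADR index the matrix is aligned to; defaults to the
#'   sorted unique ADRs in `x`.
#' @return Symmetric sparse `dgCMatrix` of similarities in `[0, 1]` with a
#'   zero diagonal.
#' @export
read_adr_similarity <- function(x, adrs = NULL) {
  if (is.character(x) && length(x) == 1L) {
    rec <- .read_tsv_records(x, 3L, "ADR similarity")
    rec <- .drop_header(rec, "ADR similarity", x)
    df <- data.frame(a = rec[, 1L], b = rec[, 2L],
                     s = suppressWarnings(as.numeric(rec[, 3L])),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(a = as.character(x[[1L]]), b = as.character(x[[2L]]),
                     s = as.numeric(x[[3L]]), stringsAsFactors = FALSE)
  }
  if (anyNA(df$s) || any(df$s < 0) || any(df$s > 1))
    stop("ADR similarities must be numeric in [0, 1]", call. = FALSE)
  if (is.null(adrs)) adrs <- .sort_ids(c(df$a, df$b))
  loops <- df$a == df$b
  if (any(loops)) {
    warning(sum(loops), " ADR self-similarity record(s) dropped", call. = FALSE)
    df <- df[!loops, , drop = FALSE]
  }
  df <- df[df$s > 0 & df$a %in% adrs & df$b %in% adrs, , drop = FALSE]
  m <- length(adrs)
  if (nrow(df) == 0L)
    return(sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                        dims = c(m, m), dimnames = list(adrs, adrs)))
  ia <- match(df$a, adrs); ib <- match(df$b, adrs)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  mx <- aggregate(s ~ lo + hi, data = data.frame(lo, hi, s = df$s), FUN = max)
  sparseMatrix(i = c(mx$lo, mx$hi), j = c(mx$hi, mx$lo), x = rep(mx$s, 2L),
               dims = c(m, m), dimnames = list(adrs, adrs))
}

#' Assemble and validate the integrated protein-ADR network
#'
#' Validates the three layer matrices and returns the integrated container.
#' `A` and `C` must be square, nonnegative with entries in `[0, 1]`; if a
#' matrix is asymmetric it is symmetrized by the elementwise maximum with a
#' warning, and nonzero diagonals are zeroed with a warning. `B` must be
#' binary.
#'
#' @param A `n x n` PPI weight matrix (sparse or dense).
#' @param B `n x m` binary protein-ADR relation matrix.
#' @param C `m x m` ADR similarity matrix.
#' @param proteins,adrs Character indices; default to the dimnames of `B`.
#' @return An object of class `hetero_network`: a list with elements `A`,
#'   `B`, `C`, `proteins`, `adrs`, `n`, `m`.
#' @export
hetero_network <- function(A, B, C, proteins = rownames(B),
                           adrs = colnames(B)) {
  A <- as(as(as(A, "CsparseMatrix"), "generalMatrix"), "dMatrix")
  B <- as(as(as(B, "CsparseMatrix"), "generalMatrix"), "dMatrix")
  C <- as(as(as(C, "CsparseMatrix"), "generalMatrix"), "dMatrix")
  n <- nrow(B); m <- ncol(B)
  if (is.null(proteins)) proteins <- paste0("p", seq_len(n))
  if (is.null(adrs)) adrs <- paste0("a", seq_len(m))
  if (anyDuplicated(proteins) || anyDuplicated(adrs))
    stop("protein and ADR identifiers must be unique", call. = FALSE)
  if (!all(dim(A) == c(n, n)) || !all(dim(C) == c(m, m)))
    stop("dimension mismatch: need A ", n, "x", n, ", B ", n, "x", m,
         ", C ", m, "x", m, call. = FALSE)
  if (length(proteins) != n || length(adrs) != m)
    stop("index length does not match matrix dimensions", call. = FALSE)
  fix_sym <- function(M, lab) {
    if (length(M@x) && max(abs(M - t(M))) > 0) {
      warning(lab, " was not symmetric; symmetrized by elementwise maximum",
              call. = FALSE)
      M <- (M + t(M) + abs(M - t(M))) / 2
    }
    if (any(diag(M) != 0)) {
      warning("nonzero diagonal of ", lab, " set to zero", call. = FALSE)
      diag(M) <- 0
    }
    M <- drop0(M)
    if (length(M@x) && (min(M@x) < 0 || max(M@x) > 1))
      stop("entries of ", lab, " must lie in [0, 1]", call. = FALSE)
    M
  }
  A <- fix_sym(A, "A"); C <- fix_sym(C, "C")
  B <- drop0(B)
  if (length(B@x) && !all(B@x == 1))
    stop("B must be binary (entries 0 or 1)", call. = FALSE)
  dimnames(A) <- list(proteins, proteins)
  dimnames(B) <- list(proteins, adrs)
  dimnames(C) <- list(adrs, adrs)
  structure(list(A = A, B = B, C = C, proteins = proteins, adrs = adrs,
                 n = n, m = m),
            class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("Integrated protein-ADR network\n")
  cat(sprintf("  proteins: %d (%d PPI edges)\n", x$n, length(x$A@x) / 2))
  cat(sprintf("  ADRs:     %d (%d similarity edges)\n", x$m,
              length(x$C@x) / 2))
  cat(sprintf("  known protein-ADR relations: %d\n", length(x$B@x)))
  invisible(x)
}

#' Build the integrated network from raw tables
#'
#' One-call constructor: reads/assembles the PPI layer, the bipartite
#' gold-standard layer and the ADR similarity layer, and returns a validated
#' [hetero_network()]. The ADR index is the set of ADRs appearing in the
#' gold-standard relations, so the ranking universe matches the evaluation
#' universe; ADRs without drug records get zero similarity rows (warning
#' from [adr_similarity()]).
#'
#' @param ppi Path to a PPI edge-list TSV or a 3-column data frame
#'   (`protein_a`, `protein_b`, `weight`).
#' @param relations Path or 2-column data frame of gold protein-ADR pairs.
#' @param drug_adr Optional path or 2-column data frame of drug-ADR pairs,
#'   used to compute Jaccard ADR similarities.
#' @param adr_sim Optional precomputed ADR similarity edge list (path or
#'   3-column data frame); overrides `drug_adr`.
#' @param weight_scale Passed to the PPI reader; see [read_ppi()].
#' @param on_missing Policy for relations naming unindexed proteins; see
#'   [read_relations()].
#' @return A `hetero_network`.
#' @export
build_network <- function(ppi, relations, drug_adr = NULL, adr_sim = NULL,
                          weight_scale = c("raw01", "string_0_999"),
                          on_missing = c("drop", "error")) {
  weight_scale <- match.arg(weight_scale)
  on_missing <- match.arg(on_missing)
  if (is.character(ppi) && length(ppi) == 1L) {
    p <- read_ppi(ppi, weight_scale)
  } else if (is.data.frame(ppi)) {
    if (ncol(ppi) < 3L) stop("'ppi' data frame needs 3 columns", call. = FALSE)
    p <- .build_ppi(as.character(ppi[[1L]]), as.character(ppi[[2L]]),
                    as.numeric(ppi[[3L]]), weight_scale)
  } else stop("'ppi' must be a file path or a data frame", call. = FALSE)
  rel <- .as_pairs(relations, c("protein", "adr"), "relations")
  adrs <- .sort_ids(rel$adr)
  B <- read_relations(rel, p$proteins, adrs, on_missing)
  if (!is.null(adr_sim)) {
    C <- read_adr_similarity(adr_sim, adrs)
  } else if (!is.null(drug_adr)) {
    C <- adr_similarity(drug_adr, adrs)
  } else {
    C <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                      dims = c(length(adrs), length(adrs)),
                      dimnames = list(adrs, adrs))
  }
  hetero_network(p$A, B, C, p$proteins, adrs)
}

#' Known proteins of an ADR
#'
#' @param net A `hetero_network`.
#' @param adr One ADR id.
#' @return Character vector of proteins with a known relation to `adr`.
#' @export
known_proteins <- function(net, adr) {
  j <- match(adr, net$adrs)
  if (is.na(j)) stop("unknown ADR: ", adr, call. = FALSE)
  net$proteins[net$B[, j] != 0]
}

#' Extract the gold-standard relations of a network as a data frame
#'
#' @param net A `hetero_network`.
#' @return Data frame with columns `protein` and `adr`, one row per known
#'   relation, in column-major (ADR-major) order.
#' @export
gold_relations <- function(net) {
  idx <- which(net$B != 0, arr.ind = TRUE)
  df <- data.frame(protein = net$proteins[idx[, 1L]],
                   adr = net$adrs[idx[, 2L]], stringsAsFactors = FALSE)
  df[order(match(df$adr, net$adrs), match(df$protein, net$proteins)), ,
     drop = FALSE]
}
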