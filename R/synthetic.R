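# Synthetic tripartite drug-ADR-protein fixtures with planted signal.
#
# The generator emulates the structure the predictor assumes: proteins live
# in modules of a planted-partition (stochastic block) PPI graph; ADRs are
# assigned to modules and draw their drugs mostly from a module-specific
# pool, so ADRs sharing a module share drugs and get high Jaccard
# similarity; gold protein-ADR relations place each ADR's proteins inside
# its module with probability `signal`, else uniformly. With high signal
# the module of an ADR is recoverable from its similar ADRs' proteins,
# which is exactly the co-localization hypothesis the walk exploits.

#' Configuration for the synthetic fixture generator
#'
#' Defaults describe the standard desk-scale study fixture: 200 proteins in
#' 5 modules, 40 ADRs, 120 drugs, about 3 gold relations and 8 drugs per
#' ADR, planted signal 0.9.
#'
#' @param n_proteins,n_adrs,n_drugs,n_modules Counts (all >= 1;
#'   `n_modules <= n_proteins`).
#' @param p_intra,p_inter Within/between-module PPI edge probabilities for
#'   the planted-partition topology.
#' @param w_min PPI edge weights are drawn uniformly from `[w_min, 1]`.
#' @param relations_per_adr Mean number of gold relations per ADR (counts
#'   are `1 + Poisson(relations_per_adr - 1)`, or exactly this value when
#'   `fixed_counts = TRUE`).
#' @param drugs_per_adr Mean number of drugs per ADR (>= 1; same scheme).
#' @param drug_module_affinity Probability that a drug of an ADR is drawn
#'   from the ADR's module pool rather than from all drugs.
#' @param signal Probability in `[0, 1]` that a gold relation's protein
#'   lies in the ADR's module; 0 plants no signal at all.
#' @param topology `"planted"` (stochastic block model, default) or
#'   `"scale_free"` (preferential attachment; modules then shape only the
#'   drug and relation layers, not the PPI topology).
#' @param fixed_counts Use exact instead of Poisson per-ADR counts.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 200L, n_adrs = 40L,
                             n_drugs = 120L, n_modules = 5L,
                             p_intra = 0.35, p_inter = 0.02, w_min = 0.3,
                             relations_per_adr = 3, drugs_per_adr = 8,
                             drug_module_affinity = 0.9, signal = 0.9,
                             topology = c("planted", "scale_free"),
                             fixed_counts = FALSE, seed = 1L) {
  topology <- match.arg(topology)
  cnt <- c(n_proteins = n_proteins, n_adrs = n_adrs, n_drugs = n_drugs,
           n_modules = n_modules)
  if (any(cnt < 1))
    stop("counts must all be >= 1", call. = FALSE)
  if (n_modules > n_proteins)
    stop("more modules than proteins is infeasible", call. = FALSE)
  if (n_modules > n_drugs)
    stop("need at least one drug per module", call. = FALSE)
  .check_prob(p_intra, "p_intra"); .check_prob(p_inter, "p_inter")
  .check_prob(drug_module_affinity, "drug_module_affinity")
  .check_prob(signal, "signal")
  if (w_min < 0 || w_min >= 1)
    stop("'w_min' must lie in [0, 1)", call. = FALSE)
  if (relations_per_adr < 1 || drugs_per_adr < 1)
    stop("per-ADR means must be >= 1", call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_adrs = as.integer(n_adrs),
                 n_drugs = as.integer(n_drugs),
                 n_modules = as.integer(n_modules),
                 p_intra = p_intra, p_inter = p_inter, w_min = w_min,
                 relations_per_adr = relations_per_adr,
                 drugs_per_adr = drugs_per_adr,
                 drug_module_affinity = drug_module_affinity,
                 signal = signal, topology = topology,
                 fixed_counts = fixed_counts, seed = as.integer(seed)),
            class = "synthetic_config")
}

# sample() without the length-1 surprise
.samp <- function(x, size, replace = FALSE) x[sample.int(length(x), size, replace = replace)]

# Per-ADR count draw: exact or 1 + Poisson(mean - 1).
.count_draw <- function(mean, fixed) {
  if (fixed) as.integer(round(mean)) else 1L + rpois(1L, mean - 1)
}

#' Generate a synthetic tripartite fixture
#'
#' Draws the PPI graph, the drug-ADR table and the gold-standard relations
#' described by a [synthetic_config()], optionally writing them as the
#' three TSV inputs plus a JSON sidecar with the hidden module assignments.
#' Gold relations only ever name proteins with at least one PPI edge, so
#' the files re-load through [build_network()] without warnings.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory; when given, writes `ppi.tsv`,
#'   `drug_adr.tsv`, `relations.tsv` and `truth.json`.
#' @return Object of class `synthetic_truth`: list with data frames `ppi`
#'   (`protein_a`, `protein_b`, `weight`), `drug_adr` (`drug`, `adr`),
#'   `relations` (`protein`, `adr`), the named module assignments
#'   `protein_modules` and `adr_modules`, and `config`.
#' @export
generate_synthetic <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  K <- config$n_modules
  n <- config$n_proteins
  m <- config$n_adrs
  sizes <- diff(floor(seq(0, n, length.out = K + 1L)))
  pmods <- rep(seq_len(K), times = sizes)
  proteins <- sprintf("P%04d", seq_len(n))
  if (config$topology == "planted") {
    pref <- matrix(config$p_inter, K, K)
    diag(pref) <- config$p_intra
    g <- sample_sbm(n, pref.matrix = pref, block.sizes = sizes)
  } else {
    g <- sample_pa(n, power = 1, m = 3, directed = FALSE)
  }
  el <- as_edgelist(g, names = FALSE)
  ppi <- data.frame(protein_a = proteins[el[, 1L]],
                    protein_b = proteins[el[, 2L]],
                    weight = runif(nrow(el), config$w_min, 1),
                    stringsAsFactors = FALSE)
  connected <- proteins[degree(g) > 0]
  adrs <- sprintf("ADR%03d", seq_len(m))
  amods <- sample.int(K, m, replace = TRUE)
  drugs <- sprintf("D%04d", seq_len(config$n_drugs))
  dmods <- rep_len(seq_len(K), config$n_drugs)
  da <- vector("list", m)
  for (j in seq_len(m)) {
    nd <- .count_draw(config$drugs_per_adr, config$fixed_counts)
    pool <- drugs[dmods == amods[j]]
    n_aff <- min(rbinom(1L, nd, config$drug_module_affinity), length(pool))
    from_pool <- .samp(pool, n_aff)
    rest <- setdiff(drugs, from_pool)
    from_any <- .samp(rest, min(nd - n_aff, length(rest)))
    da[[j]] <- data.frame(drug = c(from_pool, from_any), adr = adrs[j],
                          stringsAsFactors = FALSE)
  }
  rel <- vector("list", m)
  for (j in seq_len(m)) {
    nr <- .count_draw(config$relations_per_adr, config$fixed_counts)
    mod_pool <- intersect(proteins[pmods == amods[j]], connected)
    n_mod <- min(rbinom(1L, nr, config$signal), length(mod_pool))
    from_mod <- .samp(mod_pool, n_mod)
    rest <- setdiff(connected, from_mod)
    from_any <- .samp(rest, min(nr - n_mod, length(rest)))
    rel[[j]] <- data.frame(protein = c(from_mod, from_any), adr = adrs[j],
                           stringsAsFactors = FALSE)
  }
  truth <- structure(
    list(ppi = ppi, drug_adr = do.call(rbind, da),
         relations = do.call(rbind, rel),
         protein_modules = stats::setNames(pmods, proteins),
         adr_modules = stats::setNames(amods, adrs),
         config = config),
    class = "synthetic_truth")
  rownames(truth$drug_adr) <- NULL
  rownames(truth$relations) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, file) {
      con <- .out_con(file.path(dir, file))
      on.exit(close(con))
      write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    wt(truth$ppi, "ppi.tsv")
    wt(truth$drug_adr, "drug_adr.tsv")
    wt(truth$relations, "relations.tsv")
    write_json(list(config = unclass(config),
                    protein_modules = as.list(truth$protein_modules),
                    adr_modules = as.list(truth$adr_modules)),
               file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  truth
}

#' Summarize a synthetic fixture
#'
#' @param truth A `synthetic_truth`.
#' @return Object of class `synthetic_summary`: node/edge counts, mean gold
#'   relations and drugs per ADR, and a PPI degree summary (mean, max, and
#'   the share of nodes in the top degree decile's tail).
#' @export
summarize_synthetic <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  prot <- .sort_ids(c(truth$ppi$protein_a, truth$ppi$protein_b))
  deg <- table(factor(c(truth$ppi$protein_a, truth$ppi$protein_b),
                      levels = prot))
  structure(list(
    n_proteins = length(prot),
    n_ppi_edges = nrow(truth$ppi),
    n_adrs = length(unique(truth$relations$adr)),
    n_drugs = length(unique(truth$drug_adr$drug)),
    n_relations = nrow(truth$relations),
    mean_relations_per_adr = nrow(truth$relations) /
      length(unique(truth$relations$adr)),
    mean_drugs_per_adr = nrow(truth$drug_adr) /
      length(unique(truth$drug_adr$adr)),
    degree_mean = mean(deg), degree_max = max(deg),
    degree_p90 = as.numeric(stats::quantile(deg, 0.9))),
    class = "synthetic_summary")
}

#' @export
print.synthetic_summary <- function(x, ...) {
  cat("Synthetic fixture summary\n")
  cat(sprintf("  proteins: %d, PPI edges: %d\n", x$n_proteins, x$n_ppi_edges))
  cat(sprintf("  ADRs: %d, drugs: %d, gold relations: %d\n", x$n_adrs,
              x$n_drugs, x$n_relations))
  cat(sprintf("  mean relations/ADR: %.2f, mean drugs/ADR: %.2f\n",
              x$mean_relations_per_adr, x$mean_drugs_per_adr))
  cat(sprintf("  PPI degree: mean %.1f, p90 %.0f, max %d\n", x$degree_mean,
              x$degree_p90, x$degree_max))
  invisible(x)
}

#' Permute gold-standard labels (null model)
#'
#' Reassigns each ADR's related proteins to a uniform draw (without
#' replacement, preserving the per-ADR relation count) from the eligible
#' protein pool, destroying any planted protein-module alignment. Uses the
#' current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param relations Data frame whose first two columns are protein and ADR.
#' @param proteins Pool of eligible protein ids to draw from.
#' @return Data frame of permuted `(protein, adr)` pairs.
#' @export
permute_relations <- function(relations, proteins) {
  df <- .as_pairs(relations, c("protein", "adr"), "relations")
  out <- lapply(split(df$protein, df$adr), function(p)
    .samp(proteins, min(length(p), length(proteins))))
  data.frame(protein = unlist(out, use.names = FALSE),
             adr = rep(names(out), lengths(out)),
             stringsAsFactors = FALSE)
}
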