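# Leave-one-out cross-validation and ROC/AUC.
#
# One fold per gold-standard relation (protein, adr): the held-out edge is
# removed from B before any seeding or scoring, the focus ADR plus its
# remaining known proteins seed the walk, and the rank of the test protein
# among the candidates (all proteins minus the remaining knowns, so the
# test protein is always a candidate) is recorded.
#
# Ranks are pooled across ADRs as normalized ranks
#   nr = (rank - 1) / (n_candidates - 1),
# the per-fold Mann-Whitney statistic complement: nr = 0 means the test
# protein beat every other candidate, nr = 1 means it lost to all. The ROC
# sweeps every distinct normalized rank as a threshold, with sensitivity
# the fraction of folds at or below the threshold and 1 - specificity the
# fraction of candidates above it (= the threshold itself under pooling).

.loocv_methods <- c("inpadr", "hypergeometric", "rwr_ppi")

#' Leave-one-out cross-validation of protein-ADR ranking
#'
#' @param net A [hetero_network()] carrying the gold-standard relations in
#'   its bipartite layer.
#' @param method `"inpadr"` (integrated-network walk), `"hypergeometric"`
#'   (enrichment baseline, see [rank_by_enrichment()]), `"rwr_ppi"`
#'   (PPI-only walk, see [rwr_ppi()]; folds whose ADR retains no seed
#'   protein are recorded as skipped), or a function
#'   `function(net_without_edge, spec)` returning a `rank_result`.
#' @param r,lambda,eta Walk parameters (ignored where a method does not use
#'   them).
#' @param tol,max_iter Convergence controls.
#' @return Object of class `cv_report`: list with `folds` (data frame:
#'   `protein`, `adr`, `status`, `rank`, `n_candidates`, `norm_rank`),
#'   `roc`, `auc`, `method`, `params`, `n_folds`, `n_failed`.
#' @export
loocv <- function(net, method = c("inpadr", "hypergeometric", "rwr_ppi"),
                  r = 0.7, lambda = 0.5, eta = 0.5, tol = 1e-10,
                  max_iter = 1000L) {
  stopifnot(inherits(net, "hetero_network"))
  if (is.function(method)) {
    fun <- method
    label <- "custom"
  } else {
    label <- match.arg(method)
    fun <- NULL
  }
  rel <- gold_relations(net)
  if (nrow(rel) == 0L)
    stop("the network carries no gold-standard relations", call. = FALSE)
  nf <- nrow(rel)
  rank_v <- rep(NA_real_, nf)
  ncand_v <- rep(NA_integer_, nf)
  status <- character(nf)
  for (f in seq_len(nf)) {
    prot <- rel$protein[f]; adr <- rel$adr[f]
    i <- match(prot, net$proteins); j <- match(adr, net$adrs)
    net2 <- net
    net2$B[i, j] <- 0
    net2$B <- drop0(net2$B)
    remaining <- known_proteins(net2, adr)
    # the held-out edge must be gone before seeding
    stopifnot(!(prot %in% remaining))
    res <- tryCatch(
      suppressWarnings(switch(label,
        inpadr = inpadr_rank(net2, adr, seed_proteins = remaining, r = r,
                             lambda = lambda, eta = eta, tol = tol,
                             max_iter = max_iter),
        hypergeometric = rank_by_enrichment(net2, adr),
        rwr_ppi = rwr_ppi(net2, adr, r = r, tol = tol, max_iter = max_iter),
        custom = fun(net2, seed_spec(adr, remaining, eta = eta, r = r)))),
      error = function(e) e)
    if (inherits(res, "error")) {
      status[f] <- paste0("failed: ", conditionMessage(res))
      next
    }
    hit <- match(prot, res$protein)
    if (is.na(hit)) {
      status[f] <- "failed: test protein not in candidate set"
      next
    }
    status[f] <- "ok"
    rank_v[f] <- res$rank[hit]
    ncand_v[f] <- attr(res, "n_candidates")
  }
  folds <- data.frame(protein = rel$protein, adr = rel$adr, status = status,
                      rank = rank_v, n_candidates = ncand_v,
                      stringsAsFactors = FALSE)
  folds$norm_rank <- ifelse(folds$n_candidates > 1L,
                            (folds$rank - 1) / (folds$n_candidates - 1), 0)
  ok <- folds$status == "ok"
  if (any(!ok))
    warning(sum(!ok), " of ", nf, " fold(s) failed or were skipped",
            call. = FALSE)
  if (!any(ok))
    stop("no fold produced a ranking", call. = FALSE)
  ra <- roc_auc(folds[ok, , drop = FALSE])
  structure(list(folds = folds, roc = ra$roc, auc = ra$auc, method = label,
                 params = list(r = r, lambda = lambda, eta = eta),
                 n_folds = nf, n_failed = sum(!ok)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LOOCV [%s]: %d folds (%d failed/skipped), AUC = %.4f\n",
              x$method, x$n_folds, x$n_failed, x$auc))
  cat(sprintf("  params: r = %g, lambda = %g, eta = %g\n", x$params$r,
              x$params$lambda, x$params$eta))
  invisible(x)
}

#' ROC curve and AUC from LOOCV folds
#'
#' Sweeps every distinct normalized rank as a threshold: sensitivity is the
#' fraction of folds whose normalized rank is at or below the threshold,
#' and 1 - specificity equals the threshold (the fraction of candidate
#' proteins ranked above it, pooled on the normalized scale). The curve is
#' the exact step polygon (vertical jump then horizontal run), so its
#' trapezoidal area equals the Mann-Whitney statistic of the normalized
#' ranks against a uniform reference.
#'
#' @param folds A `cv_report` folds data frame (columns `rank` and
#'   `n_candidates`, or a precomputed `norm_rank`), or a bare numeric
#'   vector of normalized ranks in `[0, 1]`.
#' @return List with `roc` (data frame `fpr`, `tpr` from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(folds) {
  if (is.numeric(folds)) {
    nr <- folds
  } else if (!is.null(folds$norm_rank)) {
    nr <- folds$norm_rank
  } else {
    nr <- ifelse(folds$n_candidates > 1L,
                 (folds$rank - 1) / (folds$n_candidates - 1), 0)
  }
  nr <- nr[!is.na(nr)]
  if (length(nr) == 0L) stop("no folds to evaluate", call. = FALSE)
  if (any(nr < 0 | nr > 1))
    stop("normalized ranks must lie in [0, 1]", call. = FALSE)
  th <- sort(unique(nr))
  cdf <- cumsum(tabulate(match(nr, th), nbins = length(th))) / length(nr)
  pre <- c(0, cdf[-length(cdf)])
  fpr <- c(0, rep(th, each = 2L), 1)
  tpr <- c(0, as.vector(rbind(pre, cdf)), 1)
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1L]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Sweep one walk parameter over a grid of LOOCV runs
#'
#' Runs a full leave-one-out cross-validation per value of `lambda`, `eta`
#' or `r`, holding the other parameters at their defaults (0.5, 0.5, 0.7).
#'
#' @param net A [hetero_network()].
#' @param param One of `"lambda"`, `"eta"`, `"r"`.
#' @param values Numeric grid within the parameter's valid range.
#' @param ... Passed on to [loocv()] (e.g. `method`).
#' @return Data frame with columns `param`, `value`, `auc`, `n_folds`,
#'   `n_failed`.
#' @export
parameter_sweep <- function(net, param = c("lambda", "eta", "r"), values,
                            ...) {
  param <- match.arg(param)
  hi_open <- param == "r"
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1) ||
      (hi_open && any(values <= 0)))
    stop("'values' outside the valid range of ", param, call. = FALSE)
  rows <- lapply(values, function(v) {
    args <- c(list(net = net), stats::setNames(list(v), param), list(...))
    rep <- do.call(loocv, args)
    data.frame(param = param, value = v, auc = rep$auc,
               n_folds = rep$n_folds, n_failed = rep$n_failed)
  })
  do.call(rbind, rows)
}
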