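# Hallmark-signature activity via the weighted Kolmogorov-Smirnov
# running-sum enrichment statistic, stepwise pairwise organoid comparisons
# with a gene-relabeling permutation null, per-sample activity, and group
# activity correlations.

# Core running-sum ES given the metric sorted in ranking order and a logical
# hit indicator along that order.  Hit steps are proportional to
# |metric|^weight normalized over hits; misses step down by 1/(N - Nh).
# ES is the signed maximum deviation of the running sum from zero.  When all
# hit weights are zero (e.g. weight > 0 with a flat metric) hits step
# uniformly, the unweighted statistic.
es_running <- function(stat_sorted, hits, weight = 1) {
  n <- length(stat_sorted)
  nh <- sum(hits)
  nm <- n - nh
  w <- abs(stat_sorted)^weight
  hw <- ifelse(hits, w, 0)
  s <- sum(hw)
  inc <- if (s > 0) hw / s else hits / nh
  run <- cumsum(inc - (!hits) / nm)
  pos <- max(run); neg <- min(run)
  # signed maximum deviation; an (effectively) exact magnitude tie between
  # the extremes resolves to the positive deviation
  if (pos >= -neg - 1e-12) pos else neg
}

#' Running-sum enrichment score of a gene set on a ranked list
#'
#' The classical weighted Kolmogorov-Smirnov statistic: walking down the
#' ranking, in-set genes add an increment proportional to `|metric|^weight`
#' (normalized over in-set genes) and out-of-set genes subtract
#' `1/(N - |set|)`; the enrichment score is the signed maximum deviation of
#' this running sum.  `weight = 0` gives the unweighted KS statistic.
#'
#' @param metric named numeric vector (names are gene symbols); the ranking
#'   orders it decreasingly, ties broken by gene symbol.
#' @param members character vector, the signature's genes.
#' @param weight exponent on `|metric|` for hit increments (default 1).
#' @return enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(metric, members, weight = 1) {
  if (is.null(names(metric))) stop("'metric' must be a named numeric vector")
  if (anyDuplicated(names(metric))) stop("duplicate gene names in 'metric'")
  ord <- order(-metric, names(metric))
  ms <- metric[ord]
  hits <- names(ms) %in% members
  if (!any(hits)) stop("no signature gene present in the ranked list")
  if (all(hits)) stop("signature covers the entire ranked list; enrichment undefined")
  es_running(unname(ms), hits, weight)
}

#' Pairwise signature activation test between two organoid groups
#'
#' Ranks genes by the difference of group-mean rank scores (`B` minus `A`;
#' by convention `B` is the organoid with more mutations) and computes each
#' signature's running-sum enrichment score on that ranking.  The null
#' permutes gene labels: each permutation applies one random relabeling of
#' the gene universe to every sample of both groups, equivalent to scoring
#' random gene sets of the same size on the observed ranking.  Activation
#' p-values take the upper tail (permuted ES >= observed), inactivation the
#' lower tail, both with the add-one pseudocount; Benjamini-Hochberg runs
#' within each tail across signatures.
#'
#' @param rs_A,rs_B rank-score matrices over a shared gene universe.
#' @param signatures named list of gene sets (>= 2 recommended; a single
#'   signature is allowed with a warning since FDR is degenerate).
#' @param n_perm permutations (>= 1).
#' @param fdr FDR threshold for calls.
#' @param weight running-sum weight exponent.
#' @param seed integer seed (required).
#' @return data.frame: `signature`, `n_genes_used`, `es_A`, `es_B`,
#'   `es_diff`, `p_act`, `p_inact`, `q_act`, `q_inact`, `call`
#'   (`activated` / `inactivated` / `ns`).
#' @export
pairwise_signature_test <- function(rs_A, rs_B, signatures, n_perm = 1000,
                                    fdr = 0.05, weight = 1, seed) {
  rs_A <- as_rank_scores(rs_A); rs_B <- as_rank_scores(rs_B)
  if (n_perm < 1L) stop("'n_perm' must be at least 1")
  if (!setequal(rownames(rs_A), rownames(rs_B))) {
    stop("the two groups must share one gene universe")
  }
  rs_B <- rs_B[rownames(rs_A), , drop = FALSE]
  if (length(signatures) < 1L) stop("at least one signature is required")
  if (length(signatures) == 1L) {
    warning("only one signature: FDR adjustment is degenerate")
  }
  genes <- rownames(rs_A)
  n <- length(genes)
  mA <- rowMeans(rs_A)
  mB <- rowMeans(rs_B)
  metric <- mB - mA
  degenerate <- stats::sd(metric) == 0
  if (degenerate) {
    warning("the two groups have identical mean score profiles; ",
            "all signatures are reported non-significant")
  }
  ord <- order(-metric, genes)
  ms <- unname(metric[ord])
  gidx_sorted <- ord                       # gene index occupying each ranking slot

  memvec <- lapply(signatures, function(m) genes %in% m)
  used <- vapply(memvec, function(v) sum(v) >= 1L && sum(v) < n, logical(1L))
  if (!all(used)) {
    warning("skipping ", sum(!used), " signature(s) empty (or universe-covering) ",
            "after intersection: ", paste(names(signatures)[!used], collapse = ", "))
  }
  if (!any(used)) stop("no usable signatures")
  memvec <- memvec[used]
  signatures <- signatures[used]
  ns <- length(signatures)

  es_obs <- vapply(seq_len(ns), function(j) {
    es_running(ms, memvec[[j]][gidx_sorted], weight)
  }, numeric(1L))
  es_A <- vapply(seq_len(ns), function(j) {
    enrichment_score(mA, signatures[[j]], weight)
  }, numeric(1L))
  es_B <- vapply(seq_len(ns), function(j) {
    enrichment_score(mB, signatures[[j]], weight)
  }, numeric(1L))

  up <- integer(ns); dn <- integer(ns)
  if (degenerate) {
    up <- rep(n_perm, ns); dn <- rep(n_perm, ns)
  } else with_seed(seed, {
    for (b in seq_len(n_perm)) {
      rel <- sample.int(n)                 # gene relabeling
      mapped <- rel[gidx_sorted]
      for (j in seq_len(ns)) {
        e <- es_running(ms, memvec[[j]][mapped], weight)
        if (e >= es_obs[j]) up[j] <- up[j] + 1L
        if (e <= es_obs[j]) dn[j] <- dn[j] + 1L
      }
    }
  })
  p_act <- (1 + up) / (n_perm + 1)
  p_inact <- (1 + dn) / (n_perm + 1)
  q_act <- stats::p.adjust(p_act, method = "BH")
  q_inact <- stats::p.adjust(p_inact, method = "BH")
  call <- rep("ns", ns)
  call[q_act <= fdr & p_act < p_inact] <- "activated"
  call[q_inact <= fdr & p_inact < p_act] <- "inactivated"
  data.frame(signature = names(signatures),
             n_genes_used = vapply(memvec, sum, integer(1L)),
             es_A = es_A, es_B = es_B, es_diff = es_obs,
             p_act = p_act, p_inact = p_inact,
             q_act = q_act, q_inact = q_inact,
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample signature activity (single-sample enrichment)
#'
#' For each sample, genes are ranked by that sample's rank scores and each
#' signature's running-sum enrichment score is computed, giving a
#' signatures x samples activity matrix.
#'
#' @param rs rank-score matrix.
#' @param signatures named list of gene sets.
#' @param weight running-sum weight exponent.
#' @return numeric matrix, signatures x samples.
#' @export
sample_signature_activity <- function(rs, signatures, weight = 1) {
  rs <- as_rank_scores(rs)
  out <- matrix(NA_real_, nrow = length(signatures), ncol = ncol(rs),
                dimnames = list(names(signatures), colnames(rs)))
  for (s in seq_len(ncol(rs))) {
    metric <- rs[, s]
    for (j in seq_along(signatures)) {
      out[j, s] <- enrichment_score(metric, signatures[[j]], weight)
    }
  }
  out
}

#' Group-level and sample-level activity correlations
#'
#' Computes per-group mean activity profiles (columns averaged within each
#' group), the Pearson correlation matrix between those group means, and
#' the Pearson correlation matrix between all sample activity columns.
#' Zero-variance activity vectors yield `NA` correlations with a warning.
#'
#' @param activity signatures x samples matrix, e.g. from
#'   [sample_signature_activity()].
#' @param groups `sample_groups` object (or named list with `samples`).
#' @return list with `group_means`, `group_cor`, `sample_cor`.
#' @export
group_activity_correlation <- function(activity, groups) {
  if (nrow(activity) < 2L) stop("at least 2 signatures are required to correlate activities")
  gm <- vapply(groups, function(g) {
    ids <- g$samples
    if (!all(ids %in% colnames(activity))) {
      stop("group samples missing from the activity matrix: ",
           paste(setdiff(ids, colnames(activity)), collapse = ", "))
    }
    rowMeans(activity[, ids, drop = FALSE])
  }, numeric(nrow(activity)))
  colnames(gm) <- names(groups)
  sds <- apply(gm, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance group activity vector(s): ",
            paste(colnames(gm)[sds == 0], collapse = ", "),
            "; correlations involving them are NA")
  }
  gcor <- suppressWarnings(stats::cor(gm))
  scor <- suppressWarnings(stats::cor(activity))
  list(group_means = gm, group_cor = gcor, sample_cor = scor)
}
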