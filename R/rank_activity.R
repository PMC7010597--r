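# Rank-based score transform, normalized-centroid functional activity, and
# permutation-tested identification of dysregulated functions between an
# organoid group (S) and its matched tumor group (T).

#' Rank-based score transform
#'
#' Per sample, genes are sorted by decreasing expression; the gene of rank
#' `i` among `N` genes receives the score `exp(-i / N)`, so the highest
#' expressed gene (rank 1) scores just below 1 and the lowest scores
#' `exp(-1)`.  Scores depend only on within-sample ranks, which is what
#' makes profiles from different platforms jointly analyzable.  Ties in
#' expression are broken by gene symbol (lexicographic), keeping the
#' transform deterministic.
#'
#' @param expr numeric expression matrix (genes x samples) with unique
#'   rownames/colnames; see [validate_expression()].
#' @return numeric matrix of scores in `(0, 1]` with attribute `n_genes`,
#'   classed `rank_scores`.
#' @export
rank_transform <- function(expr) {
  validate_expression(expr)
  n <- nrow(expr)
  genes <- rownames(expr)
  scores <- matrix(NA_real_, nrow = n, ncol = ncol(expr),
                   dimnames = dimnames(expr))
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], genes)   # decreasing expression, ties by symbol
    rk <- integer(n)
    rk[ord] <- seq_len(n)
    scores[, j] <- exp(-rk / n)
  }
  structure(scores, n_genes = n, class = c("rank_scores", "matrix", "array"))
}

# Coerce/validate a rank-score matrix.
as_rank_scores <- function(rs) {
  if (!is.matrix(rs) || !is.numeric(rs)) stop("rank scores must be a numeric matrix")
  if (is.null(rownames(rs)) || is.null(colnames(rs))) {
    stop("rank-score matrix needs gene rownames and sample colnames")
  }
  rs
}

#' Functional activity score (FAS) of a gene set, per sample
#'
#' The normalized-centroid shift: the mean rank score of the function's
#' genes minus the mean rank score of all remaining genes, computed per
#' sample.  Genes of the set absent from the score matrix are ignored.
#'
#' @param rs rank-score matrix from [rank_transform()].
#' @param members character vector of the function's gene symbols.
#' @param detail if `TRUE`, also return the two centroids.
#' @return named numeric vector of FAS per sample, or (with
#'   `detail = TRUE`) a list with `fas`, `nc_in`, `nc_out`.
#' @export
compute_fas <- function(rs, members, detail = FALSE) {
  rs <- as_rank_scores(rs)
  inset <- rownames(rs) %in% members
  k <- sum(inset)
  if (k == 0L) stop("none of the function's genes are present in the score matrix")
  if (k == nrow(rs)) stop("function covers the whole gene universe; no complement to compare against")
  nc_in <- colMeans(rs[inset, , drop = FALSE])
  nc_out <- colMeans(rs[!inset, , drop = FALSE])
  fas <- nc_in - nc_out
  if (detail) list(fas = fas, nc_in = nc_in, nc_out = nc_out) else fas
}

#' Functional activity table over a gene-set collection
#'
#' @param rs rank-score matrix.
#' @param functions named list of gene sets (e.g. from [read_gmt()]).
#' @return numeric matrix, functions x samples.
#' @export
fas_table <- function(rs, functions) {
  rs <- as_rank_scores(rs)
  out <- t(vapply(functions, function(m) compute_fas(rs, m),
                  numeric(ncol(rs))))
  rownames(out) <- names(functions)
  out
}

# Sparse membership matrix (functions x genes) used to vectorize FAS over
# many gene sets: FAS(j) = (M w)/k_j - (sum(w) - M w)/(N - k_j) for a score
# vector w, which by linearity also gives group-mean FAS from the group-mean
# score vector.
membership_matrix <- function(functions, genes) {
  idx <- lapply(functions, function(m) which(genes %in% m))
  Matrix::sparseMatrix(
    i = rep.int(seq_along(idx), lengths(idx)),
    j = unlist(idx, use.names = FALSE),
    x = 1,
    dims = c(length(functions), length(genes)),
    dimnames = list(names(functions), NULL))
}

fas_from_meanvec <- function(M, w, sizes) {
  n <- length(w)
  inside <- as.numeric(M %*% w)
  inside / sizes - (sum(w) - inside) / (n - sizes)
}

#' Permutation test for dysregulated functions
#'
#' For each function, the dysregulation statistic is
#' `DFAS = |mean_S FAS - mean_T FAS|`, the absolute difference between the
#' organoid group's and the tumor group's average functional activity.
#' Significance comes from a gene-relabeling null: each permutation draws
#' one random relabeling of the gene universe and applies it to every
#' sample of both groups, which preserves each sample's score distribution
#' and the cross-sample correlation structure, and amounts to scoring the
#' observed set against random gene sets of equal size.  Empirical p-values
#' use the add-one rule `p = (1 + #{DFAS_perm >= DFAS}) / (n_perm + 1)`;
#' Benjamini-Hochberg q-values are thresholded at `fdr`.
#'
#' Functions with fewer than 3 member genes in the shared universe (or
#' covering the whole universe) are skipped with a warning.
#'
#' @param rs_S,rs_T rank-score matrices for the two groups over the same
#'   gene universe.
#' @param functions named list of gene sets.
#' @param n_perm number of permutations (>= 1).
#' @param fdr FDR threshold for the dysregulation call.
#' @param seed integer seed (required).
#' @return data.frame with columns `function_name`, `n_genes_used`,
#'   `fas_S_mean`, `fas_T_mean`, `dfas`, `p`, `q`, `dysregulated`.
#' @export
dysregulation_test <- function(rs_S, rs_T, functions, n_perm = 1000,
                               fdr = 0.01, seed) {
  rs_S <- as_rank_scores(rs_S); rs_T <- as_rank_scores(rs_T)
  if (n_perm < 1L) stop("'n_perm' must be at least 1")
  if (!setequal(rownames(rs_S), rownames(rs_T))) {
    stop("the two groups must share one gene universe")
  }
  rs_T <- rs_T[rownames(rs_S), , drop = FALSE]
  genes <- rownames(rs_S)
  n <- length(genes)
  if (is.null(names(functions))) stop("'functions' must be a named list of gene sets")

  sizes_all <- vapply(functions, function(m) sum(genes %in% m), integer(1L))
  usable <- sizes_all >= 3L & sizes_all < n
  if (any(!usable)) {
    warning("skipping ", sum(!usable), " function(s) with <3 genes in the ",
            "universe or covering it entirely: ",
            paste(names(functions)[!usable], collapse = ", "))
  }
  if (!any(usable)) stop("no usable functions after intersecting with the gene universe")
  functions <- functions[usable]
  sizes <- sizes_all[usable]

  M <- membership_matrix(functions, genes)
  wS <- rowMeans(rs_S)
  wT <- rowMeans(rs_T)
  fas_S <- fas_from_meanvec(M, wS, sizes)
  fas_T <- fas_from_meanvec(M, wT, sizes)
  dfas <- abs(fas_S - fas_T)

  exceed <- integer(length(dfas))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      d <- abs(fas_from_meanvec(M, wS[p], sizes) -
               fas_from_meanvec(M, wT[p], sizes))
      exceed <- exceed + (d >= dfas)
    }
  })
  pval <- (1 + exceed) / (n_perm + 1)
  qval <- stats::p.adjust(pval, method = "BH")
  data.frame(function_name = names(functions),
             n_genes_used = sizes,
             fas_S_mean = fas_S,
             fas_T_mean = fas_T,
             dfas = dfas,
             p = pval,
             q = qval,
             dysregulated = qval <= fdr,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Binary dysregulation matrix across organoid types
#'
#' @param records named list of [dysregulation_test()] results, one per
#'   organoid type; all must cover the same functions.
#' @return integer matrix functions x types; 1 marks a dysregulated
#'   function.
#' @export
dysregulation_matrix <- function(records) {
  if (is.null(names(records))) stop("'records' must be a named list, one entry per organoid type")
  fns <- records[[1L]]$function_name
  for (r in records) {
    if (!identical(sort(r$function_name), sort(fns))) {
      stop("all organoid types must cover the same function universe")
    }
  }
  out <- vapply(records, function(r) {
    as.integer(r$dysregulated[match(fns, r$function_name)])
  }, integer(length(fns)))
  out <- matrix(out, nrow = length(fns),
                dimnames = list(fns, names(records)))
  out
}
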