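# Subsequent-key-gene inference: seed selection from dysregulated pathway
# hubs, random walk with restart on the interaction network, pseudo-seed
# empirical significance, Fisher chi-square combination across dysregulated
# functions, FDR key-gene calling.

#' Select seed genes from a pathway graph
#'
#' Ranks the pathway's genes by their degree within the pathway graph
#' (descending, ties at the cutoff broken by gene symbol) and takes the top
#' `ceiling(fraction * |pathway|)` (at least 1).  Selected seeds absent from
#' the interaction network are dropped afterwards; it is an error if none
#' survives.
#'
#' @param pathway connected undirected `igraph` pathway graph.
#' @param network undirected `igraph` interaction network.
#' @param fraction fraction of pathway genes to take (default 0.10).
#' @return list with `seeds` (character), `degrees` (named, pathway
#'   degrees of the seeds), `pathway_name`.
#' @export
select_seeds <- function(pathway, network, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  pgenes <- igraph::V(pathway)$name
  netgenes <- igraph::V(network)$name
  if (!any(pgenes %in% netgenes)) {
    stop("no pathway gene is present in the interaction network")
  }
  deg <- igraph::degree(pathway)
  ord <- order(-deg, pgenes)
  n_take <- max(1L, ceiling(fraction * length(pgenes)))
  sel <- pgenes[ord][seq_len(n_take)]
  kept <- sel[sel %in% netgenes]
  if (length(kept) == 0L) {
    stop("all selected seed genes are absent from the interaction network")
  }
  list(seeds = kept,
       degrees = deg[kept],
       pathway_name = igraph::graph_attr(pathway, "name") %||% NA_character_)
}

# Column-stochastic transfer matrix of an undirected network.  Degree-zero
# nodes get a unit self-loop column so every column sums to 1.
transfer_matrix <- function(network) {
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  deg <- Matrix::colSums(A)
  iso <- which(deg == 0)
  if (length(iso) > 0L) {
    A[cbind(iso, iso)] <- 1
    deg[iso] <- 1
  }
  A %*% Matrix::Diagonal(x = 1 / deg)
}

rwr_p0 <- function(nodes, seeds) {
  if (!all(seeds %in% nodes)) {
    stop("seed gene(s) not in the network: ",
         paste(setdiff(seeds, nodes), collapse = ", "))
  }
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)
  p0
}

#' Random walk with restart
#'
#' Iterates `P_{t+1} = (1 - r) W P_t + r P_0` where `W` is the
#' column-normalized adjacency of the network and `P_0` places probability
#' `1/n` on each of the `n` seed genes, until
#' `max |P_{t+1} - P_t| < tol`.  The steady state measures each gene's
#' network proximity to the seed set.  `r = 1` returns `P_0` exactly.
#'
#' @param network undirected `igraph`.
#' @param seeds character vector of seed genes, or the list returned by
#'   [select_seeds()].
#' @param r restart probability in `(0, 1]` (default 0.7).
#' @param tol convergence tolerance on the max absolute change
#'   (default 1e-8).
#' @param max_iter iteration bound; exceeding it is an error reporting the
#'   last residual.
#' @return list with `p` (named steady-state probabilities, summing to 1)
#'   and `iterations`.
#' @export
rwr <- function(network, seeds, r = 0.7, tol = 1e-8, max_iter = 10000L) {
  if (r <= 0 || r > 1) stop("restart probability 'r' must be in (0, 1]")
  if (tol <= 0) stop("'tol' must be positive")
  if (is.list(seeds)) seeds <- seeds$seeds
  nodes <- igraph::V(network)$name
  W <- transfer_matrix(network)
  p0 <- rwr_p0(nodes, seeds)
  p <- p0
  for (it in seq_len(max_iter)) {
    pn <- as.numeric((1 - r) * (W %*% p) + r * p0)
    resid <- max(abs(pn - p))
    p <- pn
    if (resid < tol) {
      return(list(p = stats::setNames(p, nodes), iterations = it))
    }
  }
  stop("random walk did not converge within ", max_iter,
       " iterations (last residual ", format(resid, digits = 4), ")")
}

#' Closed-form random-walk-with-restart steady state
#'
#' Solves `P = r (I - (1 - r) W)^{-1} P_0` directly; used as a fast mode
#' and as an independent check on the iterative walk.
#'
#' @inheritParams rwr
#' @return named numeric vector of steady-state probabilities.
#' @export
rwr_solve <- function(network, seeds, r = 0.7) {
  if (r <= 0 || r > 1) stop("restart probability 'r' must be in (0, 1]")
  if (is.list(seeds)) seeds <- seeds$seeds
  nodes <- igraph::V(network)$name
  W <- transfer_matrix(network)
  p0 <- rwr_p0(nodes, seeds)
  A <- Matrix::Diagonal(length(nodes)) - (1 - r) * W
  stats::setNames(as.numeric(Matrix::solve(A, r * p0)), nodes)
}

# Batched RWR: one sparse fixed-point iteration over many P0 columns at
# once.  Exact vectorization of per-column runs (identical fixed points),
# used to make 1,000 pseudo-seed walks affordable.
rwr_batch <- function(W, P0, r, tol, max_iter = 10000L) {
  P <- P0
  for (it in seq_len(max_iter)) {
    Pn <- (1 - r) * (W %*% P) + r * P0
    resid <- max(abs(Pn - P))
    P <- Pn
    if (resid < tol) return(as.matrix(P))
  }
  stop("batched random walk did not converge within ", max_iter, " iterations")
}

#' Pseudo-seed empirical p-values for one dysregulated function
#'
#' Runs the random walk from the function's true seeds, then from
#' `n_random` pseudo-seed sets of the same size drawn uniformly without
#' replacement from the network's nodes (optionally degree-matched), and
#' scores each gene by how often a pseudo-seed steady-state value reaches
#' its observed value:
#' `p = (1 + #{random >= observed}) / (n_random + 1)`.
#'
#' @param network undirected `igraph`.
#' @param seeds character vector or [select_seeds()] result.
#' @param n_random number of pseudo-seed sets (>= 1).
#' @param seed integer seed (required).
#' @param r,tol,max_iter random-walk parameters as in [rwr()].
#' @param degree_matched if `TRUE`, pseudo-seeds are sampled within
#'   decile bins of network degree instead of uniformly.
#' @return named numeric vector of per-gene empirical p-values in `(0, 1]`.
#' @export
function_pvalues <- function(network, seeds, n_random = 1000, seed,
                             r = 0.7, tol = 1e-8, max_iter = 10000L,
                             degree_matched = FALSE) {
  if (n_random < 1L) stop("'n_random' must be at least 1")
  if (is.list(seeds)) seeds <- seeds$seeds
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  if (length(seeds) >= n) {
    stop("seed set must be smaller than the network (",
         length(seeds), " seeds, ", n, " nodes)")
  }
  W <- transfer_matrix(network)
  p0 <- rwr_p0(nodes, seeds)
  obs <- as.numeric(rwr_batch(W, Matrix::Matrix(p0, ncol = 1, sparse = TRUE),
                              r, tol, max_iter))
  k <- length(seeds)
  deg <- igraph::degree(network)
  pool_of <- NULL
  if (degree_matched) {
    bins <- cut(rank(deg, ties.method = "first"), breaks = 10, labels = FALSE)
    seed_bins <- bins[match(seeds, nodes)]
    pool_of <- split(seq_len(n), bins)
  }
  draws <- with_seed(seed, {
    lapply(seq_len(n_random), function(b) {
      if (degree_matched) {
        unlist(lapply(seed_bins, function(bb) {
          sample(pool_of[[bb]], 1L)
        }), use.names = FALSE)
      } else {
        sample.int(n, k)
      }
    })
  })
  P0 <- Matrix::sparseMatrix(
    i = unlist(draws, use.names = FALSE),
    j = rep.int(seq_len(n_random), vapply(draws, length, integer(1L))),
    x = 1 / k, dims = c(n, n_random))
  R <- rwr_batch(W, P0, r, tol, max_iter)
  exceed <- rowSums(R >= obs)
  stats::setNames((1 + exceed) / (n_random + 1), nodes)
}

#' Combine per-function significance by Fisher's method
#'
#' For each gene with p-values `P_1..P_K` over the `K` dysregulated
#' functions, `chi2 = -2 * sum(log P_k)` follows a chi-square distribution
#' with `2K` degrees of freedom under the null; the combined p-value is its
#' upper tail.  Benjamini-Hochberg runs across genes; genes with
#' `q <= fdr` are called subsequent key genes, except genes already mutated
#' in the organoid, which are reported but flagged rather than called.
#'
#' @param pmat numeric matrix genes x K of p-values in `(0, 1]`.
#' @param fdr FDR threshold for the key-gene call (default 0.05).
#' @param mutated_genes genes to exclude from key-gene calls (reported with
#'   `excluded_reason = "driver_mutated"`).
#' @return data.frame sorted by `q` then decreasing `chi2`: `gene`, `K`,
#'   `chi2`, `df`, `p_combined`, `q`, `is_key`, `excluded_reason`.
#' @export
combine_significance <- function(pmat, fdr = 0.05, mutated_genes = character(0L)) {
  pmat <- as.matrix(pmat)
  if (is.null(rownames(pmat))) stop("'pmat' needs gene rownames")
  if (ncol(pmat) < 1L) stop("at least one function's p-values are required (K >= 1)")
  if (any(pmat <= 0)) {
    stop("p-value of 0 encountered; upstream empirical p-values must use the ",
         "add-one pseudocount so p >= 1/(n+1)")
  }
  if (any(pmat > 1)) stop("p-values must lie in (0, 1]")
  K <- ncol(pmat)
  chi2 <- -2 * rowSums(log(pmat))
  p_comb <- stats::pchisq(chi2, df = 2 * K, lower.tail = FALSE)
  q <- stats::p.adjust(p_comb, method = "BH")
  mutated <- rownames(pmat) %in% mutated_genes
  out <- data.frame(gene = rownames(pmat),
                    K = K,
                    chi2 = chi2,
                    df = 2L * K,
                    p_combined = p_comb,
                    q = q,
                    is_key = q <= fdr & !mutated,
                    excluded_reason = ifelse(mutated, "driver_mutated", ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$q, -out$chi2, out$gene), , drop = FALSE]
}

#' Infer subsequent key genes from dysregulated pathways
#'
#' Composes [select_seeds()] (top 10% pathway-degree hubs), per-pathway
#' [function_pvalues()] (pseudo-seed random walks), and
#' [combine_significance()] (Fisher chi-square over the K dysregulated
#' functions, Benjamini-Hochberg across genes).
#'
#' @param network undirected `igraph` interaction network.
#' @param pathways non-empty named list of dysregulated pathway graphs.
#' @param n_random pseudo-seed sets per pathway.
#' @param fdr key-gene FDR threshold.
#' @param fraction seed fraction (default 0.10).
#' @param mutated_genes driver genes already mutated in the organoid;
#'   reported but excluded from key-gene calls.
#' @param seed integer master seed; each pathway's pseudo-seed stream is
#'   derived from it and the pathway's name.
#' @param r,tol,max_iter random-walk parameters.
#' @return list with `table` (the [combine_significance()] data.frame) and
#'   `pvalues` (genes x K matrix of per-function p-values).
#' @export
infer_key_genes <- function(network, pathways, n_random = 1000, fdr = 0.05,
                            fraction = 0.10, mutated_genes = character(0L),
                            seed, r = 0.7, tol = 1e-8, max_iter = 10000L) {
  if (length(pathways) == 0L) stop("at least one dysregulated pathway is required")
  if (is.null(names(pathways))) {
    names(pathways) <- paste0("pathway_", seq_along(pathways))
  }
  nodes <- igraph::V(network)$name
  pmat <- matrix(NA_real_, nrow = length(nodes), ncol = length(pathways),
                 dimnames = list(nodes, names(pathways)))
  for (j in seq_along(pathways)) {
    ss <- select_seeds(pathways[[j]], network, fraction = fraction)
    pmat[, j] <- function_pvalues(network, ss, n_random = n_random,
                                  seed = stage_seed(seed, names(pathways)[j]),
                                  r = r, tol = tol, max_iter = max_iter)[nodes]
  }
  list(table = combine_significance(pmat, fdr = fdr,
                                    mutated_genes = mutated_genes),
       pvalues = pmat)
}
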