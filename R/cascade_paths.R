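# Functional-coherence network over driver + candidate key genes, top-2
# sparsification, and extraction of gene cascading paths ending at the
# candidate farthest from the mutant set.

#' Functional coherence of two genes
#'
#' Default measure: cosine similarity of the genes' binary
#' function-membership vectors over a shared annotation (e.g. the pathway
#' and signature collections the pipeline already loads).  Identical
#' annotation sets give 1, disjoint sets 0.  The measure is pluggable via
#' `method`.
#'
#' @param gene_a,gene_b gene symbols.
#' @param annotation named list mapping gene to a character vector of
#'   function names; both genes must be annotated with at least one
#'   function.
#' @param method a function `(set_a, set_b) -> numeric in [0,1]`; the
#'   default is the cosine over binary membership,
#'   `|A intersect B| / sqrt(|A| * |B|)`.
#' @return numeric in `[0, 1]`.
#' @export
functional_coherence <- function(gene_a, gene_b, annotation, method = NULL) {
  for (g in c(gene_a, gene_b)) {
    a <- annotation[[g]]
    if (is.null(a) || length(a) == 0L) {
      stop("gene '", g, "' has no functional annotation")
    }
  }
  a <- unique(annotation[[gene_a]])
  b <- unique(annotation[[gene_b]])
  if (is.null(method)) {
    length(intersect(a, b)) / sqrt(length(a) * length(b))
  } else {
    method(a, b)
  }
}

#' Invert gene-set collections into a gene-to-functions annotation
#'
#' @param ... one or more named lists of gene sets (as from [read_gmt()]).
#' @return named list mapping each gene to the function names it belongs
#'   to.
#' @export
annotation_from_sets <- function(...) {
  sets <- c(...)
  genes <- unique(unlist(sets, use.names = FALSE))
  ann <- vector("list", length(genes))
  names(ann) <- genes
  for (j in seq_along(sets)) {
    for (g in sets[[j]]) ann[[g]] <- c(ann[[g]], names(sets)[j])
  }
  lapply(ann, unique)
}

#' Pairwise functional-coherence matrix
#'
#' @param genes character vector of genes (all must be annotated).
#' @param annotation gene-to-functions list; see [annotation_from_sets()].
#' @return symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
coherence_matrix <- function(genes, annotation) {
  genes <- unique(genes)
  miss <- genes[vapply(genes, function(g) length(annotation[[g]]) == 0L, logical(1L))]
  if (length(miss) > 0L) {
    stop("gene(s) without functional annotation: ", paste(miss, collapse = ", "))
  }
  fns <- unique(unlist(annotation[genes], use.names = FALSE))
  B <- vapply(genes, function(g) as.numeric(fns %in% annotation[[g]]),
              numeric(length(fns)))
  B <- matrix(B, nrow = length(fns), dimnames = list(fns, genes))
  cp <- crossprod(B)
  nrm <- sqrt(diag(cp))
  C <- cp / outer(nrm, nrm)
  diag(C) <- 1
  C
}

#' Threshold a coherence matrix into a weighted graph
#'
#' Keeps an (undirected) edge wherever pairwise coherence reaches the
#' threshold; the comparison is inclusive (`>=`), so a pair at exactly the
#' threshold is connected.
#'
#' @param coherence symmetric coherence matrix with gene dimnames.
#' @param threshold edge threshold in `(0, 1)` (default 0.4).
#' @return weighted undirected `igraph`; an empty graph triggers a
#'   warning.
#' @export
build_coherence_network <- function(coherence, threshold = 0.4) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  if (!isTRUE(all.equal(coherence, t(coherence), tolerance = 1e-12))) {
    stop("coherence matrix must be symmetric")
  }
  genes <- rownames(coherence)
  keep <- which(upper.tri(coherence) & coherence >= threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  igraph::V(g)$name <- genes
  if (nrow(keep) == 0L) {
    warning("no gene pair reaches the coherence threshold ", threshold,
            "; the network is edgeless")
    return(g)
  }
  g <- igraph::add_edges(g, rbind(keep[, 1L], keep[, 2L]))
  igraph::E(g)$weight <- coherence[keep]
  g
}

#' Sparsify a coherence network to each gene's top-2 neighbors
#'
#' Every node marks its (up to) two highest-weight incident edges, ties
#' broken by weight then alphabetical neighbor; the sparse network is the
#' union of all marked edges, so a node's final degree can exceed 2 through
#' its neighbors' selections.  Each kept edge carries a `selected_by`
#' attribute naming the endpoint(s) that marked it.
#'
#' @param g weighted undirected `igraph` from [build_coherence_network()].
#' @return undirected `igraph` with `weight` and `selected_by` edge
#'   attributes.
#' @export
sparsify_top2 <- function(g) {
  if (igraph::ecount(g) == 0L) return(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  sel <- vector("list", igraph::ecount(g))
  for (v in igraph::V(g)$name) {
    inc <- which(el[, 1L] == v | el[, 2L] == v)
    if (length(inc) == 0L) next
    nb <- ifelse(el[inc, 1L] == v, el[inc, 2L], el[inc, 1L])
    ord <- inc[order(-w[inc], nb)]
    for (e in ord[seq_len(min(2L, length(ord)))]) {
      sel[[e]] <- c(sel[[e]], v)
    }
  }
  kept <- which(lengths(sel) > 0L)
  sg <- igraph::subgraph_from_edges(g, kept, delete.vertices = FALSE)
  igraph::E(sg)$selected_by <- vapply(sel[kept], paste, character(1L), collapse = ",")
  sg
}

#' Extract the gene cascading path for one organoid type
#'
#' Each candidate key gene's distance to the mutant set is the minimum
#' unweighted shortest-path length from any mutant gene in the sparsified
#' coherence network.  The path endpoint is the reachable candidate with
#' the maximum such distance (ties broken by smaller key-gene q-value,
#' then alphabetically); the path itself is one shortest path realizing
#' that distance, found by breadth-first search with alphabetical neighbor
#' expansion from the alphabetically first mutant achieving the distance.
#' Candidates unreachable from every mutant are reported separately and
#' never chosen.
#'
#' @param net sparsified coherence network (`igraph`).
#' @param mutant_genes character vector of the organoid's mutated driver
#'   genes (at least one must be a network node).
#' @param candidates named numeric vector of candidate key genes' q-values
#'   (names are genes), or a data.frame with columns `gene` and `q`.
#' @return list with `path` (ordered gene vector), `endpoint`, `distance`,
#'   `candidate_table` (gene, distance, q, chosen), `unreachable`.
#' @export
extract_cascade_path <- function(net, mutant_genes, candidates) {
  if (is.data.frame(candidates)) {
    candidates <- stats::setNames(candidates$q, candidates$gene)
  }
  nodes <- igraph::V(net)$name
  mut <- intersect(mutant_genes, nodes)
  if (length(mut) == 0L) stop("no mutant gene is a node of the coherence network")
  cand <- intersect(names(candidates), nodes)
  cand <- setdiff(cand, mut)
  if (length(cand) == 0L) stop("no candidate key gene is a node of the coherence network")
  D <- igraph::distances(net, v = mut, to = cand, weights = NA)
  dist_cand <- apply(D, 2L, min)
  unreachable <- cand[!is.finite(dist_cand)]
  reach <- cand[is.finite(dist_cand)]
  if (length(reach) == 0L) {
    comps <- igraph::components(net)
    stop("no candidate is reachable from the mutant genes; components: ",
         paste(vapply(split(nodes, comps$membership), paste,
                      character(1L), collapse = "/"), collapse = " | "))
  }
  dr <- dist_cand[reach]
  qr <- candidates[reach]
  ordc <- order(-dr, qr, reach)
  endpoint <- reach[ordc[1L]]
  dist_end <- dr[ordc[1L]]

  # alphabetically-first shortest path: BFS with sorted neighbor expansion
  # from the alphabetically first mutant achieving the endpoint distance
  src_ok <- sort(mut[D[, endpoint] == dist_end])
  src <- src_ok[1L]
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)), function(v) sort(v$name))
  names(adj) <- nodes
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  queue <- src; seen[src] <- TRUE
  while (length(queue) > 0L && !seen[endpoint]) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        parent[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  path <- endpoint
  while (!is.na(parent[path[1L]])) path <- c(parent[path[1L]], path)

  tab <- data.frame(gene = reach,
                    distance = as.numeric(dr),
                    q = as.numeric(qr),
                    chosen = reach == endpoint,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$distance, tab$q, tab$gene), , drop = FALSE]
  list(path = unname(path), endpoint = endpoint,
       distance = as.numeric(dist_end),
       candidate_table = tab, unreachable = unreachable)
}
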