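# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths: the enrichment
# oracle is a plain scalar loop, the random-walk oracle a dense base-R
# linear solve.

# Brute-force running-sum enrichment score (scalar loop).
oracle_es <- function(metric, members, weight = 1) {
  ord <- order(-metric, names(metric))
  nm <- names(metric)[ord]
  vals <- unname(metric[ord])
  n <- length(vals)
  hits <- nm %in% members
  nh <- sum(hits)
  wsum <- sum(abs(vals[hits])^weight)
  run <- 0; pos <- -Inf; neg <- Inf
  for (i in seq_len(n)) {
    if (hits[i]) {
      run <- run + (if (wsum > 0) abs(vals[i])^weight / wsum else 1 / nh)
    } else {
      run <- run - 1 / (n - nh)
    }
    if (run > pos) pos <- run
    if (run < neg) neg <- run
  }
  # same declared tie-break as the package: near-exact magnitude ties
  # between the extremes resolve to the positive deviation
  if (pos >= -neg - 1e-12) pos else neg
}

# Direct steady-state solve P = r (I - (1 - r) W)^{-1} P0, dense base R.
oracle_rwr <- function(g, seeds, r) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- colSums(A)
  iso <- which(deg == 0)
  if (length(iso) > 0) A[cbind(iso, iso)] <- 1
  W <- sweep(A, 2, colSums(A), "/")
  n <- nrow(A)
  p0 <- setNames(rep(0, n), rownames(A))
  p0[seeds] <- 1 / length(seeds)
  drop(solve(diag(n) - (1 - r) * W, r * p0))
}

# Random connected G(n, p) graph with named vertices.
random_connected_graph <- function(n, p = 0.08) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  g
}

# Tiny 4-gene x 2-sample expression toy with distinct values.
toy_expression <- function() {
  matrix(c(9, 5, 3, 1, 2, 8, 6, 4), ncol = 2,
         dimnames = list(c("g1", "g2", "g3", "g4"), c("s1", "s2")))
}

# Worked cascade toy: mutant APC, chain APC-X-Y-C1 plus edge APC-C2.
toy_cascade_net <- function() {
  g <- igraph::make_graph(c("APC", "X", "X", "Y", "Y", "C1", "APC", "C2"),
                          directed = FALSE)
  igraph::E(g)$weight <- c(0.9, 0.8, 0.7, 0.6)
  g
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
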