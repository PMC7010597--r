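# Seed selection, random walk with restart, pseudo-seed significance, and
# Fisher combination.

test_that("seed selection takes top-decile pathway hubs with symbol tie-break", {
  # star: 1 hub + 10 leaves -> ceil(1.1) = 2 seeds: hub + first leaf
  star <- igraph::make_star(11, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf_", letters[1:10]))
  net <- star
  ss <- select_seeds(star, net)
  expect_identical(ss$seeds, c("hub", "leaf_a"))
  expect_equal(unname(ss$degrees["hub"]), 10)

  # 10-node path graph: one seed, first of the tied max-degree internals
  pg <- igraph::make_ring(10, circular = FALSE)
  igraph::V(pg)$name <- sprintf("n%02d", 1:10)
  ss2 <- select_seeds(pg, pg)
  expect_identical(ss2$seeds, "n02")   # degree-2 nodes n02..n09, tie by name

  expect_error(select_seeds(star, net, fraction = 0), "fraction")
  # seeds absent from the network are dropped afterwards
  net2 <- igraph::make_graph(~ leaf_a - leaf_b)
  expect_identical(select_seeds(star, net2)$seeds, "leaf_a")
  net3 <- igraph::make_graph(~ x - y)
  expect_error(select_seeds(star, net3), "no pathway gene")
})

test_that("random walk matches the worked path-graph example and its limits", {
  g <- igraph::make_graph(~ a - b, b - c)
  r <- rwr(g, "a", r = 0.7)
  expect_lt(max(abs(r$p - c(0.734615, 0.230769, 0.034615))), 1e-6)
  expect_equal(unname(r$p), unname(oracle_rwr(g, "a", 0.7)), tolerance = 1e-6)
  expect_equal(sum(r$p), 1, tolerance = 1e-10)

  # r = 1 returns the restart distribution exactly
  r1 <- rwr(g, c("a", "c"), r = 1)
  expect_equal(unname(r1$p), c(0.5, 0, 0.5))

  expect_error(rwr(g, "zz"), "not in the network")
  expect_error(rwr(g, "a", r = 0), "must be in")
  expect_error(rwr(g, "a", max_iter = 1), "did not converge")
})

test_that("iterative walk agrees with the direct linear solve on random graphs", {
  set.seed(101)
  for (i in 1:8) {
    g <- random_connected_graph(50)
    seeds <- sample(igraph::V(g)$name, sample(1:5, 1))
    it <- rwr(g, seeds, r = 0.7)$p
    expect_equal(unname(it), unname(oracle_rwr(g, seeds, 0.7)),
                 tolerance = 1e-6)
    expect_equal(unname(it), unname(rwr_solve(g, seeds, 0.7)),
                 tolerance = 1e-6)
    expect_equal(sum(it), 1, tolerance = 1e-10)
  }
})

test_that("steady state is initialization-independent and seed mass grows with r", {
  set.seed(102)
  g <- random_connected_graph(40)
  seeds <- c("v003", "v017")
  fp <- rwr(g, seeds, r = 0.5, tol = 1e-12)$p
  # closed form is the unique fixed point regardless of the starting vector
  expect_equal(unname(fp), unname(rwr_solve(g, seeds, 0.5)), tolerance = 1e-8)
  mass <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0), function(r) {
    sum(rwr(g, seeds, r = r)$p[seeds])
  }, numeric(1))
  expect_true(all(diff(mass) >= -1e-10))
  expect_equal(mass[length(mass)], 1)
})

test_that("pseudo-seed p-values flag seed-adjacent hubs and validate inputs", {
  star <- igraph::make_star(41, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", sprintf("l%02d", 1:40))
  p <- function_pvalues(star, "hub", n_random = 400, seed = 5)
  expect_lt(p["hub"], 0.05)
  expect_true(all(p > 0 & p <= 1))

  g5 <- igraph::make_ring(5)
  igraph::V(g5)$name <- paste0("n", 1:5)
  expect_error(function_pvalues(g5, paste0("n", 1:5), n_random = 10, seed = 1),
               "smaller than the network")
  expect_error(function_pvalues(g5, "n1", n_random = 0, seed = 1), "n_random")
})

test_that("pseudo-seed p-values are super-uniform when seeds carry no signal", {
  # regular graph: every node equivalent; "observed" seeds are themselves random
  set.seed(111)
  g <- igraph::sample_k_regular(60, 4)
  igraph::V(g)$name <- sprintf("v%02d", 1:60)
  p <- function_pvalues(g, sample(igraph::V(g)$name, 3),
                        n_random = 300, seed = 12)
  # exclude the seeds themselves (their own walk concentrates on them)
  expect_lte(mean(p <= 0.05), 0.12)
})

test_that("Fisher combination reproduces closed forms and flags key genes", {
  # K = 1: combined p equals the input p (chi-square_2 survival = e^{-x/2})
  p1 <- matrix(seq(0.001, 0.999, length.out = 200), ncol = 1,
               dimnames = list(sprintf("g%03d", 1:200), NULL))
  r1 <- combine_significance(p1, fdr = 0.05)
  expect_equal(r1$p_combined[match(rownames(p1), r1$gene)],
               unname(p1[, 1]), tolerance = 1e-12)
  expect_equal(unname(-2 * log(p1[, 1])),
               r1$chi2[match(rownames(p1), r1$gene)], tolerance = 1e-9)

  # K = 2, p = (0.05, 0.05): chi2 ~ 11.9829, survival e^{-x/2}(1 + x/2)
  r2 <- combine_significance(matrix(c(0.05, 0.05), nrow = 1,
                                    dimnames = list("g", NULL)))
  x <- -4 * log(0.05)
  expect_equal(r2$chi2, x, tolerance = 1e-9)
  expect_equal(r2$chi2, 11.9829, tolerance = 1e-4)
  expect_equal(r2$p_combined, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(r2$p_combined, 0.01748, tolerance = 1e-4)

  # all p = 1 -> chi2 = 0, combined p = 1
  r3 <- combine_significance(matrix(1, 2, 3,
                                    dimnames = list(c("a", "b"), NULL)))
  expect_equal(r3$chi2, c(0, 0))
  expect_equal(r3$p_combined, c(1, 1))

  # mutated drivers are reported but never called
  pm <- matrix(c(0.0001, 0.5, 0.0001, 0.5), 2, byrow = FALSE,
               dimnames = list(c("KRAS", "other"), NULL))
  rm <- combine_significance(pm, fdr = 0.05, mutated_genes = "KRAS")
  expect_false(rm$is_key[rm$gene == "KRAS"])
  expect_identical(rm$excluded_reason[rm$gene == "KRAS"], "driver_mutated")

  expect_error(combine_significance(matrix(0, 1, 1,
                                           dimnames = list("g", NULL))),
               "pseudocount")
})

test_that("key-gene inference composes its stages and recovers planted genes", {
  # tiny composition check: one pathway, manual pipeline equals infer_key_genes
  set.seed(121)
  net <- random_connected_graph(30, p = 0.15)
  pw <- igraph::induced_subgraph(net, sprintf("v%03d", 1:8))
  if (!igraph::is_connected(pw)) {
    pw <- igraph::induced_subgraph(
      net, igraph::V(net)$name[unlist(igraph::bfs(net, 1, order = TRUE)$order)[1:8]])
  }
  igraph::graph_attr(pw, "name") <- "pwX"
  auto <- infer_key_genes(net, list(pwX = pw), n_random = 50, seed = 99)
  ss <- select_seeds(pw, net)
  pv <- function_pvalues(net, ss, n_random = 50,
                         seed = cascadepath:::stage_seed(99, "pwX"))
  manual <- combine_significance(matrix(pv, ncol = 1,
                                        dimnames = list(names(pv), "pwX")),
                                 fdr = 0.05)
  expect_equal(auto$table$gene, manual$gene)
  expect_equal(auto$table$p_combined, manual$p_combined, tolerance = 1e-12)
  expect_error(infer_key_genes(net, list(), seed = 1), "at least one")

  # planted recovery: genes wired to seed hubs rank above background
  cfg <- synthetic_config(n_genes = 600, n_pathways = 12,
                          pathway_size = c(8, 15), n_key_genes = 6,
                          frac_dysregulated = 0.25, seed = 131)
  nw <- generate_network(cfg)
  pws <- generate_pathways(nw, cfg)
  ex <- generate_expression(nw, pws, cfg)
  kg <- infer_key_genes(nw, pws[ex$truth$dysregulated],
                        n_random = 300, seed = 132)
  rk <- match(ex$truth$key_genes, kg$table$gene)
  bg <- setdiff(seq_len(nrow(kg$table)), rk)
  expect_lt(median(rk), median(bg))
  expect_lt(wilcox.test(rk, bg, alternative = "less")$p.value, 0.01)
})
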