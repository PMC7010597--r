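# Synthetic generators: network, pathways, expression, mutations, bundle.

test_that("preferential-attachment networks have the closed-form edge count", {
  cfg <- synthetic_config(n_genes = 10, n_pathways = 1, pathway_size = c(3, 5),
                          m = 2, seed = 7)
  g <- generate_network(cfg)
  n <- 10; m <- 2
  expect_equal(igraph::ecount(g), m * (n - m - 1) + m * (m + 1) / 2)  # 17
  expect_true(igraph::is_connected(g))
  expect_false(igraph::any_loop(g))
  expect_equal(igraph::vcount(g), n)

  # determinism: same seed, identical edge list
  g2 <- generate_network(cfg)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))

  expect_error(synthetic_config(n_genes = 10, pathway_size = c(3, 5),
                                m = 9, seed = 1), "m")
  expect_error(synthetic_config(seed = ), "seed")
})

test_that("generated pathways are connected induced subgraphs of target size", {
  cfg <- synthetic_config(n_genes = 400, n_pathways = 10,
                          pathway_size = c(6, 12), seed = 17)
  nw <- generate_network(cfg)
  pws <- generate_pathways(nw, cfg)
  expect_length(pws, 10L)
  for (p in pws) {
    expect_true(igraph::is_connected(p))
    sz <- igraph::vcount(p)
    expect_gte(sz, 6); expect_lte(sz, 12)
    expect_true(all(igraph::V(p)$name %in% igraph::V(nw)$name))
  }
  # whole-network pathway when size equals n_genes
  cfg2 <- synthetic_config(n_genes = 30, n_pathways = 1,
                           pathway_size = c(30, 30), overlap_cap = 1,
                           seed = 18)
  nw2 <- generate_network(cfg2)
  expect_equal(igraph::vcount(generate_pathways(nw2, cfg2)[[1]]), 30L)
  # determinism
  expect_identical(lapply(generate_pathways(nw, cfg), igraph::as_edgelist),
                   lapply(pws, igraph::as_edgelist))
})

test_that("expression generator plants shifts and records ground truth", {
  cfg <- synthetic_config(n_genes = 500, n_pathways = 10,
                          pathway_size = c(6, 12), frac_dysregulated = 0.2,
                          n_key_genes = 5, seed = 27)
  nw <- generate_network(cfg)
  pws <- generate_pathways(nw, cfg)
  ex <- generate_expression(nw, pws, cfg)
  expect_identical(dim(ex$organoid), dim(ex$tumor))
  expect_length(ex$truth$dysregulated, 2L)
  expect_true(all(ex$truth$dysregulated %in% names(pws)))
  sh <- unique(unlist(lapply(pws[ex$truth$dysregulated],
                             function(p) igraph::V(p)$name)))
  expect_setequal(ex$truth$shifted_genes, sh)
  # shifted genes are up in the tumor group on the log scale, about delta*sigma
  lfc <- rowMeans(log(ex$tumor)) - rowMeans(log(ex$organoid))
  expect_gt(mean(lfc[sh]), cfg$delta * cfg$sigma - 1)
  expect_lt(abs(mean(lfc[setdiff(rownames(ex$organoid), sh)])), 0.5)
  # planted key genes neighbor the dysregulated seeds but are not seeds
  expect_true(all(ex$truth$key_genes %in%
                    setdiff(unique(unlist(lapply(
                      igraph::adjacent_vertices(nw, ex$truth$seeds),
                      function(v) v$name))), ex$truth$seeds)))
  # purity: same cfg, identical matrices
  ex2 <- generate_expression(nw, pws, cfg)
  expect_identical(ex$organoid, ex2$organoid)
  expect_identical(ex$tumor, ex2$tumor)
})

test_that("mutation generator covers declared drivers plus silent decoys", {
  cfg <- synthetic_config(n_genes = 50, n_pathways = 1, pathway_size = c(4, 6),
                          decoy_fraction = 0.2, seed = 37)
  gr <- sample_groups(list(
    A_tum = list(samples = sprintf("a%02d", 1:10), drivers = "g0001"),
    AK_tum = list(samples = sprintf("k%02d", 1:10),
                  drivers = c("g0001", "g0002"))))
  m <- generate_mutations(gr, cfg)
  mis <- m[m$mutation_type == "Missense", ]
  # every sample of every group mutates each declared driver
  expect_equal(sum(mis$sample_id %in% gr$A_tum$samples & mis$gene == "g0001"),
               10L)
  expect_equal(nrow(mis), 10L + 20L)
  # decoys are exactly the Silent records, removed by the default filter
  expect_equal(nrow(m) - nrow(mis), round(0.2 * nrow(mis)))
  expect_identical(filter_mutations(m)$mutation_type,
                   rep("Missense", nrow(mis)))
  # configured patterns round-trip through the combination summary
  cc <- summarize_mutation_combinations(filter_mutations(m),
                                        c("g0001", "g0002"))
  expect_equal(cc$sample_count[cc$combination_pattern == "g0001"], 10L)
  expect_equal(cc$sample_count[cc$combination_pattern == "g0001+g0002"], 10L)
})

test_that("a null generator stays null through the dysregulation test", {
  # delta = 0: organoid and tumor exchangeable; false-call rate at FDR 0.01
  # stays below 5% across seeds
  rates <- vapply(1:4, function(s) {
    cfg <- synthetic_config(n_genes = 500, n_pathways = 20,
                            pathway_size = c(6, 12), delta = 0,
                            n_key_genes = 0, seed = 200 + s)
    nw <- generate_network(cfg)
    # the cap is tight on a network this small; overlap warnings are expected
    pws <- suppressWarnings(generate_pathways(nw, cfg))
    ex <- generate_expression(nw, pws, cfg)
    sets <- lapply(pws, function(p) igraph::V(p)$name)
    r <- dysregulation_test(rank_transform(ex$organoid),
                            rank_transform(ex$tumor),
                            sets, n_perm = 300, fdr = 0.01, seed = 300 + s)
    mean(r$dysregulated)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("simulate_bundle writes a loadable, reader-consistent input set", {
  dir <- tempfile("bundle")
  cfg <- synthetic_config(n_genes = 150, n_pathways = 6,
                          pathway_size = c(5, 8), n_key_genes = 3,
                          frac_dysregulated = 0.34, seed = 47)
  b <- simulate_bundle(cfg, dir, organoid_types = c("A", "AK"),
                       n_signatures = 5)
  expect_true(all(file.exists(unlist(b$paths))))
  # readers reproduce what was generated
  org <- read_expression(b$paths$expression_organoid)
  expect_equal(org, b$organoid, tolerance = 1e-12)
  expect_identical(read_gmt(b$paths$signatures), b$signatures)
  nw <- read_network(b$paths$network)
  expect_equal(igraph::ecount(nw), igraph::ecount(b$network))
  pws <- read_pathways(b$paths$pathways_manifest)
  expect_identical(names(pws), names(b$pathways))
  expect_true(all(vapply(pws, igraph::is_connected, logical(1))))
  gr <- read_groups(b$paths$groups, expression = cbind(org,
                    read_expression(b$paths$expression_tumor)))
  expect_setequal(names(gr), c("A_org", "A_tum", "AK_org", "AK_tum"))
})
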