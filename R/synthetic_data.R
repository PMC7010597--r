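# Synthetic-data generator: scale-free interaction networks, connected
# pathway subgraphs, expression matrices with planted dysregulation, and
# driver-mutation labels with recorded ground truth.  Stands in for the
# public resources the method was designed around (organoid microarrays,
# tumor RNA-seq, curated pathway graphs, a protein interaction network)
# so every pipeline stage is testable offline.

#' Synthetic study configuration
#'
#' Defaults encode the simulated study conditions used throughout the
#' package's tests: a 3,000-gene scale-free network, 50 connected pathways
#' of 10-25 genes, 10 samples per group, log-normal expression with unit
#' log-scale noise, a 3-standard-deviation shift planted on 10% of
#' pathways in the tumor group, and 10 planted key genes adjacent to
#' dysregulated-pathway hubs.
#'
#' @param n_genes number of network genes.
#' @param n_samples samples per group (organoid and tumor each).
#' @param n_pathways number of pathway subgraphs.
#' @param pathway_size length-2 integer range of pathway sizes.
#' @param m preferential-attachment edges per new node (`1 <= m < n_genes`).
#' @param delta planted shift magnitude, in units of the within-gene
#'   log-scale standard deviation `sigma`.
#' @param sigma within-gene log-scale noise standard deviation.
#' @param frac_dysregulated fraction of pathways planted as dysregulated.
#' @param n_key_genes number of planted key genes.
#' @param decoy_fraction fraction of silent decoy mutation records added.
#' @param overlap_cap maximum fraction of a new pathway's genes allowed to
#'   overlap any existing pathway (roots are resampled up to
#'   `max_retries` times to respect it).
#' @param max_retries bounded retries for pathway sampling.
#' @param seed mandatory integer master seed.
#' @return classed list `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 3000L, n_samples = 10L,
                             n_pathways = 50L, pathway_size = c(10L, 25L),
                             m = 2L, delta = 3, sigma = 1,
                             frac_dysregulated = 0.10, n_key_genes = 10L,
                             decoy_fraction = 0.2, overlap_cap = 0.10,
                             max_retries = 100L, seed) {
  if (missing(seed)) stop("'seed' is mandatory in a synthetic configuration")
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size), m = as.integer(m),
              delta = delta, sigma = sigma,
              frac_dysregulated = frac_dysregulated,
              n_key_genes = as.integer(n_key_genes),
              decoy_fraction = decoy_fraction, overlap_cap = overlap_cap,
              max_retries = as.integer(max_retries), seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 3L, cfg$n_samples >= 1L, cfg$n_pathways >= 1L,
            length(cfg$pathway_size) == 2L,
            cfg$pathway_size[1L] >= 2L,
            cfg$pathway_size[2L] <= cfg$n_genes,
            cfg$delta >= 0, cfg$sigma > 0,
            cfg$frac_dysregulated >= 0, cfg$frac_dysregulated <= 1,
            cfg$n_key_genes >= 0L)
  if (cfg$m < 1L || cfg$m >= cfg$n_genes - 1L) {
    stop("'m' must satisfy 1 <= m < n_genes - 1")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a scale-free interaction network
#'
#' Preferential-attachment growth: start from a complete graph on `m + 1`
#' nodes; each subsequent node attaches `m` edges to distinct existing
#' nodes chosen with probability proportional to their current degree.
#' The graph is connected by construction and has exactly
#' `m * (n - m - 1) + m * (m + 1) / 2` edges.  Deterministic given
#' `cfg$seed`.
#'
#' @param cfg [synthetic_config()].
#' @return undirected `igraph` with gene names `g0001`, `g0002`, ...
#' @export
generate_network <- function(cfg) {
  n <- cfg$n_genes; m <- cfg$m
  genes <- sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
  with_seed(stage_seed(cfg$seed, "network"), {
    deg <- integer(n)
    from <- integer(0L); to <- integer(0L)
    core <- utils::combn(m + 1L, 2L)
    from <- core[1L, ]; to <- core[2L, ]
    deg[seq_len(m + 1L)] <- m
    for (v in seq.int(m + 2L, n)) {
      existing <- seq_len(v - 1L)
      tgt <- sample(existing, m, replace = FALSE, prob = deg[existing])
      from <- c(from, rep.int(v, m)); to <- c(to, tgt)
      deg[tgt] <- deg[tgt] + 1L
      deg[v] <- m
    }
    g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
    igraph::V(g)$name <- genes
    g
  })
}

# BFS-prefix pathway: the first `size` nodes in breadth-first order from a
# root induce a connected subgraph (every non-root has its BFS parent
# earlier in the order).
bfs_ball <- function(network, root, size) {
  ord <- igraph::bfs(network, root = root, order = TRUE)$order
  ord <- ord[!is.na(ord)]
  if (length(ord) < size) return(NULL)
  igraph::V(network)$name[ord[seq_len(size)]]
}

#' Generate connected pathway subgraphs
#'
#' Each pathway is the induced subgraph of a breadth-first ball around a
#' random root, truncated to a target size drawn uniformly from
#' `cfg$pathway_size`; connectivity holds by construction and degrees are
#' those of the induced subgraph.  Roots are resampled (bounded retries)
#' when the target size is unreachable or the ball would overlap an
#' existing pathway by more than `cfg$overlap_cap` of its genes; if the
#' overlap cap cannot be met the least-overlapping ball found is kept with
#' a warning.
#'
#' @param network `igraph` from [generate_network()].
#' @param cfg [synthetic_config()].
#' @return named list of connected pathway `igraph`s (`pw01`, `pw02`, ...).
#' @export
generate_pathways <- function(network, cfg) {
  nodes <- igraph::V(network)$name
  with_seed(stage_seed(cfg$seed, "pathways"), {
    sizes <- resample(seq.int(cfg$pathway_size[1L], cfg$pathway_size[2L]),
                      cfg$n_pathways, replace = TRUE)
    members <- vector("list", cfg$n_pathways)
    for (j in seq_len(cfg$n_pathways)) {
      best <- NULL; best_ov <- Inf
      for (try in seq_len(cfg$max_retries)) {
        root <- sample(nodes, 1L)
        ball <- bfs_ball(network, root, sizes[j])
        if (is.null(ball)) next
        ov <- 0
        if (j > 1L) {
          ov <- max(vapply(members[seq_len(j - 1L)], function(mm) {
            length(intersect(mm, ball)) / sizes[j]
          }, numeric(1L)))
        }
        if (ov < best_ov) { best <- ball; best_ov <- ov }
        if (ov <= cfg$overlap_cap) break
      }
      if (is.null(best)) {
        stop("could not sample a connected pathway of size ", sizes[j],
             " within ", cfg$max_retries, " retries")
      }
      if (best_ov > cfg$overlap_cap) {
        warning("pathway ", j, " overlaps an existing pathway by ",
                round(100 * best_ov), "% (cap ",
                round(100 * cfg$overlap_cap), "%)")
      }
      members[[j]] <- best
    }
    out <- lapply(seq_len(cfg$n_pathways), function(j) {
      sg <- igraph::induced_subgraph(network, members[[j]])
      igraph::graph_attr(sg, "name") <- sprintf("pw%02d", j)
      sg
    })
    names(out) <- vapply(out, igraph::graph_attr, character(1L), "name")
    out
  })
}

#' Generate organoid and tumor expression with planted dysregulation
#'
#' Per-gene log-scale baseline `mu_g ~ Normal(0, 1)` shared by both
#' groups; each sample adds `Normal(0, sigma)` noise and expression is
#' exponentiated (log-normal).  A fraction of pathways is designated
#' dysregulated: the tumor group's log-expression of every gene in those
#' pathways is shifted by `+delta * sigma`, while the organoid group is
#' left unshifted.  Planted key genes are drawn from the network neighbors
#' of the dysregulated pathways' seed hubs (excluding the seeds
#' themselves), so recovering them exercises the propagation stage.
#'
#' @param network interaction network `igraph`.
#' @param pathways list from [generate_pathways()].
#' @param cfg [synthetic_config()].
#' @return list with `organoid` and `tumor` expression matrices and
#'   `truth` (`dysregulated`, `key_genes`, `seeds`, `shifted_genes`).
#' @export
generate_expression <- function(network, pathways, cfg) {
  genes <- igraph::V(network)$name
  n <- length(genes)
  with_seed(stage_seed(cfg$seed, "expression"), {
    n_dys <- round(cfg$frac_dysregulated * length(pathways))
    dys <- if (n_dys > 0L) sort(sample(names(pathways), n_dys)) else character(0L)
    shifted <- unique(unlist(lapply(pathways[dys], function(p) igraph::V(p)$name)))
    seeds <- unique(unlist(lapply(pathways[dys], function(p) {
      select_seeds(p, network)$seeds
    })))
    key_pool <- character(0L)
    if (length(seeds) > 0L) {
      nb <- unique(unlist(lapply(
        igraph::adjacent_vertices(network, seeds), function(v) v$name)))
      key_pool <- sort(setdiff(nb, seeds))
    }
    keys <- if (length(key_pool) > 0L && cfg$n_key_genes > 0L) {
      sort(sample(key_pool, min(cfg$n_key_genes, length(key_pool))))
    } else character(0L)

    mu <- stats::rnorm(n)
    shift <- ifelse(genes %in% shifted, cfg$delta * cfg$sigma, 0)
    draw <- function(prefix, add_shift) {
      eps <- matrix(stats::rnorm(n * cfg$n_samples, sd = cfg$sigma),
                    nrow = n)
      logx <- mu + (if (add_shift) shift else 0) + eps
      x <- exp(logx)
      dimnames(x) <- list(genes,
                          sprintf("%s_s%02d", prefix, seq_len(cfg$n_samples)))
      x
    }
    organoid <- draw("org", FALSE)
    tumor <- draw("tum", TRUE)
    list(organoid = organoid, tumor = tumor,
         truth = list(dysregulated = dys, key_genes = keys,
                      seeds = sort(seeds), shifted_genes = sort(shifted)))
  })
}

#' Generate driver-mutation records for sample groups
#'
#' Every sample of a group receives a `Missense` record for each of the
#' group's declared driver genes; silent decoy records (a
#' `decoy_fraction` of the driver record count, on random sample/gene
#' pairs) are added so type filtering is exercised downstream.
#'
#' @param groups `sample_groups` object.
#' @param cfg [synthetic_config()].
#' @return mutation data.frame (`sample_id`, `gene`, `mutation_type`).
#' @export
generate_mutations <- function(groups, cfg) {
  recs <- do.call(rbind, lapply(names(groups), function(lab) {
    g <- groups[[lab]]
    if (length(g$drivers) == 0L) return(NULL)
    expand.grid(sample_id = g$samples, gene = g$drivers,
                stringsAsFactors = FALSE)
  }))
  if (is.null(recs)) {
    recs <- data.frame(sample_id = character(0L), gene = character(0L))
  }
  recs$mutation_type <- rep("Missense", nrow(recs))
  with_seed(stage_seed(cfg$seed, "mutations"), {
    n_decoy <- round(cfg$decoy_fraction * nrow(recs))
    if (n_decoy > 0L) {
      idx <- sample.int(nrow(recs), n_decoy, replace = TRUE)
      decoys <- recs[idx, , drop = FALSE]
      decoys$mutation_type <- "Silent"
      recs <- rbind(recs, decoys)
    }
    rownames(recs) <- NULL
    recs
  })
}

#' Draw random gene sets
#'
#' Utility for null calibrations: `n_sets` gene sets with sizes uniform in
#' `size_range`, members drawn without replacement from `genes`.
#'
#' @param genes gene universe.
#' @param n_sets number of sets.
#' @param size_range length-2 integer range.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
random_gene_sets <- function(genes, n_sets, size_range = c(10L, 25L), seed) {
  with_seed(seed, {
    sizes <- resample(seq.int(size_range[1L], size_range[2L]), n_sets,
                      replace = TRUE)
    sets <- lapply(sizes, function(k) sample(genes, k))
    names(sets) <- sprintf("set%03d", seq_len(n_sets))
    sets
  })
}

#' Write a complete synthetic input bundle to a directory
#'
#' Generates the network, pathways, expression (one organoid/tumor pair
#' per organoid type), signature sets, groups, mutations and ground truth,
#' and writes them in the plain-text formats the readers accept, together
#' with a ready-to-run pipeline `config.yaml`.
#'
#' @param cfg [synthetic_config()].
#' @param dir output directory (created if needed).
#' @param organoid_types ordered character vector of organoid type labels;
#'   type `i` carries the first `i` driver genes (the highest-degree
#'   network genes stand in for known drivers).
#' @param n_signatures number of hallmark-like signature sets generated.
#' @return invisibly, a list with the generated objects and `paths` to all
#'   written files.
#' @export
simulate_bundle <- function(cfg, dir, organoid_types = c("A", "AK"),
                            n_signatures = 20L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pathways"), showWarnings = FALSE)
  network <- generate_network(cfg)
  pathways <- generate_pathways(network, cfg)
  genes <- igraph::V(network)$name

  drivers_pool <- names(sort(igraph::degree(network), decreasing = TRUE))[
    seq_len(max(length(organoid_types), 5L))]

  exprs <- list(); groups_def <- list(); type_truth <- list()
  for (i in seq_along(organoid_types)) {
    lab <- organoid_types[i]
    tcfg <- cfg; tcfg$seed <- stage_seed(cfg$seed, paste0("type_", lab))
    ex <- generate_expression(network, pathways, tcfg)
    colnames(ex$organoid) <- paste0(lab, "_", colnames(ex$organoid))
    colnames(ex$tumor) <- paste0(lab, "_", colnames(ex$tumor))
    exprs[[lab]] <- ex
    drv <- drivers_pool[seq_len(i)]
    groups_def[[paste0(lab, "_org")]] <- list(samples = colnames(ex$organoid),
                                              drivers = drv)
    groups_def[[paste0(lab, "_tum")]] <- list(samples = colnames(ex$tumor),
                                              drivers = drv)
    type_truth[[lab]] <- ex$truth
  }
  organoid <- do.call(cbind, lapply(exprs, `[[`, "organoid"))
  tumor <- do.call(cbind, lapply(exprs, `[[`, "tumor"))
  groups <- sample_groups(groups_def)
  mutations <- generate_mutations(
    groups[grepl("_tum$", names(groups))], cfg)
  signatures <- random_gene_sets(genes, n_signatures,
                                 size_range = cfg$pathway_size,
                                 seed = stage_seed(cfg$seed, "signatures"))
  functions <- lapply(pathways, function(p) igraph::V(p)$name)

  paths <- list(
    network = file.path(dir, "network.tsv"),
    pathways_manifest = file.path(dir, "pathways.tsv"),
    functions = file.path(dir, "functions.gmt"),
    signatures = file.path(dir, "signatures.gmt"),
    expression_organoid = file.path(dir, "expression_organoid.tsv"),
    expression_tumor = file.path(dir, "expression_tumor.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    groups = file.path(dir, "groups.tsv"),
    group_config = file.path(dir, "group_config.yaml"),
    ground_truth = file.path(dir, "ground_truth.tsv"),
    config = file.path(dir, "config.yaml"))

  write_edgelist(network, paths$network)
  pw_files <- sprintf("pathways/%s.tsv", names(pathways))
  for (j in seq_along(pathways)) {
    write_edgelist(pathways[[j]], file.path(dir, pw_files[j]))
  }
  write_tsv_file(data.frame(name = names(pathways), path = pw_files,
                            stringsAsFactors = FALSE),
                 paths$pathways_manifest)
  write_gmt(functions, paths$functions)
  write_gmt(signatures, paths$signatures)
  write_expression(organoid, paths$expression_organoid)
  write_expression(tumor, paths$expression_tumor)
  write_mutations(mutations, paths$mutations)
  gdf <- do.call(rbind, lapply(names(groups), function(lab) {
    data.frame(sample_id = groups[[lab]]$samples, group_label = lab,
               stringsAsFactors = FALSE)
  }))
  write_tsv_file(gdf, paths$groups)
  yaml::write_yaml(list(organoid_types = lapply(seq_along(organoid_types), function(i) {
    lab <- organoid_types[i]
    list(label = lab,
         organoid_group = paste0(lab, "_org"),
         tumor_group = paste0(lab, "_tum"),
         drivers = as.list(drivers_pool[seq_len(i)]))
  })), paths$group_config)
  tt <- do.call(rbind, lapply(names(type_truth), function(lab) {
    tr <- type_truth[[lab]]
    rbind(
      data.frame(type = lab, kind = "dysregulated_pathway",
                 name = tr$dysregulated, stringsAsFactors = FALSE),
      data.frame(type = lab, kind = "key_gene", name = tr$key_genes,
                 stringsAsFactors = FALSE))
  }))
  write_tsv_file(tt, paths$ground_truth)
  yaml::write_yaml(list(
    inputs = list(
      expression_organoid = "expression_organoid.tsv",
      expression_tumor = "expression_tumor.tsv",
      network = "network.tsv",
      pathways_manifest = "pathways.tsv",
      functions = "functions.gmt",
      signatures = "signatures.gmt",
      mutations = "mutations.tsv",
      groups = "groups.tsv",
      group_config = "group_config.yaml"),
    params = list(n_perm = 1000L, n_random = 1000L, fdr_dysreg = 0.01,
                  fdr_key = 0.05, fdr_signature = 0.05, r = 0.7,
                  tol = 1e-8, coherence_threshold = 0.4,
                  seed = cfg$seed)), paths$config)

  invisible(list(network = network, pathways = pathways,
                 organoid = organoid, tumor = tumor, groups = groups,
                 mutations = mutations, signatures = signatures,
                 functions = functions, truth = type_truth, paths = paths))
}
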