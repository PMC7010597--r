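# End-to-end orchestration: one config drives rank transform, functional
# activity, dysregulation per organoid type, stepwise signature
# comparisons, key-gene inference, the coherence network and cascade
# paths, with deterministic per-stage seeds and a run manifest.

default_params <- function() {
  list(n_perm = 1000L, n_random = 1000L, fdr_dysreg = 0.01, fdr_key = 0.05,
       fdr_signature = 0.05, r = 0.7, tol = 1e-8,
       coherence_threshold = 0.4, seed_fraction = 0.10, seed = 1L)
}

#' Load a pipeline configuration
#'
#' Reads a YAML configuration (or accepts an equivalent list) with an
#' `inputs` block of file paths (resolved relative to the config file's
#' directory), an optional `params` block overriding the defaults
#' (`n_perm = 1000`, `n_random = 1000`, `fdr_dysreg = 0.01`,
#' `fdr_key = 0.05`, `fdr_signature = 0.05`, `r = 0.7`, `tol = 1e-8`,
#' `coherence_threshold = 0.4`), and an optional `out_dir`.
#'
#' @param config path to a YAML file, or a list.
#' @return normalized config list.
#' @export
load_pipeline_config <- function(config) {
  base <- "."
  if (is.character(config) && length(config) == 1L) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$inputs)) {
    stop("pipeline config needs an 'inputs' block")
  }
  config$inputs <- lapply(config$inputs, function(p) {
    if (file.exists(p)) p else file.path(base, p)
  })
  params <- default_params()
  for (k in names(config$params %||% list())) params[[k]] <- config$params[[k]]
  config$params <- params
  config
}

read_group_config <- function(path) {
  gc <- yaml::read_yaml(path)
  types <- gc$organoid_types
  if (is.null(types) || length(types) == 0L) {
    stop("group config needs a non-empty 'organoid_types' list")
  }
  lapply(types, function(t) {
    list(label = t$label, organoid_group = t$organoid_group,
         tumor_group = t$tumor_group,
         drivers = as.character(unlist(t$drivers %||% character(0L))))
  })
}

#' Run the full integrative pipeline
#'
#' Executes, in order: rank transform of the gene-intersected organoid and
#' tumor expression; group functional-activity means; dysregulation tests
#' per organoid type against its matched tumor group; stepwise pairwise
#' signature comparisons between organoid types; key-gene inference per
#' type from its dysregulated pathways; the functional-coherence network
#' and cascade-path extraction; mutation combination summaries.  All stage
#' outputs are TSV files carrying a header comment with the config digest
#' and master seed; a `manifest.json` records the config snapshot, input
#' digests, package version and per-stage timing and record counts.
#' Stage seeds derive deterministically from the master seed and the stage
#' name, so reruns with the same config and inputs reproduce every stage
#' output byte for byte.
#'
#' @param config YAML path or list; see [load_pipeline_config()].
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, a list of the in-memory stage results plus
#'   `out_dir`.
#' @export
run_all <- function(config, out_dir = NULL) {
  cfg <- load_pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("an output directory is required ('out_dir')")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params
  seed <- p$seed

  # pre-flight: every input must exist before any computation starts
  missing <- names(cfg$inputs)[!vapply(cfg$inputs, file.exists, logical(1L))]
  if (length(missing) > 0L) {
    stop("missing input file(s): ",
         paste(sprintf("%s (%s)", missing,
                       unlist(cfg$inputs[missing])), collapse = ", "))
  }

  cfg_digest <- config_digest(cfg)
  hdr <- sprintf("config=%s seed=%d", cfg_digest, as.integer(seed))
  manifest <- list(config = cfg[c("inputs", "params")],
                   input_md5 = as.list(tools::md5sum(unlist(cfg$inputs))),
                   package_version = as.character(utils::packageVersion("cascadepath")),
                   stages = list(), status = "running")
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest, manifest_path)
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    message("[", name, "] running")
    val <- expr
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3L),
      records = if (is.data.frame(val)) nrow(val) else NA)
    val
  }

  inputs <- t_stage("read_inputs", {
    list(org = read_expression(cfg$inputs$expression_organoid),
         tum = read_expression(cfg$inputs$expression_tumor),
         network = read_network(cfg$inputs$network),
         pathways = read_pathways(cfg$inputs$pathways_manifest),
         functions = read_gmt(cfg$inputs$functions),
         signatures = read_gmt(cfg$inputs$signatures),
         mutations = read_mutations(cfg$inputs$mutations),
         types = read_group_config(cfg$inputs$group_config))
  })
  groups <- read_groups(cfg$inputs$groups)

  rs <- t_stage("rank_transform", {
    both <- intersect_genes(inputs$org, inputs$tum)
    list(org = rank_transform(both$a), tum = rank_transform(both$b))
  })

  results <- list(out_dir = out_dir)

  results$mutation_combinations <- t_stage("mutations", {
    filtered <- filter_mutations(inputs$mutations)
    all_drivers <- unique(unlist(lapply(inputs$types, `[[`, "drivers")))
    combos <- summarize_mutation_combinations(filtered, all_drivers)
    write_tsv_file(combos, file.path(out_dir, "mutation_combinations.tsv"), hdr)
    combos
  })

  results$fas_means <- t_stage("fas", {
    fas_org <- fas_table(rs$org, inputs$functions)
    fas_tum <- fas_table(rs$tum, inputs$functions)
    gm <- vapply(inputs$types, function(ty) {
      c(rowMeans(fas_org[, groups[[ty$organoid_group]]$samples, drop = FALSE]),
        rowMeans(fas_tum[, groups[[ty$tumor_group]]$samples, drop = FALSE]))
    }, numeric(2L * nrow(fas_org)))
    labs <- vapply(inputs$types, `[[`, character(1L), "label")
    gm <- matrix(gm, ncol = length(labs))
    df <- data.frame(function_name = rep(rownames(fas_org), 2L),
                     side = rep(c("organoid", "tumor"),
                                each = nrow(fas_org)),
                     gm, stringsAsFactors = FALSE, check.names = FALSE)
    names(df)[-(1:2)] <- labs
    write_tsv_file(df, file.path(out_dir, "fas_means.tsv"), hdr)
    df
  })

  results$dysregulation <- t_stage("dysregulation", {
    recs <- list()
    for (ty in inputs$types) {
      lab <- ty$label
      r <- dysregulation_test(
        rs$org[, groups[[ty$organoid_group]]$samples, drop = FALSE],
        rs$tum[, groups[[ty$tumor_group]]$samples, drop = FALSE],
        inputs$functions, n_perm = p$n_perm, fdr = p$fdr_dysreg,
        seed = stage_seed(seed, paste0("dysreg_", lab)))
      write_tsv_file(r, file.path(out_dir,
                                  sprintf("dysregulation_%s.tsv", lab)), hdr)
      recs[[lab]] <- r
    }
    bm <- dysregulation_matrix(recs)
    write_tsv_file(data.frame(function_name = rownames(bm), bm,
                              check.names = FALSE, stringsAsFactors = FALSE),
                   file.path(out_dir, "dysregulation_matrix.tsv"), hdr)
    recs
  })

  results$signatures <- t_stage("signatures", {
    labs <- vapply(inputs$types, `[[`, character(1L), "label")
    out <- list()
    if (length(labs) >= 2L) {
      for (i in seq_len(length(labs) - 1L)) {
        for (j in seq.int(i + 1L, length(labs))) {
          a <- inputs$types[[i]]; b <- inputs$types[[j]]
          r <- pairwise_signature_test(
            rs$org[, groups[[a$organoid_group]]$samples, drop = FALSE],
            rs$org[, groups[[b$organoid_group]]$samples, drop = FALSE],
            inputs$signatures, n_perm = p$n_perm, fdr = p$fdr_signature,
            seed = stage_seed(seed, paste0("sig_", a$label, "_", b$label)))
          write_tsv_file(r, file.path(out_dir,
                                      sprintf("signatures_%s_vs_%s.tsv",
                                              a$label, b$label)), hdr)
          out[[paste0(a$label, "_vs_", b$label)]] <- r
        }
      }
    }
    out
  })

  results$key_genes <- t_stage("key_genes", {
    out <- list()
    for (ty in inputs$types) {
      lab <- ty$label
      dys <- results$dysregulation[[lab]]
      dys_names <- dys$function_name[dys$dysregulated]
      dys_pw <- inputs$pathways[intersect(dys_names, names(inputs$pathways))]
      if (length(dys_pw) == 0L) {
        message("[key_genes] no dysregulated pathway with a graph for type ",
                lab, "; skipping")
        tab <- data.frame(gene = character(0L), K = integer(0L),
                          chi2 = numeric(0L), df = integer(0L),
                          p_combined = numeric(0L), q = numeric(0L),
                          is_key = logical(0L),
                          excluded_reason = character(0L))
      } else {
        tab <- infer_key_genes(
          inputs$network, dys_pw, n_random = p$n_random, fdr = p$fdr_key,
          fraction = p$seed_fraction, mutated_genes = ty$drivers,
          seed = stage_seed(seed, paste0("key_", lab)),
          r = p$r, tol = p$tol)$table
      }
      write_tsv_file(tab, file.path(out_dir,
                                    sprintf("key_genes_%s.tsv", lab)), hdr)
      out[[lab]] <- tab
    }
    out
  })

  results$cascades <- t_stage("cascade_paths", {
    ann <- annotation_from_sets(inputs$functions, inputs$signatures)
    out <- list()
    for (ty in inputs$types) {
      lab <- ty$label
      tab <- results$key_genes[[lab]]
      cand <- tab[tab$is_key, c("gene", "q"), drop = FALSE]
      if (nrow(cand) == 0L && nrow(tab) > 0L) {
        message("[cascade_paths] no key-gene call for type ", lab,
                "; using the 5 best-ranked candidates")
        cand <- utils::head(tab[tab$excluded_reason == "", c("gene", "q")], 5L)
      }
      res <- NULL
      if (nrow(cand) > 0L) {
        genes <- unique(c(ty$drivers, cand$gene))
        annotated <- genes[vapply(genes,
                                  function(g) length(ann[[g]]) > 0L,
                                  logical(1L))]
        if (length(annotated) < length(genes)) {
          message("[cascade_paths] dropping unannotated gene(s) for type ",
                  lab, ": ", paste(setdiff(genes, annotated), collapse = ", "))
        }
        res <- tryCatch({
          C <- coherence_matrix(annotated, ann)
          net <- sparsify_top2(
            build_coherence_network(C, threshold = p$coherence_threshold))
          extract_cascade_path(net, intersect(ty$drivers, annotated),
                               cand[cand$gene %in% annotated, ])
        }, error = function(e) {
          message("[cascade_paths] no path for type ", lab, ": ",
                  conditionMessage(e))
          NULL
        })
      }
      if (is.null(res)) {
        write_tsv_file(data.frame(gene = character(0L), distance = numeric(0L),
                                  q = numeric(0L), chosen = logical(0L)),
                       file.path(out_dir,
                                 sprintf("cascade_%s.tsv", lab)), hdr)
        writeLines(paste0("# ", hdr), file.path(out_dir,
                                                sprintf("cascade_path_%s.txt", lab)))
      } else {
        write_tsv_file(res$candidate_table,
                       file.path(out_dir, sprintf("cascade_%s.tsv", lab)), hdr)
        writeLines(c(paste0("# ", hdr), paste(res$path, collapse = "\t")),
                   file.path(out_dir, sprintf("cascade_path_%s.txt", lab)))
      }
      out[[lab]] <- res
    }
    out
  })

  manifest$status <- "complete"
  write_manifest(manifest, manifest_path)
  message("pipeline complete: ", out_dir)
  invisible(results)
}

config_digest <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  yaml::write_yaml(cfg[c("inputs", "params")], tf)
  unname(tools::md5sum(tf))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
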