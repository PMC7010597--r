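# Domain types and readers/writers: expression matrices, gene sets (GMT),
# pathway graphs, interaction networks, mutation profiles, sample groups.
#
# Representations are the field's standard containers: a numeric matrix with
# gene rownames and sample colnames for expression; a named list of character
# vectors for gene-set collections; undirected igraph objects for pathway
# graphs and the interaction network; a data.frame for mutation records.

#' Validate a genes-by-samples expression matrix
#'
#' Checks the invariants every downstream stage relies on: unique gene and
#' sample identifiers, all values finite, at least two genes.
#'
#' @param x numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers).
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (nrow(x) < 2L) stop("expression matrix needs at least 2 genes")
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers in expression matrix")
  if (!all(is.finite(x))) stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and gene symbols in the first
#' column.  Rows sharing a gene symbol (multiple probes of one gene) are
#' collapsed by their arithmetic mean.  Malformed input produces an error
#' naming the offending line.
#'
#' @param path path to a tab-separated file.
#' @return validated numeric matrix (genes x samples).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("format error in ", path, ": need a header and at least one gene row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stop("format error in ", path, " line 1: malformed header (need gene column plus samples)")
  samples <- header[-1L]
  ncolumns <- length(header)
  genes <- character(length(lines) - 1L)
  vals <- matrix(NA_real_, nrow = length(lines) - 1L, ncol = ncolumns - 1L)
  for (i in seq_along(genes)) {
    fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != ncolumns) {
      stop("format error in ", path, " line ", i + 1L, ": expected ",
           ncolumns, " fields, found ", length(fields))
    }
    genes[i] <- fields[1L]
    v <- suppressWarnings(as.numeric(fields[-1L]))
    if (any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1L]
      stop("format error in ", path, " line ", i + 1L, ": non-numeric cell '",
           fields[-1L][bad], "' in column ", bad + 1L)
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(genes)) {
    # probe-level collapse: arithmetic mean of raw values per gene
    vals <- rowsum(vals, group = genes, reorder = FALSE)
    counts <- as.vector(table(factor(genes, levels = rownames(vals))))
    vals <- vals / counts
    genes <- rownames(vals)
  }
  rownames(vals) <- genes
  colnames(vals) <- samples
  validate_expression(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' @param x numeric matrix as from [read_expression()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' Restrict two expression matrices to their common genes
#'
#' Both outputs carry the sorted intersection of the two gene universes in
#' identical order, mirroring the cross-platform integration step in which
#' only genes measured by both platforms are kept.
#'
#' @param a,b expression matrices.
#' @return list with elements `a` and `b`, row-aligned.
#' @export
intersect_genes <- function(a, b) {
  validate_expression(a); validate_expression(b)
  common <- sort(intersect(rownames(a), rownames(b)))
  if (length(common) == 0L) stop("no common genes between the two expression matrices")
  if (length(common) < 2L) stop("fewer than 2 common genes between the two expression matrices")
  list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE])
}

#' Read a gene-set collection from GMT
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members.  Duplicate members within a set are dropped.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("format error in ", path, ": empty GMT file")
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("format error in ", path, " line ", i,
           ": GMT line needs name, description and at least one member")
    }
    nms[i] <- fields[1L]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nms)) stop("duplicate gene-set names in ", path)
  names(sets) <- nms
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# Parse a 2/3-column edge list (or SIF) into an undirected simple graph.
read_edges <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("format error in ", path, ": no edges")
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop("format error in ", path, " line ", which(nf < 2L)[1L],
         ": an edge needs two endpoints")
  }
  from <- vapply(parts, `[[`, character(1L), 1L)
  second <- vapply(parts, `[[`, character(1L), 2L)
  third <- ifelse(nf >= 3L, vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_, character(1L)), NA_character_)
  third_num <- suppressWarnings(as.numeric(third))
  # SIF convention: source, interaction type, target (3rd column non-numeric)
  sif <- all(nf >= 3L) && all(is.na(third_num) & !is.na(third))
  to <- if (sif) third else second
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

edges_to_graph <- function(df, what = "network") {
  self <- df$from == df$to
  if (any(self)) {
    warning("dropping ", sum(self), " self-loop(s) from ", what)
    df <- df[!self, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g
}

#' Read a protein interaction network
#'
#' Accepts a 2-column edge list (optional third weight column) or SIF
#' (`source  interaction  target`).  The result is undirected and simple:
#' self-loops and duplicate edges are removed.
#'
#' @param path path to the edge-list/SIF file.
#' @return undirected `igraph` object.
#' @export
read_network <- function(path) {
  edges_to_graph(read_edges(path), what = paste0("network ", path))
}

#' Read a pathway graph
#'
#' Same format as [read_network()], but the graph must be connected —
#' pathways whose genes are not connected with each other are rejected,
#' matching the topology filter applied when KEGG pathways are converted
#' to undirected graphs.
#'
#' @param path path to the edge-list/SIF file.
#' @param name pathway name; defaults to the file name without extension.
#' @return undirected connected `igraph` with a `name` graph attribute.
#' @export
read_pathway <- function(path, name = NULL) {
  g <- edges_to_graph(read_edges(path), what = paste0("pathway ", path))
  if (!igraph::is_connected(g)) {
    stop("pathway '", name %||% path, "' is not connected; ",
         "only pathways whose genes form a single connected component are accepted")
  }
  igraph::graph_attr(g, "name") <- name %||% sub("\\.[^.]*$", "", basename(path))
  g
}

#' Read a collection of pathway graphs via a manifest
#'
#' @param manifest TSV with columns `name` and `path` (paths relative to the
#'   manifest's directory unless absolute).
#' @return named list of pathway graphs.
#' @export
read_pathways <- function(manifest) {
  df <- read_tsv_file(manifest)
  if (!all(c("name", "path") %in% names(df))) {
    stop("pathway manifest needs columns 'name' and 'path': ", manifest)
  }
  base <- dirname(manifest)
  out <- lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, df$path[i])
    read_pathway(p, name = df$name[i])
  })
  names(out) <- df$name
  out
}

#' Write a graph as a 2-column edge-list TSV
#'
#' @param g `igraph` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  swap <- el[, 1L] > el[, 2L]
  el[swap, ] <- el[swap, c(2L, 1L)]
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  # headerless, the usual edge-list convention
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Read a mutation profile
#'
#' @param path TSV with columns `sample_id`, `gene`, `mutation_type`.
#' @return data.frame of mutation records.
#' @export
read_mutations <- function(path) {
  df <- read_tsv_file(path)
  need <- c("sample_id", "gene", "mutation_type")
  if (!all(need %in% names(df))) {
    stop("mutation file needs columns sample_id, gene, mutation_type: ", path)
  }
  df[need]
}

#' Write a mutation profile
#'
#' @param m mutation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(m, path) {
  write_tsv_file(m[c("sample_id", "gene", "mutation_type")], path)
}

#' Remove uninformative mutation types
#'
#' Drops records whose type is in `excluded_types` (matched
#' case-insensitively); unknown types are kept.  The default exclusion list
#' removes silent, intron and 5'UTR records, the types that do not alter the
#' protein product.
#'
#' @param m mutation data.frame (`sample_id`, `gene`, `mutation_type`).
#' @param excluded_types non-empty character vector of type labels to drop.
#' @return filtered data.frame (possibly empty).
#' @export
filter_mutations <- function(m, excluded_types = c("Silent", "Intron", "5'UTR")) {
  if (length(excluded_types) == 0L) {
    stop("'excluded_types' must be a non-empty list of mutation-type labels")
  }
  keep <- !(tolower(m$mutation_type) %in% tolower(excluded_types))
  m[keep, , drop = FALSE]
}

#' Tabulate driver-mutation combination patterns
#'
#' Maps each sample to the subset of `driver_genes` it mutates and counts
#' samples per distinct subset.  Fractions are over samples carrying at
#' least one driver mutation; samples with none are excluded from the
#' denominator.
#'
#' @param m filtered mutation data.frame.
#' @param driver_genes non-empty ordered character vector of driver genes.
#' @return data.frame with `combination_pattern` (driver symbols joined by
#'   `+`, in `driver_genes` order), `sample_count`, `fraction`.
#' @export
summarize_mutation_combinations <- function(m, driver_genes) {
  if (length(driver_genes) == 0L) stop("'driver_genes' must be non-empty")
  m <- m[m$gene %in% driver_genes, , drop = FALSE]
  if (nrow(m) == 0L) stop("no sample carries a mutation in any driver gene")
  pat <- vapply(split(m$gene, m$sample_id), function(gs) {
    paste(driver_genes[driver_genes %in% gs], collapse = "+")
  }, character(1L))
  tab <- table(pat)
  out <- data.frame(combination_pattern = names(tab),
                    sample_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$fraction <- out$sample_count / sum(out$sample_count)
  out <- out[order(-out$sample_count, out$combination_pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a sample-group set
#'
#' Groups pair a label (e.g. an organoid mutation-combination type) with its
#' sample identifiers and the ordered list of driver genes mutated in that
#' group (may be empty, e.g. for a normal group).
#'
#' @param groups named list; each element a list with `samples` (character)
#'   and `drivers` (character, possibly empty).
#' @param expression optional expression matrix to validate sample ids
#'   against.
#' @return the validated group list, classed `sample_groups`.
#' @export
sample_groups <- function(groups, expression = NULL) {
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("group labels must be unique and named")
  }
  for (lab in names(groups)) {
    g <- groups[[lab]]
    if (is.null(g$samples) || length(g$samples) == 0L) {
      stop("group '", lab, "' has no samples")
    }
    if (!is.null(expression) && !all(g$samples %in% colnames(expression))) {
      missing <- setdiff(g$samples, colnames(expression))
      stop("group '", lab, "' refers to samples absent from the expression matrix: ",
           paste(missing, collapse = ", "))
    }
    groups[[lab]]$drivers <- as.character(g$drivers %||% character(0L))
  }
  structure(groups, class = "sample_groups")
}

#' Read sample groups from TSV plus a driver map
#'
#' @param path TSV with columns `sample_id` and `group_label`.
#' @param drivers named list (or path to a TSV with columns `group_label`,
#'   `drivers` where drivers are comma-separated) mapping labels to driver
#'   gene lists.
#' @param expression optional expression matrix for validation.
#' @return `sample_groups` object.
#' @export
read_groups <- function(path, drivers = list(), expression = NULL) {
  df <- read_tsv_file(path)
  if (!all(c("sample_id", "group_label") %in% names(df))) {
    stop("groups file needs columns sample_id and group_label: ", path)
  }
  if (is.character(drivers) && length(drivers) == 1L) {
    dd <- read_tsv_file(drivers)
    drivers <- stats::setNames(
      lapply(dd$drivers, function(s) {
        if (is.na(s) || !nzchar(s)) character(0L) else strsplit(s, ",", fixed = TRUE)[[1L]]
      }),
      dd$group_label)
  }
  labs <- unique(df$group_label)
  groups <- lapply(labs, function(lab) {
    list(samples = df$sample_id[df$group_label == lab],
         drivers = drivers[[lab]] %||% character(0L))
  })
  names(groups) <- labs
  sample_groups(groups, expression = expression)
}
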