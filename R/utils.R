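# Internal helpers shared across modules.

#' Run code with a temporary RNG state
#'
#' Seeds the RNG, evaluates `code`, and restores the caller's RNG state on
#' exit, so stochastic operations are reproducible without clobbering the
#' session stream.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("a single finite 'seed' is required for every stochastic operation")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic per-stage seed derived from a master seed and a stage name.
# Keyed by the name so adding a stage never perturbs other stages' streams.
stage_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647L)
}

# TSV writer with fixed conventions so reruns are byte-identical.
write_tsv_file <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# Consistent number formatting for text outputs (full double precision).
num_chr <- function(x) {
  formatC(x, digits = 15, format = "g")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric vector as 1:n; this never does.
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
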