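# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that every generator is a pure function of its seed and
#' parameters, and so that calling a seeded function never perturbs the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar validators ---------------------------------------------------------

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop(sprintf("`%s` = %g is outside its valid range", name, x),
         call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# file I/O with provenance headers ------------------------------------------

#' Write a table with a provenance header
#'
#' All pipeline outputs are plain TSV/CSV files that begin with `#`-prefixed
#' provenance lines (tool version, timestamp-free parameters, seed) so that a
#' run can be reconstructed from its outputs alone.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param meta named list of provenance fields written as `# key: value`.
#' @param sep field separator (`"\t"` for TSV, `","` for CSV).
#' @return `path`, invisibly.
#' @export
write_table_prov <- function(x, path, meta = list(), sep = "\t") {
  meta <- c(list(tool = paste0("stemchrom ",
                               as.character(utils::packageVersion("stemchrom")))),
            meta)
  hdr <- vapply(seq_along(meta), function(i) {
    sprintf("# %s: %s", names(meta)[i],
            paste(trimws(as.character(meta[[i]])), collapse = ","))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table_prov()]
#'
#' @param path input path.
#' @param sep field separator.
#' @return data.frame; provenance lines are exposed as attribute `"prov"`.
#' @export
read_table_prov <- function(path, sep = "\t") {
  lines <- readLines(path, n = 100L)
  prov <- grep("^#", lines, value = TRUE)
  out <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "prov") <- prov
  out
}

CHROMATIN_CLASSES <- c("bivalent", "active", "unmarked")
CHIP_MARKS <- c("H2AZ", "H3K4me3", "H3K27me3")
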