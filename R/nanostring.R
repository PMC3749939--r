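# NanoString-style count normalization: housekeeping anchoring, gene
# centring, fold calls, and a Monte Carlo permutation FDR.

#' Construct a count matrix with a designated housekeeping set
#'
#' @param counts non-negative numeric matrix, genes x samples, with row
#'   and column names.
#' @param housekeeping housekeeping gene ids (must be rows of `counts`);
#'   defaults to the Gapdh/Tubb5/Cltc trio.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts,
                         housekeeping = c("Gapdh", "Tubb5", "Cltc")) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts)))
    stop("`counts` must be a matrix with gene and sample names",
         call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!length(housekeeping))
    stop("housekeeping set is empty", call. = FALSE)
  if (!all(housekeeping %in% rownames(counts)))
    stop("housekeeping genes missing from the matrix: ",
         paste(setdiff(housekeeping, rownames(counts)), collapse = ", "),
         call. = FALSE)
  structure(list(counts = counts, housekeeping = housekeeping),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples, housekeeping {%s}\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$housekeeping, collapse = ", ")))
  invisible(x)
}

#' Normalize log2 counts to the housekeeping geometric mean
#'
#' `value(g, s) = log2(count(g, s) + c) - mean_h log2(count(h, s) + c)`
#' over the housekeeping genes `h`: subtracting the mean of logs is the
#' log of the geometric mean, so housekeeping rows average exactly zero in
#' every sample and per-sample scale factors cancel (exactly when `c = 0`).
#'
#' @param m a [count_matrix()].
#' @param pseudocount count pseudocount `c` (>= 0); every housekeeping
#'   gene must satisfy `count + c > 0` in every sample.
#' @return object of class `normalized_matrix`: list with `values`
#'   (log2-scale matrix), `housekeeping`, `pseudocount`, `centered`.
#' @export
normalize_housekeeping <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "count_matrix"))
  stopifnot_scalar(pseudocount, "pseudocount", 0)
  hk <- m$housekeeping
  if (any(m$counts[hk, , drop = FALSE] + pseudocount <= 0))
    stop("housekeeping count + pseudocount must be positive everywhere",
         call. = FALSE)
  l <- log2(m$counts + pseudocount)
  anchor <- colMeans(l[hk, , drop = FALSE])
  structure(list(values = sweep(l, 2, anchor), housekeeping = hk,
                 pseudocount = pseudocount, centered = FALSE),
            class = "normalized_matrix")
}

#' Centre each gene across samples
#'
#' Subtracts the row mean, expressing each gene relative to its own
#' average across the experiments; idempotent.
#'
#' @param nm a `normalized_matrix` (>= 2 samples).
#' @return the centred `normalized_matrix`.
#' @export
center_genes <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (ncol(nm$values) < 2) stop("need at least 2 samples", call. = FALSE)
  nm$values <- nm$values - rowMeans(nm$values)
  nm$centered <- TRUE
  nm
}

#' Up/down fold calls on a normalized matrix
#'
#' Inclusive thresholds: `up` iff `value >= log2(fold)`, `down` iff
#' `value <= -log2(fold)`, `none` otherwise.
#'
#' @param nm a `normalized_matrix`.
#' @param fold linear fold threshold (> 1).
#' @return character matrix in `{"up", "down", "none"}` with the same
#'   dimnames as the values.
#' @export
fold_calls <- function(nm, fold = 2) {
  stopifnot(inherits(nm, "normalized_matrix"))
  stopifnot_scalar(fold, "fold", 1, strict_lower = TRUE)
  thr <- log2(fold)
  calls <- ifelse(nm$values >= thr, "up",
                  ifelse(nm$values <= -thr, "down", "none"))
  dimnames(calls) <- dimnames(nm$values)
  calls
}

# pooled-variance t statistic p-values for many label assignments at once;
# rows of `assign` are logical membership vectors for group A
.perm_t_pvalues <- function(meds, assign) {
  n <- length(meds)
  na <- rowSums(assign)
  nb <- n - na
  sa <- assign %*% meds
  sb <- sum(meds) - sa
  ssa <- assign %*% meds^2
  ssb <- sum(meds^2) - ssa
  ma <- sa / na; mb <- sb / nb
  va <- (ssa - na * ma^2) / (na - 1)
  vb <- (ssb - nb * mb^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(abs(tstat), df = na + nb - 2, lower.tail = FALSE)
}

#' Monte Carlo FDR for a median-expression group comparison
#'
#' The observed statistic is the unpaired equal-variance t-test p-value
#' comparing per-sample median expression between the two groups. The null
#' is built by randomly permuting the sample labels each iteration and
#' recomputing the p-value; the reported FDR is the fraction of null
#' iterations whose p-value falls at or below `p_threshold`. The statistic
#' is pluggable: `statistic` maps the normalized value matrix to one
#' number per sample.
#'
#' @param nm a `normalized_matrix`.
#' @param groups factor/character vector of length `ncol(values)` with
#'   exactly two levels, each with n >= 2 samples.
#' @param p_threshold the p-value threshold whose false discovery rate is
#'   estimated.
#' @param n_iter number of random label permutations (>= 100).
#' @param seed integer seed (deterministic estimate).
#' @param statistic function collapsing the gene x sample matrix to a
#'   per-sample summary; defaults to the per-sample median.
#' @return object of class `mc_fdr`: list with `observed_p`, `fdr`,
#'   `n_iter`, `p_threshold`, `group_sizes`.
#' @export
monte_carlo_fdr <- function(nm, groups, p_threshold = 0.05,
                            n_iter = 10000, seed = 1,
                            statistic = function(v) apply(v, 2,
                                                          stats::median)) {
  stopifnot(inherits(nm, "normalized_matrix"))
  stopifnot_scalar(p_threshold, "p_threshold", 0, 1)
  stopifnot_scalar(n_iter, "n_iter", 100)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2 || length(groups) != ncol(nm$values))
    stop("`groups` must label every sample with one of two levels",
         call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("each group needs at least 2 samples", call. = FALSE)
  if (choose(length(groups), sizes[1]) < 2)
    stop("groups too small to permute non-trivially", call. = FALSE)
  meds <- statistic(nm$values)
  in_a <- groups == levels(groups)[1]
  obs <- .perm_t_pvalues(meds, matrix(in_a, nrow = 1))[1]
  n <- length(groups)
  na <- sum(in_a)
  fdr <- with_seed(seed, {
    assign <- matrix(FALSE, n_iter, n)
    for (i in seq_len(n_iter))
      assign[i, sample.int(n, na)] <- TRUE
    null_p <- .perm_t_pvalues(meds, assign)
    mean(null_p <= p_threshold)
  })
  structure(list(observed_p = obs, fdr = fdr, n_iter = n_iter,
                 p_threshold = p_threshold,
                 group_sizes = as.integer(sizes)),
            class = "mc_fdr")
}

#' @export
print.mc_fdr <- function(x, ...) {
  cat(sprintf(
    "mc_fdr: observed p = %.4g; FDR at p <= %.3g is %.3f (%d iterations)\n",
    x$observed_p, x$p_threshold, x$fdr, x$n_iter))
  invisible(x)
}

#' Read / write count matrices as CSV
#'
#' Genes in rows (first column `gene_id`), samples in columns; `#` lines
#' are provenance.
#' @param m a `count_matrix`.
#' @param path file path.
#' @param meta extra provenance fields.
#' @return `path` (write) or a `count_matrix` (read).
#' @export
write_counts_csv <- function(m, path, meta = list()) {
  df <- data.frame(gene_id = rownames(m$counts), m$counts,
                   check.names = FALSE)
  write_table_prov(df, path,
                   c(meta, list(housekeeping = m$housekeeping)), sep = ",")
}

#' @rdname write_counts_csv
#' @param housekeeping housekeeping ids used when the header records none.
#' @export
read_counts_csv <- function(path,
                            housekeeping = c("Gapdh", "Tubb5", "Cltc")) {
  df <- read_table_prov(path, sep = ",")
  prov <- attr(df, "prov")
  hk_line <- grep("^# housekeeping:", prov, value = TRUE)
  if (length(hk_line))
    housekeeping <- trimws(strsplit(sub("^# housekeeping: *", "",
                                        hk_line[1]), ",")[[1]])
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  count_matrix(counts, housekeeping = housekeeping)
}
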