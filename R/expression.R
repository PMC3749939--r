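# Integration of per-isoform expression with promoter chromatin classes:
# per-TSS summation, fold-change stratification, overlap and
# distributional tests, hierarchical clustering.

#' Sum isoform RPKMs per TSS
#'
#' Each isoform contributes exactly once to the transcriptional output of
#' its TSS; genes with no isoforms are absent from the result.
#'
#' @param isoforms data.frame with `isoform_id`, `gene_id`, and one or more
#'   `rpkm_*` columns (e.g. `rpkm_A`, `rpkm_B`); optional `chrom`, `tss`
#'   columns are carried through.
#' @return object of class `tss_expression`: data.frame keyed by `gene_id`
#'   with the per-condition sums.
#' @export
sum_by_tss <- function(isoforms) {
  if (anyDuplicated(isoforms$isoform_id))
    stop("duplicate isoform ids", call. = FALSE)
  rpkm_cols <- grep("^rpkm", names(isoforms), value = TRUE)
  if (!length(rpkm_cols)) stop("no rpkm_* columns found", call. = FALSE)
  key <- factor(isoforms$gene_id, levels = unique(isoforms$gene_id))
  sums <- rowsum(isoforms[rpkm_cols], key)
  out <- data.frame(gene_id = levels(key), sums, stringsAsFactors = FALSE)
  for (col in intersect(c("chrom", "tss"), names(isoforms)))
    out[[col]] <- isoforms[[col]][match(out$gene_id, isoforms$gene_id)]
  rownames(out) <- NULL
  structure(out, class = c("tss_expression", "data.frame"))
}

#' Per-gene log2 fold changes with a pseudocount
#'
#' `log2((B + c) / (A + c))`; the pseudocount bounds fold changes for
#' silent genes (0/0 maps to 0).
#'
#' @param tss_expr a [sum_by_tss()] result with `rpkm_A` and `rpkm_B`.
#' @param pseudocount RPKM pseudocount `c` (> 0).
#' @param classes optional named vector (`gene_id` -> chromatin class), or
#'   a `promoter_table`; attaches a `class` column.
#' @return object of class `fold_change_set`: data.frame with `gene_id`,
#'   `log2fc` and (optionally) `class`.
#' @export
log2_fold_changes <- function(tss_expr, pseudocount = 1, classes = NULL) {
  stopifnot_scalar(pseudocount, "pseudocount", 0, strict_lower = TRUE)
  fc <- log2((tss_expr$rpkm_B + pseudocount) /
             (tss_expr$rpkm_A + pseudocount))
  out <- data.frame(gene_id = tss_expr$gene_id, log2fc = fc,
                    stringsAsFactors = FALSE)
  if (!is.null(classes)) {
    if (inherits(classes, "promoter_table") || is.data.frame(classes))
      classes <- stats::setNames(classes$class, classes$gene_id)
    out$class <- unname(classes[out$gene_id])
  }
  structure(out, pseudocount = pseudocount,
            class = c("fold_change_set", "data.frame"))
}

#' Differentially-expressed gene set at a linear fold threshold
#'
#' Strict inequality: a gene qualifies iff `|log2 FC| > log2(threshold)`,
#' so a fold change of exactly `threshold` is excluded.
#'
#' @param fc a `fold_change_set`.
#' @param threshold linear fold-change threshold (> 1).
#' @return character vector of gene ids.
#' @export
differential_set <- function(fc, threshold = 1.5) {
  stopifnot_scalar(threshold, "threshold", 1, strict_lower = TRUE)
  fc$gene_id[abs(fc$log2fc) > log2(threshold)]
}

#' Upper-tail hypergeometric overlap test between two gene sets
#'
#' `p = P(X >= |A intersect B|)` when `|B|` genes are drawn without
#' replacement from the universe containing `|A|` successes.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param universe character vector containing both sets.
#' @return object of class `overlap_test`: list with `n_a`, `n_b`,
#'   `n_universe`, `n_overlap`, `p`, and `log_p` (natural-log p, exact even
#'   when `p` underflows).
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be subsets of the universe", call. = FALSE)
  k <- length(intersect(set_a, set_b))
  m <- length(set_a); n <- length(universe) - m; b <- length(set_b)
  p <- stats::phyper(k - 1, m, n, b, lower.tail = FALSE)
  log_p <- stats::phyper(k - 1, m, n, b, lower.tail = FALSE, log.p = TRUE)
  structure(list(n_a = m, n_b = b, n_universe = length(universe),
                 n_overlap = k, p = p, log_p = log_p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap_test: |A|=%d |B|=%d |A&B|=%d universe=%d  p=%.4g\n",
    x$n_a, x$n_b, x$n_overlap, x$n_universe, x$p))
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of class-stratified fold changes
#'
#' Two-sample, two-sided KS tests between the log2 fold-change
#' distributions of every pair of chromatin classes, and of each class
#' against all genes. Classes with fewer than 2 genes are skipped with a
#' warning record.
#'
#' @param fc a `fold_change_set` with a `class` column.
#' @return data.frame with `sample1`, `sample2`, `n1`, `n2`, `D`, `p`;
#'   skipped comparisons are listed in `attr(, "skipped")`.
#' @export
ks_stratified <- function(fc) {
  if (is.null(fc$class)) stop("fold changes carry no class labels",
                              call. = FALSE)
  groups <- split(fc$log2fc, fc$class)
  ok <- names(groups)[lengths(groups) >= 2]
  skipped <- setdiff(names(groups), ok)
  if (length(skipped))
    warning("classes skipped (fewer than 2 genes): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  pairs <- if (length(ok) >= 2) utils::combn(ok, 2, simplify = FALSE)
           else list()
  cmp <- c(pairs, lapply(ok, function(g) c(g, "all")))
  rows <- lapply(cmp, function(pr) {
    x <- groups[[pr[1]]]
    y <- if (pr[2] == "all") fc$log2fc else groups[[pr[2]]]
    kt <- suppressWarnings(stats::ks.test(x, y))
    data.frame(sample1 = pr[1], sample2 = pr[2],
               n1 = length(x), n2 = length(y),
               D = unname(kt$statistic), p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample1 = character(), sample2 = character(),
               n1 = integer(), n2 = integer(), D = numeric(),
               p = numeric())
  attr(out, "skipped") <- skipped
  out
}

#' Classic equal-variance two-sample t test with group medians
#'
#' Unpaired, pooled-variance, two-sided; medians are reported alongside
#' the test because group location is summarised by the median in the
#' expression analyses.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return list with `median_x`, `median_y`, `t`, `df`, `p`, `n_x`, `n_y`.
#' @export
median_group_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("degenerate variance in both groups: t is undefined",
         call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(median_x = stats::median(x), median_y = stats::median(y),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_x = length(x), n_y = length(y))
}

#' Hierarchically cluster a fold-change matrix
#'
#' Agglomerative clustering under the Euclidean metric; the linkage
#' defaults to average (UPGMA). Ordering is deterministic for a given
#' distance structure.
#'
#' @param fc_matrix numeric matrix, genes x timepoints, finite values.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `hclust` (the tree) and `order` (leaf gene ids top to
#'   bottom).
#' @export
cluster_fold_changes <- function(fc_matrix, linkage = "average") {
  if (!is.matrix(fc_matrix) || nrow(fc_matrix) < 2)
    stop("need a matrix with at least 2 genes", call. = FALSE)
  if (any(!is.finite(fc_matrix)))
    stop("fold-change matrix contains non-finite values", call. = FALSE)
  h <- stats::hclust(stats::dist(fc_matrix, method = "euclidean"),
                     method = linkage)
  ids <- rownames(fc_matrix) %||% as.character(seq_len(nrow(fc_matrix)))
  list(hclust = h, order = ids[h$order])
}
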