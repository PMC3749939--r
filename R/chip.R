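# ChIP-seq enrichment calling on binned read counts, promoter
# classification, and TSS-centred display computations.
#
# Coordinates are 0-based half-open throughout; TSS windows are
# closed-open [tss - w, tss + w).

#' Enrichment-calling parameters
#'
#' Defaults follow the standard binned-Poisson recipe: reads extended to
#' the 200 bp average fragment length, allocated to 25 bp bins, bins called
#' enriched at an upper-tail Poisson p-value below 1e-9 and at least 5-fold
#' over the (library-size scaled) input. No multiple-testing correction is
#' applied; the fixed threshold is the method.
#'
#' @param extension fragment extension length (bp).
#' @param bin_width bin width (bp).
#' @param p_threshold Poisson upper-tail p-value threshold, in (0, 1).
#' @param fold_min minimum IP/input fold (pseudocount-stabilised).
#' @param merge_gap maximum number of non-enriched bins bridged when
#'   merging enriched bins into regions; 0 merges strictly adjacent bins
#'   only.
#' @param local_lambda use the local input bin count in the Poisson rate
#'   (the rate is `max(local, genome-wide mean)` when TRUE, the genome-wide
#'   mean alone when FALSE).
#' @return object of class `enrichment_params`.
#' @export
enrichment_params <- function(extension = 200, bin_width = 25,
                              p_threshold = 1e-9, fold_min = 5,
                              merge_gap = 0, local_lambda = TRUE) {
  stopifnot_scalar(extension, "extension", 1)
  stopifnot_scalar(bin_width, "bin_width", 1)
  stopifnot_scalar(p_threshold, "p_threshold", 0, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  stopifnot_scalar(fold_min, "fold_min", 0)
  stopifnot_scalar(merge_gap, "merge_gap", 0)
  structure(list(extension = extension, bin_width = bin_width,
                 p_threshold = p_threshold, fold_min = fold_min,
                 merge_gap = merge_gap, local_lambda = isTRUE(local_lambda)),
            class = "enrichment_params")
}

#' Extend reads to fragment length
#'
#' Plus-strand reads extend from their 5' start, minus-strand reads from
#' their 3' coordinate backwards: a plus read at `[s, .)` becomes
#' `[s, s + L)`; a minus read ending at `e` becomes `[e - L, e)`. Fragments
#' are clipped to chromosome bounds when the read set carries chromosome
#' sizes.
#'
#' @param reads a `read_set` data.frame (`chrom`, `start`, `end`, `strand`)
#'   with optional `attr(, "chrom_sizes")`.
#' @param length extension length (bp), >= read length.
#' @return data.frame of fragments (`chrom`, `start`, `end`) with
#'   `chrom_sizes` attribute propagated.
#' @export
extend_reads <- function(reads, length = 200) {
  stopifnot_scalar(length, "length", 1)
  if (any(reads$end - reads$start > length))
    stop("`length` must be at least the read length", call. = FALSE)
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$start, reads$end - length)
  end <- start + length
  start <- pmax(start, 0)
  sizes <- attr(reads, "chrom_sizes")
  if (!is.null(sizes)) end <- pmin(end, as.numeric(sizes[reads$chrom]))
  out <- data.frame(chrom = reads$chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  attr(out, "chrom_sizes") <- sizes
  out
}

#' Allocate fragments to fixed-width bins
#'
#' Each fragment contributes one count to the bin containing its midpoint,
#' so the track total equals the fragment count exactly. The last partial
#' bin of each chromosome is included.
#'
#' @param fragments data.frame (`chrom`, `start`, `end`) with
#'   `chrom_sizes` attribute, e.g. from [extend_reads()].
#' @param bin_width bin width (bp).
#' @param chrom_sizes named chromosome lengths; defaults to the attribute
#'   on `fragments`.
#' @param label library label stored on the track.
#' @return object of class `bin_track`: list with `bin_width`, `counts`
#'   (named list of per-chromosome integer vectors), `total`, `label`.
#' @export
bin_counts <- function(fragments, bin_width = 25,
                       chrom_sizes = attr(fragments, "chrom_sizes"),
                       label = "track") {
  stopifnot_scalar(bin_width, "bin_width", 1)
  if (is.null(chrom_sizes))
    stop("chromosome sizes are required to lay out bins", call. = FALSE)
  mid <- floor((fragments$start + fragments$end) / 2)
  bin <- mid %/% bin_width
  counts <- lapply(names(chrom_sizes), function(ch) {
    nb <- as.integer(ceiling(chrom_sizes[[ch]] / bin_width))
    sel <- fragments$chrom == ch
    tabulate(pmin(bin[sel], nb - 1L) + 1L, nbins = nb)
  })
  names(counts) <- names(chrom_sizes)
  structure(list(bin_width = bin_width, counts = counts,
                 total = sum(vapply(counts, sum, numeric(1))),
                 chrom_sizes = chrom_sizes, label = label),
            class = "bin_track")
}

#' @export
print.bin_track <- function(x, ...) {
  cat(sprintf("bin_track '%s': %d bp bins, %d chromosome(s), total %g\n",
              x$label, x$bin_width, length(x$counts), x$total))
  invisible(x)
}

# shared grid check
check_same_grid <- function(ip, input) {
  if (ip$bin_width != input$bin_width ||
      !identical(names(ip$counts), names(input$counts)) ||
      !identical(lengths(ip$counts), lengths(input$counts)))
    stop("IP and input tracks must share an identical bin grid",
         call. = FALSE)
}

#' Per-bin Poisson enrichment statistics
#'
#' The Poisson rate for each bin is
#' `lambda = max(local input count, genome-wide input mean per bin)` scaled
#' by the IP/input library-size ratio (the conservative local/global max);
#' the p-value is the upper tail `P(X >= k; lambda)` and the fold is
#' `(k + 1) / (lambda + 1)` (one-fragment pseudocount, stabilising sparse
#' bins).
#'
#' @param ip,input `bin_track` objects on the same grid; input total must
#'   be positive.
#' @param params an [enrichment_params()] object.
#' @return named list of per-chromosome data.frames with `count`,
#'   `lambda`, `p`, `fold`, `enriched`.
#' @export
bin_enrichment_stats <- function(ip, input, params = enrichment_params()) {
  stopifnot(inherits(ip, "bin_track"), inherits(input, "bin_track"))
  check_same_grid(ip, input)
  if (input$total <= 0)
    stop("input track total is zero: cannot scale the Poisson rate",
         call. = FALSE)
  if (ip$total <= 0)
    stop("IP track total is zero", call. = FALSE)
  scale <- ip$total / input$total
  n_bins <- sum(lengths(input$counts))
  gmean <- input$total / n_bins
  out <- lapply(names(ip$counts), function(ch) {
    k <- ip$counts[[ch]]
    loc <- input$counts[[ch]]
    lam <- if (params$local_lambda) pmax(loc, gmean) else rep(gmean,
                                                              length(loc))
    lam <- lam * scale
    p <- stats::ppois(k - 1, lam, lower.tail = FALSE)
    fold <- (k + 1) / (lam + 1)
    data.frame(count = k, lambda = lam, p = p, fold = fold,
               enriched = p < params$p_threshold & fold >= params$fold_min)
  })
  names(out) <- names(ip$counts)
  out
}

#' Call enriched regions from binned IP and input tracks
#'
#' Bins passing both the Poisson p-value threshold and the minimum-fold
#' filter (see [bin_enrichment_stats()]) are merged into regions; runs of
#' enriched bins separated by more than `merge_gap` non-enriched bins stay
#' separate regions.
#'
#' @inheritParams bin_enrichment_stats
#' @return object of class `enriched_regions`: data.frame with `chrom`,
#'   `start`, `end`, `n_bins`, `min_p`, `max_fold`, sorted and
#'   non-overlapping; the parameters used are attached as
#'   `attr(, "params")`.
#' @export
call_enriched <- function(ip, input, params = enrichment_params()) {
  stats_by_chrom <- bin_enrichment_stats(ip, input, params)
  w <- ip$bin_width
  regions <- lapply(names(stats_by_chrom), function(ch) {
    st <- stats_by_chrom[[ch]]
    enr <- st$enriched
    if (!any(enr)) return(NULL)
    idx <- which(enr)
    brk <- c(0L, which(diff(idx) > params$merge_gap + 1), length(idx))
    recs <- lapply(seq_len(length(brk) - 1L), function(j) {
      bins <- idx[(brk[j] + 1L):brk[j + 1L]]
      span <- bins[1]:bins[length(bins)]
      data.frame(chrom = ch,
                 start = (bins[1] - 1L) * w,
                 end = min(bins[length(bins)] * w,
                           as.numeric(ip$chrom_sizes[[ch]])),
                 n_bins = length(bins),
                 min_p = min(st$p[span]),
                 max_fold = max(st$fold[span]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
  regions <- do.call(rbind, regions)
  if (is.null(regions))
    regions <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), n_bins = integer(),
                          min_p = numeric(), max_fold = numeric(),
                          stringsAsFactors = FALSE)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  structure(regions, params = params,
            class = c("enriched_regions", "data.frame"))
}

#' Write enriched regions as BED6+2 (fold, -log10 p)
#'
#' @param regions an `enriched_regions` object.
#' @param path output path.
#' @param meta extra provenance fields.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, meta = list()) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE,
                                 trim = TRUE),
                    name = sprintf("region%d", seq_len(nrow(regions))),
                    score = 0L, strand = ".",
                    fold = signif(regions$max_fold, 6),
                    neg_log10_p = signif(-log10(pmax(regions$min_p,
                                                     1e-300)), 6))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", c(paste0("stemchrom ",
                                      utils::packageVersion("stemchrom")),
                               unlist(meta))), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Classify promoters by enrichment-region boundaries near the TSS
#'
#' A mark flags a TSS when either boundary of one of its enriched regions
#' falls inside the closed-open window `[tss - window, tss + window)`.
#' Classes follow the bivalency rule: `bivalent` = H3K4me3 and H3K27me3,
#' `active` = H3K4me3 only, `unmarked` otherwise.
#'
#' @param regions_by_mark named list of `enriched_regions` (names are mark
#'   labels); must include `H3K4me3` and `H3K27me3`.
#' @param genome a `genome_model` (or a data.frame of genes with `gene_id`,
#'   `chrom`, `tss`, `strand`).
#' @param window promoter half-width (bp).
#' @return object of class `promoter_table`: data.frame with `gene_id`,
#'   `chrom`, `tss`, `strand`, one logical column per mark, and `class`.
#' @export
annotate_promoters <- function(regions_by_mark, genome, window = 2000) {
  stopifnot_scalar(window, "window", 0, strict_lower = TRUE)
  for (req in c("H3K4me3", "H3K27me3"))
    if (!req %in% names(regions_by_mark))
      stop("missing required mark: ", req, call. = FALSE)
  genes <- if (inherits(genome, "genome_model")) genome$genes else genome
  # boundary b flags a TSS iff b falls in the half-open window
  # [tss - w, tss + w)
  flags <- lapply(regions_by_mark, function(regions) {
    hit <- logical(nrow(genes))
    if (nrow(regions)) {
      for (ch in unique(regions$chrom)) {
        gi <- which(genes$chrom == ch)
        if (!length(gi)) next
        sel <- which(regions$chrom == ch)
        bounds <- c(regions$start[sel], regions$end[sel])
        tss <- genes$tss[gi]
        for (b in bounds) hit[gi[b >= tss - window & b < tss + window]] <- TRUE
      }
    }
    hit
  })
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    tss = genes$tss, strand = genes$strand,
                    stringsAsFactors = FALSE)
  for (mk in names(flags)) out[[mk]] <- flags[[mk]]
  out$class <- ifelse(out$H3K4me3 & out$H3K27me3, "bivalent",
                      ifelse(out$H3K4me3, "active", "unmarked"))
  structure(out, window = window,
            class = c("promoter_table", "data.frame"))
}

# fragments sorted per chromosome, returns coverage accumulator over
# offsets -hw..hw for one TSS
.tss_coverage <- function(starts, ends, tss, strand, hw) {
  n <- 2L * hw + 1L
  cov <- numeric(n + 1L)
  if (!length(starts)) return(cov[seq_len(n)])
  s_off <- starts - tss
  e_off <- ends - tss
  if (strand == "-") {  # reflect: covered offsets o -> -o
    tmp <- -e_off + 1
    e_off <- -s_off + 1
    s_off <- tmp
  }
  a <- pmax(s_off, -hw) + hw + 1L
  b <- pmin(e_off, hw + 1L) + hw + 1L
  keep <- a < b
  a <- a[keep]; b <- b[keep]
  for (i in seq_along(a)) {
    cov[a[i]] <- cov[a[i]] + 1
    cov[b[i]] <- cov[b[i]] - 1
  }
  cumsum(cov)[seq_len(n)]
}

#' Average TSS-centred fragment coverage (metagene profile)
#'
#' Computes per-bp extended-fragment coverage in TSS-relative coordinates,
#' flipping minus-strand genes so that positive offsets are downstream of
#' the TSS, and averages over the selected TSSs.
#'
#' @param fragments data.frame (`chrom`, `start`, `end`), e.g. from
#'   [extend_reads()].
#' @param promoters a `promoter_table` or genome `genes` data.frame.
#' @param halfwidth window half-width (bp).
#' @param classes optional subset of promoter classes to average over
#'   (requires a `class` column).
#' @return object of class `metagene_profile`: list with `offset`
#'   (-halfwidth..halfwidth), `density` (mean coverage per bp) and `n`
#'   (number of TSSs averaged).
#' @export
metagene_profile <- function(fragments, promoters, halfwidth = 2000,
                             classes = NULL) {
  stopifnot_scalar(halfwidth, "halfwidth", 1)
  genes <- as.data.frame(promoters)
  if (!is.null(classes)) genes <- genes[genes$class %in% classes, ,
                                        drop = FALSE]
  if (!nrow(genes)) stop("no TSS passes the class filter", call. = FALSE)
  hw <- as.integer(halfwidth)
  total <- numeric(2L * hw + 1L)
  for (ch in unique(genes$chrom)) {
    frag <- fragments[fragments$chrom == ch, , drop = FALSE]
    ord <- order(frag$start)
    fs <- frag$start[ord]; fe <- frag$end[ord]
    maxlen <- if (length(fs)) max(fe - fs) else 0
    gi <- which(genes$chrom == ch)
    for (g in gi) {
      tss <- genes$tss[g]
      lo <- findInterval(tss - hw - maxlen, fs) + 1L
      hi <- findInterval(tss + hw, fs)
      if (hi < lo) {
        sel <- integer(0)
      } else {
        sel <- lo:hi
        sel <- sel[fe[sel] > tss - hw]
      }
      total <- total + .tss_coverage(fs[sel], fe[sel], tss,
                                     genes$strand[g], hw)
    }
  }
  structure(list(offset = -hw:hw, density = total / nrow(genes),
                 n = nrow(genes)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: +/-%d bp around %d TSS(s), peak %.3g\n",
              max(x$offset), x$n, max(x$density)))
  invisible(x)
}

# per-gene window sum of bin counts, strand-flipped row of densities
.gene_window_bins <- function(track, tss, strand, hw) {
  w <- track$bin_width
  nb_win <- ceiling(2 * hw / w)
  first <- floor((tss - hw) / w)
  idx <- first + seq_len(nb_win) - 1L
  counts <- track$counts[[1]]  # caller passes single-chromosome view
  v <- numeric(nb_win)
  ok <- idx >= 0 & idx < length(counts)
  v[ok] <- counts[idx[ok] + 1L]
  if (strand == "-") v <- rev(v)
  v
}

#' Gene-by-offset density matrix ordered by a ranking mark
#'
#' Rows are genes ordered from most to least enriched for `order_mark`
#' (summed bin counts over `tss +/- halfwidth`); ties break
#' lexicographically by gene id. One matrix per supplied track, all with
#' the same row order; minus-strand rows are flipped so downstream is to
#' the right.
#'
#' @param track_by_mark named list of `bin_track` objects.
#' @param promoters a `promoter_table` or genome `genes` data.frame.
#' @param halfwidth window half-width (bp).
#' @param order_mark name of the ranking track.
#' @return object of class `ordered_density_matrix`: list with `gene_id`
#'   (ordered), `score` (ranking sums, same order), `offsets` (bin-centre
#'   offsets) and `matrices` (named list of genes x offsets matrices).
#' @export
ordered_density_matrix <- function(track_by_mark, promoters,
                                   halfwidth = 4000,
                                   order_mark = "H3K27me3") {
  if (!order_mark %in% names(track_by_mark))
    stop("ranking track not supplied: ", order_mark, call. = FALSE)
  genes <- as.data.frame(promoters)
  w <- track_by_mark[[1]]$bin_width
  nb_win <- ceiling(2 * halfwidth / w)
  rows_for <- function(track) {
    m <- matrix(0, nrow(genes), nb_win)
    for (g in seq_len(nrow(genes))) {
      view <- list(bin_width = track$bin_width,
                   counts = track$counts[genes$chrom[g]])
      names(view$counts) <- NULL
      m[g, ] <- .gene_window_bins(view, genes$tss[g], genes$strand[g],
                                  halfwidth)
    }
    rownames(m) <- genes$gene_id
    m
  }
  mats <- lapply(track_by_mark, rows_for)
  score <- unname(rowSums(mats[[order_mark]]))
  ord <- order(-score, genes$gene_id)
  offsets <- -halfwidth + (seq_len(nb_win) - 0.5) * w
  structure(list(gene_id = genes$gene_id[ord], score = score[ord],
                 offsets = offsets,
                 matrices = lapply(mats, function(m) m[ord, , drop = FALSE]),
                 order_mark = order_mark),
            class = "ordered_density_matrix")
}

#' Write a metagene profile as TSV
#' @param profile a `metagene_profile`.
#' @param path output path.
#' @param meta extra provenance fields.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, meta = list()) {
  write_table_prov(data.frame(offset = profile$offset,
                              density = profile$density),
                   path, c(meta, list(n_tss = profile$n)))
}
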