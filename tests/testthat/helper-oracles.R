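# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths (and, where possible, the library calls) they check.

# Upper-tail Poisson probability P(X >= k; lambda) by direct series
# summation of the density, independent of stats::ppois.
poisson_tail_oracle <- function(k, lambda) {
  j <- seq(k, max(k + 300, ceiling(lambda * 4)))
  sum(exp(-lambda + j * log(lambda) - lgamma(j + 1)))
}

# Upper-tail hypergeometric p-value by exhaustive enumeration of every
# possible draw of |B| elements from the universe (feasible for
# universes up to ~12).
hypergeom_enum_oracle <- function(set_a, set_b, universe) {
  k_obs <- length(intersect(set_a, set_b))
  draws <- utils::combn(universe, length(set_b), simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, set_a)) >= k_obs,
              logical(1)))
}

# Two-sample KS D statistic by direct CDF scan over the pooled values.
ks_d_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(fx - fy))
}

# Pooled-variance two-sample t statistic by hand.
pooled_t_oracle <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# Build a bin_track directly from a counts vector (single chromosome).
make_bin_track <- function(counts, bin_width = 25, label = "track",
                           chrom = "chr1") {
  structure(list(bin_width = bin_width,
                 counts = stats::setNames(list(as.numeric(counts)), chrom),
                 total = sum(counts),
                 chrom_sizes = stats::setNames(length(counts) * bin_width,
                                               chrom),
                 label = label),
            class = "bin_track")
}

# Minimal read_set constructor for hand-built fixtures (sorted by start,
# matching the package convention).
make_reads <- function(chrom, start, end, strand, chrom_len = 1e6) {
  sizes <- stats::setNames(rep(chrom_len, length(unique(chrom))),
                           unique(chrom))
  ord <- order(chrom, start)
  structure(data.frame(chrom = chrom[ord], start = start[ord],
                       end = end[ord], strand = strand[ord],
                       stringsAsFactors = FALSE),
            chrom_sizes = sizes, class = c("read_set", "data.frame"))
}

# Fragment midpoints of a read set after extension, for density oracles.
fragment_midpoints <- function(reads, extension = 200) {
  fr <- extend_reads(reads, extension)
  floor((fr$start + fr$end) / 2)
}
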