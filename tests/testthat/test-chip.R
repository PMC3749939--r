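# Enrichment calling: extension, binning, the Poisson caller, promoter
# classification and TSS-centred displays.

test_that("extend_reads is strand-aware and clips at chromosome bounds", {
  reads <- make_reads(rep("chr1", 3), c(1000, 800, 0), c(1036, 1000, 150),
                      c("+", "-", "-"))
  fr <- extend_reads(reads, 200)
  # read_set rows are sorted by start: (0,150,-), (800,1000,-), (1000,...)
  expect_equal(fr$start, c(0, 800, 1000))
  expect_equal(fr$end, c(150, 1000, 1200))
  expect_error(extend_reads(make_reads("chr1", 0, 300, "+"), 200),
               "at least the read length")
})

test_that("bin_counts assigns fragments by midpoint and conserves totals", {
  fr <- data.frame(chrom = "chr1", start = 1000, end = 1200)
  attr(fr, "chrom_sizes") <- c(chr1 = 2000)
  tr <- bin_counts(fr, 25)
  expect_equal(which(tr$counts$chr1 == 1) - 1L, 44L)  # midpoint 1100
  expect_equal(tr$total, 1)

  tr0 <- bin_counts(fr[0, ], 25, chrom_sizes = c(chr1 = 2000))
  expect_equal(tr0$total, 0)
  expect_true(all(tr0$counts$chr1 == 0))

  fr10 <- data.frame(chrom = "chr1", start = rep(1000, 10),
                     end = rep(1010, 10))
  tr10 <- bin_counts(fr10, 25, chrom_sizes = c(chr1 = 2000))
  expect_equal(max(tr10$counts$chr1), 10)
  expect_equal(tr10$total, 10)

  # conservation on arbitrary input
  set.seed(42)
  n <- 1000
  st <- sort(sample.int(99000, n))
  frr <- data.frame(chrom = "chr1", start = st, end = st + 200)
  expect_equal(bin_counts(frr, 25, chrom_sizes = c(chr1 = 1e5))$total, n)
})

test_that("the minimum enriched count at lambda = 1 matches the exact tail", {
  # independent oracle: direct series summation of the Poisson density
  tails <- vapply(1:30, function(k) poisson_tail_oracle(k, 1), numeric(1))
  expect_equal(min(which(tails < 1e-9)), 12)

  # implementation: lambda is exactly 1 on a uniform unit input with
  # equal library sizes and the global-mean-only rate
  input1 <- make_bin_track(rep(1, 465))
  ip1 <- make_bin_track(c(1:30, rep(1, 435)))
  ip1$total <- input1$total  # equal library sizes -> scale 1
  st <- bin_enrichment_stats(ip1, input1,
                             enrichment_params(local_lambda = FALSE))$chr1
  expect_equal(st$lambda, rep(1, 465))
  expect_equal(min(st$count[st$p < 1e-9]), 12)
  expect_equal(st$p[1:30], tails[1:30], tolerance = 1e-12)
})

test_that("identical IP and input tracks yield no enriched regions", {
  set.seed(7)
  x <- rpois(5000, 3) + 1
  tr <- make_bin_track(x)
  reg <- call_enriched(tr, tr, enrichment_params(fold_min = 5))
  expect_equal(nrow(reg), 0)
})

test_that("the caller is calibrated on i.i.d. Poisson null tracks", {
  # 10 seeded pairs of 1e5-bin null tracks: essentially no enriched bins
  total_bins <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    ip <- make_bin_track(rpois(1e5, 2))
    input <- make_bin_track(rpois(1e5, 2))
    st <- bin_enrichment_stats(ip, input)$chr1
    total_bins <- total_bins + sum(st$p < 1e-9)  # before the fold filter
  }
  expect_lte(total_bins, 2L)
})

test_that("the enrichment p-value is monotone in the IP count", {
  input <- make_bin_track(rep(2, 100))
  ip <- make_bin_track(0:99)
  ip$total <- input$total
  st <- bin_enrichment_stats(ip, input,
                             enrichment_params(local_lambda = FALSE))$chr1
  expect_true(all(diff(st$p) <= 0))
})

test_that("adjacent enriched bins merge; a gap splits regions", {
  counts <- rep(1, 200)
  counts[50:52] <- 40       # one run of three enriched bins
  counts[60] <- 40          # an isolated enriched bin
  ip <- make_bin_track(counts)
  input <- make_bin_track(rep(1, 200))
  input$total <- ip$total   # scale 1, lambda 1
  reg <- call_enriched(ip, input)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start, c(49 * 25, 59 * 25))
  expect_equal(reg$end, c(52 * 25, 60 * 25))
  expect_equal(reg$n_bins, c(3L, 1L))
  # a permissive merge gap bridges the separation
  reg2 <- call_enriched(ip, input, enrichment_params(merge_gap = 10))
  expect_equal(nrow(reg2), 1)
})

test_that("zero-total input is rejected", {
  ip <- make_bin_track(rep(1, 10))
  input <- make_bin_track(rep(0, 10))
  expect_error(call_enriched(ip, input), "input track total is zero")
})

test_that("annotate_promoters applies the boundary-in-window rule", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000,
                      strand = "+", stringsAsFactors = FALSE)
  reg <- function(s, e) data.frame(chrom = rep("chr1", length(s)),
                                   start = s, end = e,
                                   stringsAsFactors = FALSE)
  none <- reg(numeric(0), numeric(0))

  # K4 region overlapping the TSS, no K27: active
  pt <- annotate_promoters(list(H3K4me3 = reg(9900, 10300), H3K27me3 = none),
                           genes, window = 2000)
  expect_equal(pt$class, "active")

  # both marks: bivalent
  pt2 <- annotate_promoters(list(H3K4me3 = reg(9900, 10300),
                                 H3K27me3 = reg(9000, 11000)),
                            genes, window = 2000)
  expect_equal(pt2$class, "bivalent")

  # K27 region [TSS+1990, TSS+2400]: start boundary just inside the window
  pt3 <- annotate_promoters(list(H3K4me3 = none,
                                 H3K27me3 = reg(11990, 12400)),
                            genes, window = 2000)
  expect_true(pt3$H3K27me3)
  expect_equal(pt3$class, "unmarked")  # K27 without K4

  # boundary exactly at TSS + window is outside the half-open window
  pt4 <- annotate_promoters(list(H3K4me3 = none,
                                 H3K27me3 = reg(12000, 12400)),
                            genes, window = 2000)
  expect_false(pt4$H3K27me3)

  expect_error(annotate_promoters(list(H3K4me3 = none), genes),
               "missing required mark: H3K27me3")
})

test_that("metagene_profile maps fragments into TSS-relative coordinates", {
  genes_p <- data.frame(gene_id = "g1", chrom = "chr1", tss = 5000,
                        strand = "+", stringsAsFactors = FALSE)
  fr <- data.frame(chrom = "chr1", start = 5050, end = 5250)
  pr <- metagene_profile(fr, genes_p, halfwidth = 500)
  expect_equal(pr$density[pr$offset >= 50 & pr$offset < 250],
               rep(1, 200))
  expect_equal(sum(pr$density), 200)

  # minus-strand TSS: same fragment appears reflected
  genes_m <- transform(genes_p, strand = "-")
  prm <- metagene_profile(fr, genes_m, halfwidth = 500)
  expect_equal(prm$density[prm$offset > -250 & prm$offset <= -50],
               rep(1, 200))
  expect_equal(sum(prm$density), 200)

  expect_error(metagene_profile(fr, genes_p[0, ], halfwidth = 500),
               "no TSS")
})

test_that("metagene profile of simulated bimodal IP peaks at +/-100 bp", {
  g <- gen_genome(1, 1e6, 40, c(1, 0, 0), seed = 2)
  sp <- sim_params(fold = c(bivalent = 20, active = 1, unmarked = 1),
                   total_reads = 3e5, depletion = 0, seed = 4)
  libs <- gen_chip_reads(g, sp, "H2AZ")
  # fragment-midpoint density (the binned-count view of the data); raw
  # 200 bp coverage blurs the two flanking components into one plateau
  mid <- fragment_midpoints(libs$ip)
  fr_mid <- data.frame(chrom = extend_reads(libs$ip, 200)$chrom,
                       start = mid, end = mid + 1)
  pr <- metagene_profile(fr_mid, g$genes, halfwidth = 1000)
  peak_up <- pr$offset[which.max(pr$density * (pr$offset < 0))]
  peak_dn <- pr$offset[which.max(pr$density * (pr$offset > 0))]
  expect_lt(abs(peak_up + 100), 50)
  expect_lt(abs(peak_dn - 100), 50)
  # flanking peaks rise above both the NFR shoulder and the far background
  far <- mean(pr$density[abs(pr$offset) > 800])
  expect_gt(pr$density[pr$offset == -100], 2 * far)
  expect_gt(pr$density[pr$offset == 100], 2 * far)
})

test_that("a strand-mirrored dataset gives the offset-reflected profile", {
  genes_p <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                        tss = c(4000, 9000), strand = "+",
                        stringsAsFactors = FALSE)
  set.seed(9)
  st <- sample(2000:10000, 300, replace = TRUE)
  fr <- data.frame(chrom = "chr1", start = st, end = st + 150)
  pr <- metagene_profile(fr, genes_p, halfwidth = 800)

  genes_m <- transform(genes_p, strand = "-")
  # reflect every fragment around its gene-free absolute frame by
  # mirroring coordinates across each TSS is equivalent to flipping the
  # gene strand; the profile must be the offset reflection
  prm <- metagene_profile(fr, genes_m, halfwidth = 800)
  expect_equal(prm$density, rev(pr$density))
})

test_that("ordered_density_matrix ranks genes by window sums with id ties", {
  genes <- data.frame(gene_id = c("gene1", "gene2", "gene3"),
                      chrom = "chr1", tss = c(2000, 6000, 10000),
                      strand = "+", stringsAsFactors = FALSE)
  counts <- rep(0, 480)  # 12 kb at 25 bp
  counts[(2000 %/% 25) + 1] <- 10
  counts[(6000 %/% 25) + 1] <- 5
  counts[(10000 %/% 25) + 1] <- 20
  k27 <- make_bin_track(counts)
  odm <- ordered_density_matrix(list(H3K27me3 = k27), genes,
                                halfwidth = 1000)
  expect_equal(odm$gene_id, c("gene3", "gene1", "gene2"))
  expect_equal(odm$score, c(20, 10, 5))

  # all-equal scores: lexicographic gene order
  flat <- make_bin_track(rep(1, 480))
  odm2 <- ordered_density_matrix(list(H3K27me3 = flat), genes,
                                 halfwidth = 1000)
  expect_equal(odm2$gene_id, c("gene1", "gene2", "gene3"))

  # adding a constant to every bin preserves the order
  odm3 <- ordered_density_matrix(list(H3K27me3 = make_bin_track(counts + 3)),
                                 genes, halfwidth = 1000)
  expect_equal(odm3$gene_id, odm$gene_id)

  expect_error(ordered_density_matrix(list(H3K4me3 = k27), genes),
               "ranking track not supplied")
})
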