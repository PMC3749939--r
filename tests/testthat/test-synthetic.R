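# Generators: determinism, parameter recovery, and degenerate settings.

test_that("gen_genome places classed genes inside bounds with 5 kb spacing", {
  g <- gen_genome(1, 1e6, 50, c(0.3, 0.5, 0.2), seed = 1)
  expect_equal(nrow(g$genes), 50)
  expect_true(all(g$genes$tss >= 0 & g$genes$tss < 1e6))
  expect_true(all(diff(sort(g$genes$tss)) >= 5000))
  expect_false(anyDuplicated(g$genes$gene_id) > 0)
  expect_true(all(g$genes$class %in% c("bivalent", "active", "unmarked")))

  g2 <- gen_genome(1, 1e6, 50, c(0.3, 0.5, 0.2), seed = 7)
  g3 <- gen_genome(1, 1e6, 50, c(0.3, 0.5, 0.2), seed = 7)
  expect_identical(g2$genes, g3$genes)

  g4 <- gen_genome(1, 1e6, 30, c(1, 0, 0), seed = 2)
  expect_true(all(g4$genes$class == "bivalent"))

  expect_error(gen_genome(1, 1e5, 50, c(0.3, 0.5, 0.2), seed = 1),
               "cannot place")
})

test_that("gene classes are drawn from the requested class probabilities", {
  probs <- c(bivalent = 0.3, active = 0.5, unmarked = 0.2)
  g <- gen_genome(1, 6e7, 10000, probs, seed = 11)
  counts <- table(factor(g$genes$class, names(probs)))
  expect_gt(stats::chisq.test(counts, p = probs)$p.value, 0.001)
})

test_that("gen_chip_reads conserves read counts and honours the seed", {
  g <- gen_genome(1, 1e6, 20, c(0.5, 0.3, 0.2), seed = 1)
  sp <- sim_params(fold = c(bivalent = 10, active = 1, unmarked = 1),
                   total_reads = 5e4, seed = 5)
  libs <- gen_chip_reads(g, sp, "H3K27me3")
  expect_equal(nrow(libs$ip), 5e4)
  expect_equal(nrow(libs$input), 5e4)
  expect_true(all(libs$ip$start >= 0))
  expect_true(all(libs$ip$end <= 1e6))
  libs2 <- gen_chip_reads(g, sp, "H3K27me3")
  expect_identical(libs$ip, libs2$ip)
  expect_error(gen_chip_reads(g, sp, "H3K9me3"), "unknown mark")
})

test_that("a unit-fold configuration is indistinguishable from input", {
  g <- gen_genome(1, 1e6, 20, c(0.5, 0.3, 0.2), seed = 1)
  sp <- sim_params(fold = c(bivalent = 1, active = 1, unmarked = 1),
                   total_reads = 1e5, seed = 9)
  libs <- gen_chip_reads(g, sp, "H2AZ")
  # counts over an arbitrary window should differ only by sampling noise
  win <- c(3e5, 7e5)
  k_ip <- sum(libs$ip$start >= win[1] & libs$ip$start < win[2])
  k_in <- sum(libs$input$start >= win[1] & libs$input$start < win[2])
  expect_gt(stats::binom.test(k_ip, k_ip + k_in, 0.5)$p.value, 0.001)
})

test_that("the promoter enrichment fold is recovered from read densities", {
  g <- gen_genome(1, 1e6, 50, c(0.3, 0.5, 0.2), seed = 1)
  sp <- sim_params(fold = c(bivalent = 20, active = 1, unmarked = 1),
                   total_reads = 1e6, depletion = 0, seed = 3)
  libs <- gen_chip_reads(g, sp, "H2AZ")
  mi <- fragment_midpoints(libs$ip)
  mn <- fragment_midpoints(libs$input)
  biv <- g$genes[g$genes$class == "bivalent", ]
  ratio <- vapply(biv$tss, function(t) {
    sum(mi >= t - 200 & mi < t + 200) /
      max(sum(mn >= t - 200 & mn < t + 200), 1)
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 20) / 20, 0.25)
})

test_that("full depletion removes the downstream (+1) peak", {
  g <- gen_genome(1, 1e6, 50, c(0.3, 0.5, 0.2), seed = 1)
  sp <- sim_params(fold = c(bivalent = 20, active = 1, unmarked = 1),
                   total_reads = 5e5, depletion = 1, seed = 3)
  libs <- gen_chip_reads(g, sp, "H2AZ")
  mid <- fragment_midpoints(libs$ip)
  biv <- g$genes[g$genes$class == "bivalent", ]
  down <- 0; up <- 0
  for (i in seq_len(nrow(biv))) {
    rel <- (mid - biv$tss[i]) * ifelse(biv$strand[i] == "+", 1, -1)
    down <- down + sum(rel > 25 & rel <= 200)
    up <- up + sum(rel < -25 & rel >= -200)
  }
  expect_lt(down / up, 0.1)
})

test_that("gen_expression applies class shifts to per-TSS sums", {
  g <- gen_genome(1, 1e6, 100, c(0.4, 0.3, 0.3), seed = 4)
  cls <- stats::setNames(g$genes$class, g$genes$gene_id)

  # no shift, no noise: conditions identical
  iso0 <- gen_expression(g, c(bivalent = 0, active = 0, unmarked = 0),
                         noise_sd = 0, seed = 2)
  expect_equal(iso0$rpkm_A, iso0$rpkm_B)

  # +1 shift, no noise: every bivalent TSS sum doubles exactly
  iso1 <- gen_expression(g, c(bivalent = 1, active = 0, unmarked = 0),
                         noise_sd = 0, seed = 2)
  tss <- sum_by_tss(iso1)
  biv <- tss$gene_id %in% names(cls)[cls == "bivalent"]
  expect_equal(tss$rpkm_B[biv], 2 * tss$rpkm_A[biv])
  expect_equal(tss$rpkm_B[!biv], tss$rpkm_A[!biv])

  # with noise, the class mean log2 fold change converges to the shift
  g200 <- gen_genome(1, 6e6, 600, c(1 / 3, 1 / 3, 1 / 3), seed = 4)
  isoN <- gen_expression(g200, c(bivalent = 1, active = 0, unmarked = 0),
                         noise_sd = 0.1, seed = 6)
  tssN <- sum_by_tss(isoN)
  clsN <- stats::setNames(g200$genes$class, g200$genes$gene_id)
  lfc <- log2(tssN$rpkm_B / tssN$rpkm_A)
  expect_lt(abs(mean(lfc[clsN[tssN$gene_id] == "bivalent"]) - 1), 0.05)
})

test_that("gen_frap_curves realises the closed-form recovery model", {
  # noiseless long recovery: endpoint estimator round-trips the truth
  ps <- frap_sim_params(mf = 0.2, k = 0.05, dt = 30, n_frames = 20,
                        noise_sd = 0, seed = 1)  # k*T = 27
  cv <- gen_frap_curves(ps, 1)[[1]]
  expect_lt(abs(mobile_fraction(normalize_curve(cv))$mf - 0.2), 1e-3)

  # immobile pool only: flat post-bleach curve at the dip
  ps0 <- frap_sim_params(mf = 0, k = 0.05, i_dip = 0.4, n_frames = 10,
                         noise_sd = 0, seed = 1)
  cv0 <- gen_frap_curves(ps0, 1)[[1]]
  post <- cv0$intensity[cv0$bleach_index:length(cv0$intensity)]
  expect_equal(post, rep(0.4, length(post)))

  # closed-form endpoint: I(900 s) = 0.5 + 0.13*0.5*(1 - exp(-9))
  ps2 <- frap_sim_params(mf = 0.13, k = 0.01, i_dip = 0.5, dt = 30,
                         n_frames = 32, n_pre = 1, noise_sd = 0, seed = 1)
  cv2 <- gen_frap_curves(ps2, 1)[[1]]
  expect_lt(abs(utils::tail(cv2$intensity, 1) - 0.565), 1e-3)

  expect_error(frap_sim_params(n_frames = 2), "too small")
  c_a <- gen_frap_curves(frap_sim_params(seed = 3), 4)
  c_b <- gen_frap_curves(frap_sim_params(seed = 3), 4)
  expect_identical(c_a, c_b)
})

test_that("gen_nanostring anchors housekeeping rows and encodes effects", {
  # constant everything: centred normalized values are all zero
  cm <- gen_nanostring(n_genes = 5, n_samples = 4, noise_sd = 0, seed = 1)
  nm <- center_genes(normalize_housekeeping(cm, pseudocount = 0))
  expect_equal(max(abs(nm$values)), 0)

  # per-sample scaling is removed by housekeeping anchoring
  cm10 <- gen_nanostring(n_genes = 5, n_samples = 4, noise_sd = 0,
                         scale = c(10, 1, 1, 1),
                         base_meanlog = log(5000), seed = 1)
  v1 <- normalize_housekeeping(cm10, pseudocount = 0)$values
  v0 <- normalize_housekeeping(cm, pseudocount = 0)$values
  expect_lt(max(abs(v1 - v0)), 0.01)  # rounding to integer counts only

  # a +1 log2 effect in half the samples is recovered from the output
  eff <- matrix(0, 10, 20); eff[1, 11:20] <- 1
  cmE <- gen_nanostring(n_genes = 10, n_samples = 20, effects = eff,
                        noise_sd = 0.05, seed = 8)
  nmE <- normalize_housekeeping(cmE, pseudocount = 0)
  d <- mean(nmE$values["gene001", 11:20]) -
    mean(nmE$values["gene001", 1:10])
  expect_lt(abs(d - 1), 0.1)
})
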