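# Synthetic-data generators: every input the pipeline consumes can be
# produced here with known ground truth, so downstream stages are testable
# without any external download.

#' Simulation parameters for ChIP-seq read generation
#'
#' Parameterises the generative model behind [gen_chip_reads()]: a uniform
#' Poisson background plus, at each enriched TSS, two Gaussian-shaped
#' fragment-midpoint components flanking the nucleosome-free region. The
#' downstream (+1 nucleosome) component can be attenuated with
#' `depletion`, emulating loss of the +1 nucleosome signal.
#'
#' @param background_rate expected background fragment density (reads/bp);
#'   only relative weights matter because `total_reads` is fixed.
#' @param fold named per-class enrichment fold (>= 1) over background for
#'   `bivalent`, `active` and `unmarked` genes. A fold of 1 means no
#'   enrichment. Fold is calibrated so that the mean IP/input density ratio
#'   over TSS +/- `target_halfwidth` approximates the requested fold.
#' @param peak_offset distance (bp) of each flanking peak from the TSS.
#' @param peak_sd Gaussian spread (bp) of each peak component.
#' @param depletion attenuation of the downstream (+1) component in `[0,1]`;
#'   0 keeps the bimodal pattern symmetric, 1 removes the +1 peak.
#' @param total_reads total reads emitted per library (exact).
#' @param read_length sequenced read length (bp).
#' @param fragment_length immunoprecipitated fragment length (bp); reads are
#'   emitted as fragment 5' ends so that downstream extension to this length
#'   reconstitutes the fragment.
#' @param target_halfwidth half-width (bp) of the TSS window over which the
#'   enrichment fold is calibrated.
#' @param seed integer seed.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(background_rate = 0.25,
                       fold = c(bivalent = 1, active = 1, unmarked = 1),
                       peak_offset = 100, peak_sd = 50, depletion = 0,
                       total_reads = 1e6, read_length = 36,
                       fragment_length = 200, target_halfwidth = 200,
                       seed = 1) {
  stopifnot_scalar(background_rate, "background_rate", 0, strict_lower = TRUE)
  if (is.null(names(fold)) || !all(CHROMATIN_CLASSES %in% names(fold)))
    stop("`fold` must be named with classes ",
         paste(CHROMATIN_CLASSES, collapse = ", "), call. = FALSE)
  if (any(fold < 1)) stop("enrichment folds must be >= 1", call. = FALSE)
  stopifnot_scalar(depletion, "depletion", 0, 1)
  stopifnot_scalar(total_reads, "total_reads", 1)
  stopifnot_scalar(read_length, "read_length", 1)
  stopifnot_scalar(fragment_length, "fragment_length", read_length)
  stopifnot_scalar(peak_offset, "peak_offset", 0)
  stopifnot_scalar(peak_sd, "peak_sd", 0, strict_lower = TRUE)
  structure(list(background_rate = background_rate,
                 fold = fold[CHROMATIN_CLASSES],
                 peak_offset = peak_offset, peak_sd = peak_sd,
                 depletion = depletion, total_reads = total_reads,
                 read_length = read_length,
                 fragment_length = fragment_length,
                 target_halfwidth = target_halfwidth, seed = seed),
            class = "sim_params")
}

#' Generate a genome model with classed genes
#'
#' Places `n_genes` TSSs on `n_chrom` chromosomes with guaranteed >= 5 kb
#' spacing (genes occupy disjoint 5 kb slots; the TSS sits at the slot
#' centre) and draws each gene's true chromatin class i.i.d. from
#' `class_probs`.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length (bp), shared by all chromosomes.
#' @param n_genes total number of genes.
#' @param class_probs probabilities for (bivalent, active, unmarked);
#'   must sum to 1.
#' @param seed integer seed.
#' @return an object of class `genome_model`: a list with `chrom_sizes`
#'   (named vector) and `genes` (data.frame with `gene_id`, `chrom`, `tss`,
#'   `strand`, `class`).
#' @examples
#' g <- gen_genome(1, 1e6, 50, c(0.3, 0.5, 0.2), seed = 1)
#' table(g$genes$class)
#' @export
gen_genome <- function(n_chrom = 1, chrom_len = 1e6, n_genes = 50,
                       class_probs = c(bivalent = 0.3, active = 0.5,
                                       unmarked = 0.2),
                       seed = 1) {
  stopifnot_scalar(n_chrom, "n_chrom", 1)
  stopifnot_scalar(chrom_len, "chrom_len", 1)
  stopifnot_scalar(n_genes, "n_genes", 1)
  if (length(class_probs) != 3L || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-8)
    stop("`class_probs` must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  spacing <- 5000
  slots_per_chrom <- floor(chrom_len / spacing)
  if (n_genes * spacing > n_chrom * chrom_len ||
      n_genes > n_chrom * slots_per_chrom)
    stop(sprintf(paste0("cannot place %d genes with %d bp spacing on %d ",
                        "chromosome(s) of %g bp"),
                 n_genes, spacing, n_chrom, chrom_len), call. = FALSE)
  chrom_names <- sprintf("chr%d", seq_len(n_chrom))
  chrom_sizes <- stats::setNames(rep(chrom_len, n_chrom), chrom_names)
  with_seed(seed, {
    # spread genes over chromosomes as evenly as capacity allows
    per_chrom <- rep(floor(n_genes / n_chrom), n_chrom)
    extra <- n_genes - sum(per_chrom)
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    recs <- lapply(seq_len(n_chrom), function(i) {
      k <- per_chrom[i]
      if (k == 0) return(NULL)
      slots <- sort(sample.int(slots_per_chrom, k))
      data.frame(chrom = chrom_names[i],
                 tss = (slots - 1) * spacing + spacing / 2,
                 stringsAsFactors = FALSE)
    })
    genes <- do.call(rbind, recs)
    genes$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes$class <- sample(CHROMATIN_CLASSES, n_genes, replace = TRUE,
                          prob = class_probs)
    genes <- genes[order(genes$chrom, genes$tss), , drop = FALSE]
    genes <- data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                        genes, stringsAsFactors = FALSE)
    rownames(genes) <- NULL
    structure(list(chrom_sizes = chrom_sizes, genes = genes),
              class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %d genes\n",
              length(x$chrom_sizes), nrow(x$genes)))
  print(table(x$genes$class))
  invisible(x)
}

# construct a read_set data.frame (BED-like, 0-based half-open)
new_read_set <- function(chrom, start, end, strand, chrom_sizes) {
  ord <- order(chrom, start)
  structure(data.frame(chrom = chrom[ord], start = start[ord],
                       end = end[ord], strand = strand[ord],
                       stringsAsFactors = FALSE),
            chrom_sizes = chrom_sizes, class = c("read_set", "data.frame"))
}

#' Generate an IP and matched input ChIP-seq read set
#'
#' Emits exactly `params$total_reads` single-end reads (5' start + strand,
#' BED convention) per library. Input reads are uniform; IP reads are a
#' mixture of the uniform background and two Gaussian fragment-midpoint
#' components at +/- `peak_offset` from each enriched TSS, oriented by gene
#' strand, with the downstream component scaled by `1 - depletion`. The
#' per-gene peak mass is calibrated so that the expected IP/input density
#' ratio over TSS +/- `target_halfwidth` approximates the class fold.
#'
#' @param genome a `genome_model`.
#' @param params a [sim_params()] object.
#' @param mark one of `"H2AZ"`, `"H3K4me3"`, `"H3K27me3"` (label recorded on
#'   the output; unknown labels are an error).
#' @return list with elements `ip` and `input`, each a `read_set`
#'   data.frame (`chrom`, `start`, `end`, `strand`) carrying
#'   `attr(, "chrom_sizes")`.
#' @export
gen_chip_reads <- function(genome, params, mark) {
  stopifnot(inherits(genome, "genome_model"), inherits(params, "sim_params"))
  if (!is.character(mark) || length(mark) != 1L || !(mark %in% CHIP_MARKS))
    stop("unknown mark label: ", paste(mark, collapse = ","),
         "; expected one of ", paste(CHIP_MARKS, collapse = ", "),
         call. = FALSE)
  sizes <- genome$chrom_sizes
  genes <- genome$genes
  rate <- params$background_rate
  w <- 2 * params$target_halfwidth

  # mixture component weights: one uniform background per chromosome, then
  # an upstream and a downstream Gaussian per enriched gene
  bg_w <- rate * as.numeric(sizes)
  f <- unname(params$fold[genes$class])
  # per-gene extra mass relative to background so the window-averaged
  # IP/input ratio ~ fold; halved per flank, +1 flank scaled by 1-depletion
  half <- (f - 1) * rate * w / 2
  up_w <- half
  dn_w <- half * (1 - params$depletion)
  sgn <- ifelse(genes$strand == "+", 1, -1)
  up_centre <- genes$tss - sgn * params$peak_offset
  dn_centre <- genes$tss + sgn * params$peak_offset

  comp_w <- c(bg_w, up_w, dn_w)
  comp_chrom <- c(names(sizes), genes$chrom, genes$chrom)
  n_bg <- length(bg_w)
  n_g <- nrow(genes)

  draw_library <- function(weights) {
    n <- as.integer(params$total_reads)
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    centre <- numeric(n)
    is_bg <- comp <= n_bg
    if (any(is_bg)) {
      len <- as.numeric(sizes)[comp[is_bg]]
      centre[is_bg] <- stats::runif(sum(is_bg), 0, len)
    }
    is_up <- comp > n_bg & comp <= n_bg + n_g
    if (any(is_up)) {
      gi <- comp[is_up] - n_bg
      centre[is_up] <- stats::rnorm(sum(is_up), up_centre[gi], params$peak_sd)
    }
    is_dn <- comp > n_bg + n_g
    if (any(is_dn)) {
      gi <- comp[is_dn] - n_bg - n_g
      centre[is_dn] <- stats::rnorm(sum(is_dn), dn_centre[gi], params$peak_sd)
    }
    chrom <- comp_chrom[comp]
    len <- as.numeric(sizes[chrom])
    # fragment [centre - L/2, centre + L/2); sequence a read from one end
    frag <- params$fragment_length
    rl <- params$read_length
    plus <- stats::runif(length(comp)) < 0.5
    start <- ifelse(plus, round(centre - frag / 2),
                    round(centre + frag / 2) - rl)
    start <- pmin(pmax(start, 0), len - rl)
    new_read_set(chrom, start, start + rl,
                 ifelse(plus, "+", "-"), sizes)
  }

  with_seed(params$seed, {
    ip <- draw_library(comp_w)
    input <- draw_library(c(bg_w, rep(0, 2 * n_g)))
    list(ip = ip, input = input)
  })
}

#' Generate a two-condition isoform expression table
#'
#' Condition A isoform RPKMs are lognormal; condition B values are the
#' condition A values shifted by a per-class log2 effect with multiplicative
#' lognormal noise. All isoforms of a gene share its TSS, so per-TSS sums
#' inherit the class shift.
#'
#' @param genome a `genome_model`.
#' @param class_shift_log2 named per-class log2 fold shift applied in
#'   condition B.
#' @param n_isoforms isoforms per gene.
#' @param meanlog,sdlog lognormal law for condition A isoform RPKMs.
#' @param noise_sd standard deviation (log2 units) of the multiplicative
#'   noise on condition B.
#' @param seed integer seed.
#' @return data.frame with `isoform_id`, `gene_id`, `chrom`, `tss`,
#'   `rpkm_A`, `rpkm_B`.
#' @export
gen_expression <- function(genome,
                           class_shift_log2 = c(bivalent = 0, active = 0,
                                                unmarked = 0),
                           n_isoforms = 2, meanlog = log(10), sdlog = 1,
                           noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(genome, "genome_model"))
  if (!all(CHROMATIN_CLASSES %in% names(class_shift_log2)))
    stop("`class_shift_log2` must be named with all chromatin classes",
         call. = FALSE)
  if (any(!is.finite(class_shift_log2)))
    stop("class shifts must be finite", call. = FALSE)
  stopifnot_scalar(n_isoforms, "n_isoforms", 1)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  genes <- genome$genes
  n <- nrow(genes) * n_isoforms
  idx <- rep(seq_len(nrow(genes)), each = n_isoforms)
  with_seed(seed, {
    a <- stats::rlnorm(n, meanlog, sdlog)
    shift <- unname(class_shift_log2[genes$class[idx]])
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    b <- a * 2^(shift + noise)
    data.frame(isoform_id = sprintf("%s.i%d", genes$gene_id[idx],
                                    rep(seq_len(n_isoforms), nrow(genes))),
               gene_id = genes$gene_id[idx],
               chrom = genes$chrom[idx],
               tss = genes$tss[idx],
               rpkm_A = a, rpkm_B = b,
               stringsAsFactors = FALSE)
  })
}

#' FRAP simulation parameters
#'
#' Parameterises the single-exponential recovery model with an immobile
#' fraction: pre-bleach frames at 1, then
#' `I(t) = I_dip + MF * (1 - I_dip) * (1 - exp(-k t))` with additive
#' Gaussian noise, where `t` is time since the bleach frame.
#'
#' @param mf true mobile fraction in `[0, 1]`.
#' @param k recovery rate constant (1/s), > 0.
#' @param i_dip normalized intensity immediately after the bleach pulse,
#'   in (0, 1).
#' @param dt frame interval (s).
#' @param n_frames total frames, pre-bleach included.
#' @param n_pre pre-bleach frames (>= 1).
#' @param noise_sd additive Gaussian noise s.d. (intensity units).
#' @param seed integer seed.
#' @return object of class `frap_sim_params`.
#' @export
frap_sim_params <- function(mf = 0.13, k = 0.01, i_dip = 0.5, dt = 30,
                            n_frames = 30, n_pre = 1, noise_sd = 0.01,
                            seed = 1) {
  stopifnot_scalar(mf, "mf", 0, 1)
  stopifnot_scalar(k, "k", 0, strict_lower = TRUE)
  stopifnot_scalar(i_dip, "i_dip", 0, 1, strict_lower = TRUE,
                   strict_upper = TRUE)
  stopifnot_scalar(dt, "dt", 0, strict_lower = TRUE)
  stopifnot_scalar(n_frames, "n_frames", 1)
  stopifnot_scalar(n_pre, "n_pre", 1)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  if (n_frames < n_pre + 2)
    stop("`n_frames` too small to contain the bleach and a recovery segment",
         call. = FALSE)
  structure(list(mf = mf, k = k, i_dip = i_dip, dt = dt,
                 n_frames = n_frames, n_pre = n_pre, noise_sd = noise_sd,
                 seed = seed),
            class = "frap_sim_params")
}

#' Generate FRAP recovery curves
#'
#' @param params a [frap_sim_params()] object.
#' @param n_cells number of cells (one curve each).
#' @return list of [frap_curve()] objects. The bleach frame (index
#'   `n_pre + 1`) holds the dip intensity (zero elapsed recovery time).
#' @export
gen_frap_curves <- function(params, n_cells = 1) {
  stopifnot(inherits(params, "frap_sim_params"))
  stopifnot_scalar(n_cells, "n_cells", 1)
  tt <- (seq_len(params$n_frames) - 1) * params$dt
  b <- params$n_pre + 1L
  elapsed <- tt - tt[b]
  model <- ifelse(seq_along(tt) < b, 1,
                  params$i_dip + params$mf * (1 - params$i_dip) *
                    (1 - exp(-params$k * elapsed)))
  with_seed(params$seed, {
    lapply(seq_len(n_cells), function(i) {
      noise <- if (params$noise_sd > 0)
        stats::rnorm(length(tt), 0, params$noise_sd) else 0
      frap_curve(tt, model + noise, bleach_index = b,
                 cell_id = sprintf("cell%03d", i))
    })
  })
}

#' Generate a NanoString-style count matrix
#'
#' Counts are `round(scale_s * base_g * 2^(effect_gs + noise))`, with
#' housekeeping gene effects fixed at zero so that housekeeping-anchored
#' normalization can undo the per-sample scale factors.
#'
#' @param n_genes number of non-housekeeping genes.
#' @param n_samples number of samples.
#' @param housekeeping housekeeping gene ids (rows added to the matrix).
#' @param scale per-sample scale factors (length `n_samples`).
#' @param effects log2 effect matrix (`n_genes` x `n_samples`), or a single
#'   number recycled; housekeeping rows are always 0.
#' @param base_meanlog,base_sdlog lognormal law for per-gene base counts.
#' @param noise_sd log2-scale multiplicative noise s.d.
#' @param seed integer seed.
#' @return object of class `count_matrix` (see [count_matrix()]).
#' @export
gen_nanostring <- function(n_genes = 20, n_samples = 6,
                           housekeeping = c("Gapdh", "Tubb5", "Cltc"),
                           scale = rep(1, n_samples), effects = 0,
                           base_meanlog = log(500), base_sdlog = 0.5,
                           noise_sd = 0.05, seed = 1) {
  stopifnot_scalar(n_genes, "n_genes", 1)
  stopifnot_scalar(n_samples, "n_samples", 2)
  if (length(scale) != n_samples || any(scale <= 0))
    stop("`scale` must give one positive factor per sample", call. = FALSE)
  if (is.matrix(effects)) {
    if (!all(dim(effects) == c(n_genes, n_samples)))
      stop("`effects` matrix must be n_genes x n_samples", call. = FALSE)
  } else {
    effects <- matrix(effects, n_genes, n_samples)
  }
  gene_ids <- c(housekeeping, sprintf("gene%03d", seq_len(n_genes)))
  eff <- rbind(matrix(0, length(housekeeping), n_samples), effects)
  with_seed(seed, {
    base <- stats::rlnorm(length(gene_ids), base_meanlog, base_sdlog)
    noise <- if (noise_sd > 0)
      matrix(stats::rnorm(length(gene_ids) * n_samples, 0, noise_sd),
             length(gene_ids), n_samples) else 0
    counts <- round(outer(base, scale) * 2^(eff + noise))
    dimnames(counts) <- list(gene_ids, sprintf("s%d", seq_len(n_samples)))
    count_matrix(counts, housekeeping = housekeeping)
  })
}

#' Write a genome's gene annotation to TSV
#'
#' Columns: `gene_id`, `chrom`, `tss`, `strand`, `class`.
#' @param genome a `genome_model`.
#' @param path output path.
#' @param meta extra provenance fields.
#' @return `path`, invisibly.
#' @export
write_genes_tsv <- function(genome, path, meta = list()) {
  write_table_prov(genome$genes, path, meta)
}

#' Write a read set as BED6
#'
#' 0-based half-open intervals; score column fixed at 0. The file starts
#' with `#` provenance lines, which standard BED consumers skip.
#' @param reads a `read_set`.
#' @param path output path.
#' @param name feature name prefix.
#' @param meta extra provenance fields.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path, name = "read", meta = list()) {
  bed <- data.frame(chrom = reads$chrom,
                    start = format(reads$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(reads$end, scientific = FALSE, trim = TRUE),
                    name = sprintf("%s%d", name, seq_len(nrow(reads))),
                    score = 0L, strand = reads$strand)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", c(paste0("stemchrom ",
                                      utils::packageVersion("stemchrom")),
                               unlist(meta))), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file into a read set
#'
#' @param path BED6 path (may contain `#` comment lines).
#' @param chrom_sizes optional named chromosome lengths attached to the
#'   result (needed for clipping during extension).
#' @return a `read_set` data.frame.
#' @export
read_reads_bed <- function(path, chrom_sizes = NULL) {
  bed <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("expected BED6 input", call. = FALSE)
  new_read_set(bed[[1]], bed[[2]], bed[[3]], bed[[6]], chrom_sizes)
}

#' Write FRAP curves as CSV
#'
#' Column 1 is `time_s`, then one intensity column per cell; the bleach
#' frame is recorded in a `#bleach_frame=` header line.
#' @param curves list of `frap_curve` objects sharing a time grid.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frap_csv <- function(curves, path) {
  stopifnot(length(curves) >= 1)
  b <- unique(vapply(curves, function(cv) cv$bleach_index, numeric(1)))
  if (length(b) != 1)
    stop("curves must share a bleach frame to share a CSV", call. = FALSE)
  tt <- curves[[1]]$time
  mat <- vapply(curves, function(cv) {
    if (!isTRUE(all.equal(cv$time, tt)))
      stop("curves must share a time grid", call. = FALSE)
    cv$intensity
  }, numeric(length(tt)))
  df <- data.frame(time_s = tt, mat)
  names(df) <- c("time_s", vapply(curves, function(cv) cv$cell_id,
                                  character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#bleach_frame=%d", b), con)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FRAP curves from CSV
#'
#' @param path CSV written by [write_frap_csv()].
#' @return list of `frap_curve` objects.
#' @export
read_frap_csv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("#bleach_frame=([0-9]+)", first))[[1]]
  if (length(m) < 2) stop("missing #bleach_frame= header", call. = FALSE)
  b <- as.integer(m[2])
  df <- utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  lapply(names(df)[-1], function(id) {
    frap_curve(df$time_s, df[[id]], bleach_index = b, cell_id = id)
  })
}
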