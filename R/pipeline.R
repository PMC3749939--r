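# End-to-end orchestration: simulate -> call -> classify -> integrate ->
# report, from a single config with one master seed. The package
# functions are the interface; run_pipeline() wires them together for a
# reproducible one-command rerun.

#' Default pipeline configuration
#'
#' Returns the demo configuration: a two-chromosome synthetic genome,
#' H3K4me3/H3K27me3 ChIP libraries enriched according to the true
#' chromatin classes, a two-condition expression table with a +1 log2
#' shift at bivalent genes, a six-sample NanoString matrix and two FRAP
#' groups. Every stage seed is derived deterministically from
#' `master_seed`.
#'
#' @param master_seed integer master seed.
#' @param outdir output directory for stage outputs and the run log.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(master_seed = 42,
                                    outdir = tempfile("stemchrom_run_")) {
  list(
    seed = master_seed,
    outdir = outdir,
    write_reads = FALSE,
    genome = list(n_chrom = 2, chrom_len = 1e6, n_genes = 200,
                  class_probs = c(bivalent = 0.3, active = 0.4,
                                  unmarked = 0.3)),
    chip = list(marks = c("H3K4me3", "H3K27me3"),
                background_rate = 0.25, total_reads = 2e5,
                enriched_fold = 20, depletion = 0.3,
                extension = 200, bin_width = 25, p_threshold = 1e-9,
                fold_min = 5, window = 2000),
    expression = list(class_shift_log2 = c(bivalent = 1, active = 0,
                                           unmarked = 0),
                      n_isoforms = 2, noise_sd = 0.1,
                      pseudocount = 1, threshold = 1.5),
    nanostring = list(n_genes = 20, n_samples = 6,
                      groups = c("wt", "wt", "wt", "mut", "mut", "mut"),
                      p_threshold = 0.05, n_iter = 2000),
    frap = list(mf = c(wt = 0.13, mutant = 0.20), k = 0.01, i_dip = 0.5,
                dt = 30, n_frames = 30, noise_sd = 0.01, n_cells = 14,
                tail_window = 3)
  )
}

# which classes a mark is enriched at
.mark_classes <- list(H3K4me3 = c("bivalent", "active"),
                      H3K27me3 = "bivalent",
                      H2AZ = c("bivalent", "active"))

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full synthetic-to-report pipeline
#'
#' Stages run in dependency order (simulate genome, ChIP libraries per
#' mark, enrichment calling, promoter classification, expression
#' integration, NanoString normalization + Monte Carlo FDR, FRAP group
#' comparison); each stage logs to stderr and a run log, each output file
#' begins with a provenance header, and a stage failure halts the run
#' naming the stage. Reruns with the same config are identical.
#'
#' @param config a configuration list (see [default_pipeline_config()]),
#'   or a path to a YAML file with the same structure; supplied fields
#'   override the defaults.
#' @param quiet suppress stderr logging.
#' @return object of class `pipeline_report` (invisibly): class counts
#'   (called vs true), differential-set overlap tests, KS stratification,
#'   NanoString FDR and the FRAP group comparison.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_pipeline_config(), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    writeLines(line, log_con)
    if (!quiet) message(line)
  }
  run_stage <- function(stage, expr) {
    say(stage, "start")
    out <- tryCatch(expr, error = function(e) {
      say(stage, paste("FAILED:", conditionMessage(e)))
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    say(stage, "done")
    out
  }
  seed <- cfg$seed
  prov <- list(master_seed = seed)

  genome <- run_stage("simulate_genome", {
    g <- do.call(gen_genome, c(cfg$genome, list(seed = seed)))
    write_genes_tsv(g, file.path(cfg$outdir, "genes.tsv"), prov)
    g
  })

  eparams <- enrichment_params(extension = cfg$chip$extension,
                               bin_width = cfg$chip$bin_width,
                               p_threshold = cfg$chip$p_threshold,
                               fold_min = cfg$chip$fold_min)
  regions_by_mark <- list()
  for (i in seq_along(cfg$chip$marks)) {
    mk <- cfg$chip$marks[i]
    regions_by_mark[[mk]] <- run_stage(paste0("chip_", mk), {
      fold <- stats::setNames(rep(1, 3), CHROMATIN_CLASSES)
      fold[.mark_classes[[mk]]] <- cfg$chip$enriched_fold
      sp <- sim_params(background_rate = cfg$chip$background_rate,
                       fold = fold, depletion = cfg$chip$depletion,
                       total_reads = cfg$chip$total_reads,
                       seed = seed + 101 * i)
      libs <- gen_chip_reads(genome, sp, mk)
      if (isTRUE(cfg$write_reads)) {
        write_reads_bed(libs$ip,
                        file.path(cfg$outdir, paste0(mk, "_ip.bed")),
                        meta = prov)
        write_reads_bed(libs$input,
                        file.path(cfg$outdir, paste0(mk, "_input.bed")),
                        meta = prov)
      }
      ip_tr <- bin_counts(extend_reads(libs$ip, eparams$extension),
                          eparams$bin_width, label = paste0(mk, "_ip"))
      in_tr <- bin_counts(extend_reads(libs$input, eparams$extension),
                          eparams$bin_width, label = paste0(mk, "_input"))
      regions <- call_enriched(ip_tr, in_tr, eparams)
      write_regions_bed(regions,
                        file.path(cfg$outdir,
                                  paste0("regions_", mk, ".bed")),
                        meta = c(prov, list(mark = mk)))
      regions
    })
  }

  promoters <- run_stage("annotate_promoters", {
    pt <- annotate_promoters(regions_by_mark, genome,
                             window = cfg$chip$window)
    write_table_prov(as.data.frame(pt),
                     file.path(cfg$outdir, "promoters.tsv"), prov)
    pt
  })

  expr_report <- run_stage("expression", {
    iso <- gen_expression(genome,
                          class_shift_log2 =
                            unlist(cfg$expression$class_shift_log2),
                          n_isoforms = cfg$expression$n_isoforms,
                          noise_sd = cfg$expression$noise_sd,
                          seed = seed + 7)
    tss <- sum_by_tss(iso)
    fc <- log2_fold_changes(tss, cfg$expression$pseudocount,
                            classes = promoters)
    write_table_prov(as.data.frame(fc),
                     file.path(cfg$outdir, "fold_changes.tsv"), prov)
    diff_set <- differential_set(fc, cfg$expression$threshold)
    universe <- fc$gene_id
    called_biv <- promoters$gene_id[promoters$class == "bivalent"]
    overlap <- hypergeometric_overlap(diff_set, called_biv, universe)
    ks <- ks_stratified(fc)
    list(n_differential = length(diff_set), overlap = overlap, ks = ks)
  })

  nano <- run_stage("nanostring", {
    cm <- gen_nanostring(n_genes = cfg$nanostring$n_genes,
                         n_samples = cfg$nanostring$n_samples,
                         seed = seed + 11)
    nm <- center_genes(normalize_housekeeping(cm))
    write_counts_csv(cm, file.path(cfg$outdir, "nanostring_counts.csv"),
                     prov)
    write_table_prov(data.frame(gene_id = rownames(nm$values),
                                round(nm$values, 4), check.names = FALSE),
                     file.path(cfg$outdir, "nanostring_normalized.tsv"),
                     prov)
    monte_carlo_fdr(nm, cfg$nanostring$groups,
                    p_threshold = cfg$nanostring$p_threshold,
                    n_iter = cfg$nanostring$n_iter, seed = seed + 13)
  })

  frap_cmp <- run_stage("frap", {
    grp <- lapply(seq_along(cfg$frap$mf), function(i) {
      ps <- frap_sim_params(mf = cfg$frap$mf[[i]], k = cfg$frap$k,
                            i_dip = cfg$frap$i_dip, dt = cfg$frap$dt,
                            n_frames = cfg$frap$n_frames,
                            noise_sd = cfg$frap$noise_sd,
                            seed = seed + 17 * i)
      curves <- gen_frap_curves(ps, cfg$frap$n_cells)
      vapply(curves, function(cv) {
        mobile_fraction(normalize_curve(cv), cfg$frap$tail_window)$mf
      }, numeric(1))
    })
    names(grp) <- names(cfg$frap$mf)
    write_table_prov(data.frame(group = rep(names(grp), lengths(grp)),
                                mf = unlist(grp)),
                     file.path(cfg$outdir, "frap_mobile_fractions.tsv"),
                     prov)
    compare_mobile_fractions(grp[[1]], grp[[2]], labels = names(grp))
  })

  truth <- genome$genes$class
  called <- promoters$class[match(genome$genes$gene_id,
                                  promoters$gene_id)]
  report <- structure(list(
    seed = seed,
    outdir = cfg$outdir,
    class_counts_true = table(factor(truth, CHROMATIN_CLASSES)),
    class_counts_called = table(factor(called, CHROMATIN_CLASSES)),
    confusion = table(true = factor(truth, CHROMATIN_CLASSES),
                      called = factor(called, CHROMATIN_CLASSES)),
    expression = expr_report,
    nanostring_fdr = nano,
    frap = frap_cmp
  ), class = "pipeline_report")
  say("report", sprintf(
    "bivalent called/true = %d/%d; overlap p = %.3g; FRAP p = %.3g",
    report$class_counts_called[["bivalent"]],
    report$class_counts_true[["bivalent"]],
    expr_report$overlap$p, frap_cmp$p))
  report_df <- data.frame(
    key = c("bivalent_true", "bivalent_called", "active_true",
            "active_called", "unmarked_true", "unmarked_called",
            "n_differential", "overlap_log10_p", "nanostring_fdr",
            "frap_t", "frap_p"),
    value = c(report$class_counts_true[["bivalent"]],
              report$class_counts_called[["bivalent"]],
              report$class_counts_true[["active"]],
              report$class_counts_called[["active"]],
              report$class_counts_true[["unmarked"]],
              report$class_counts_called[["unmarked"]],
              expr_report$n_differential,
              expr_report$overlap$log_p / log(10),
              nano$fdr, frap_cmp$t, frap_cmp$p))
  write_table_prov(report_df, file.path(cfg$outdir, "report.tsv"), prov)
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("stemchrom pipeline report (seed", x$seed, ")\n")
  cat("promoter classes (true -> called):\n")
  print(x$confusion)
  cat(sprintf("differential genes: %d; bivalent overlap p = %.3g\n",
              x$expression$n_differential, x$expression$overlap$p))
  cat(sprintf("nanostring null FDR at p<=%.3g: %.3f\n",
              x$nanostring_fdr$p_threshold, x$nanostring_fdr$fdr))
  print(x$frap)
  invisible(x)
}
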