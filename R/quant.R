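# ChIP-qPCR percent-input, qRT-PCR relative expression, and western-blot
# densitometry fold-change arithmetic.

#' ChIP-qPCR percent input
#'
#' `%Input = 2^(Cp(WCE) - Cp(IP)) * %WCE`: the immunoprecipitated signal
#' expressed as a percentage of starting chromatin, from qPCR crossing
#' points of the IP and the whole-cell-extract (WCE) dilution.
#' Vectorised over replicates.
#'
#' @param cp_wce WCE crossing point(s) (cycles, > 0).
#' @param cp_ip IP crossing point(s) (cycles, > 0).
#' @param wce_percent percentage of chromatin the WCE aliquot represents,
#'   in (0, 100].
#' @return percent input (same length as the Cp inputs).
#' @examples
#' percent_input(20, 25, wce_percent = 1)  # 2^-5 = 0.03125 %
#' @export
percent_input <- function(cp_wce, cp_ip, wce_percent = 1) {
  if (any(cp_wce <= 0) || any(cp_ip <= 0))
    stop("Cp values must be positive", call. = FALSE)
  stopifnot_scalar(wce_percent, "wce_percent", 0, 100,
                   strict_lower = TRUE)
  2^(cp_wce - cp_ip) * wce_percent
}

#' Relative expression from target and control Cp values
#'
#' `level = E^(Cp(control) - Cp(target))` with the amplification
#' efficiency `E` fixed at 2 (perfect doubling) by default. Replicate Cp
#' values are aggregated by their mean before exponentiation.
#'
#' @param cp_target target-gene Cp replicates (cycles, > 0).
#' @param cp_control control-gene Cp replicates (cycles, > 0).
#' @param efficiency amplification efficiency per cycle.
#' @return scalar relative expression level.
#' @examples
#' relative_expression(25, 23)            # 2 cycles later -> 0.25
#' relative_expression(c(25, 25.2), c(23, 22.8))
#' @export
relative_expression <- function(cp_target, cp_control, efficiency = 2) {
  if (any(cp_target <= 0) || any(cp_control <= 0))
    stop("Cp values must be positive", call. = FALSE)
  stopifnot_scalar(efficiency, "efficiency", 1, strict_lower = TRUE)
  efficiency^(mean(cp_control) - mean(cp_target))
}

#' Densitometry fold changes between wild-type and mutant band ratios
#'
#' Inputs are transgene/H3 band-signal ratios. Per replicate the fold is
#' `WT ratio / mutant ratio`; the headline average fold is the ratio of
#' means, `mean(WT ratios) / mean(mutant ratios)` (the mean of per-
#' replicate folds is also reported). Display values are rounded to two
#' decimals (round-half-even); full precision is retained.
#'
#' @param wt_ratios wild-type transgene/H3 ratio(s): one shared value or
#'   one per replicate.
#' @param mut_ratios mutant transgene/H3 ratios, one per replicate (> 0).
#' @return object of class `densitometry_fold`: list with
#'   `per_replicate`, `average` (ratio of means), `mean_of_folds`, and
#'   their 2-decimal `*_rounded` companions.
#' @examples
#' densitometry_fold_change(0.439, c(0.255, 0.219))
#' @export
densitometry_fold_change <- function(wt_ratios, mut_ratios) {
  mut_ratios <- unlist(mut_ratios)
  if (!length(mut_ratios)) stop("no mutant replicates", call. = FALSE)
  if (any(wt_ratios <= 0) || any(mut_ratios <= 0))
    stop("band ratios must be positive", call. = FALSE)
  if (!length(wt_ratios) %in% c(1L, length(mut_ratios)))
    stop("`wt_ratios` must be one shared value or one per replicate",
         call. = FALSE)
  wt <- rep_len(wt_ratios, length(mut_ratios))
  per <- wt / mut_ratios
  avg <- mean(wt) / mean(mut_ratios)
  structure(list(per_replicate = per,
                 per_replicate_rounded = round(per, 2),
                 average = avg,
                 average_rounded = round(avg, 2),
                 mean_of_folds = mean(per),
                 mean_of_folds_rounded = round(mean(per), 2)),
            class = "densitometry_fold")
}

#' @export
print.densitometry_fold <- function(x, ...) {
  cat(sprintf("densitometry fold change: per replicate %s; average %.2f\n",
              paste(sprintf("%.2f", x$per_replicate_rounded),
                    collapse = ", "),
              x$average_rounded))
  invisible(x)
}
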