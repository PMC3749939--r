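# FRAP mobile-fraction estimation: curve normalization, the endpoint
# (dip/saturation) estimator, exponential recovery fitting, curve
# averaging and group comparison.

#' Construct a FRAP intensity time course
#'
#' @param time time points (s), strictly increasing.
#' @param intensity intensities (arbitrary units), finite.
#' @param bleach_index index of the first post-bleach frame (the dip);
#'   must be >= 2 so at least one pre-bleach frame exists.
#' @param cell_id cell identifier.
#' @return object of class `frap_curve`.
#' @export
frap_curve <- function(time, intensity, bleach_index, cell_id = "cell") {
  if (length(time) != length(intensity))
    stop("time and intensity differ in length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time points must be strictly increasing", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2 || bleach_index > length(time))
    stop("bleach_index must leave at least one pre-bleach frame",
         call. = FALSE)
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 bleach_index = bleach_index, cell_id = cell_id),
            class = "frap_curve")
}

#' @export
print.frap_curve <- function(x, ...) {
  cat(sprintf("frap_curve '%s': %d frames, bleach at frame %d\n",
              x$cell_id, length(x$time), x$bleach_index))
  invisible(x)
}

#' Normalize a curve to its pre-bleach maximum
#'
#' Divides all intensities by the maximum pre-bleach intensity, so the
#' normalized pre-bleach maximum is 1; idempotent on already-normalized
#' curves.
#'
#' @param raw a `frap_curve`.
#' @return the normalized `frap_curve`.
#' @export
normalize_curve <- function(raw) {
  stopifnot(inherits(raw, "frap_curve"))
  pre_max <- max(raw$intensity[seq_len(raw$bleach_index - 1L)])
  if (pre_max <= 0)
    stop("non-positive pre-bleach maximum: cannot normalize",
         call. = FALSE)
  raw$intensity <- raw$intensity / pre_max
  raw
}

#' Endpoint mobile-fraction estimate
#'
#' `I_dip` is the first post-bleach (dip) intensity and `I_sat` the mean of
#' the last `tail_window` frames; the mobile fraction is
#' `MF = (I_sat - I_dip) / (1 - I_dip)`, the fraction of the bleached
#' deficit recovered by the end of the monitored period. For a finite
#' window the estimate underestimates the true mobile fraction by exactly
#' `MF_true * exp(-k * T_end)` on noiseless single-exponential curves.
#'
#' @param curve a normalized `frap_curve`.
#' @param tail_window number of terminal frames averaged into `I_sat`.
#' @return object of class `mobile_fraction_estimate`: list with `mf`,
#'   `i_dip`, `i_sat`, `cell_id`.
#' @export
mobile_fraction <- function(curve, tail_window = 1) {
  stopifnot(inherits(curve, "frap_curve"))
  stopifnot_scalar(tail_window, "tail_window", 1)
  n_post <- length(curve$intensity) - curve$bleach_index + 1L
  if (n_post < tail_window)
    stop("fewer post-bleach frames than `tail_window`", call. = FALSE)
  i_dip <- curve$intensity[curve$bleach_index]
  if (i_dip >= 1)
    stop("no bleach detected: dip intensity >= pre-bleach level",
         call. = FALSE)
  i_sat <- mean(utils::tail(curve$intensity, tail_window))
  structure(list(mf = (i_sat - i_dip) / (1 - i_dip),
                 i_dip = i_dip, i_sat = i_sat, cell_id = curve$cell_id),
            class = "mobile_fraction_estimate")
}

#' @export
print.mobile_fraction_estimate <- function(x, ...) {
  cat(sprintf("mobile fraction (%s): %.3f  [I_dip %.3f, I_sat %.3f]\n",
              x$cell_id, x$mf, x$i_dip, x$i_sat))
  invisible(x)
}

#' Average recovery curve with per-frame SEM
#'
#' Curves are aligned at the bleach frame; pre-bleach frame counts may
#' differ, in which case the common overlap is averaged. Frame intervals
#' must agree across curves.
#'
#' @param curves list of `frap_curve` objects (n >= 2).
#' @return data.frame with `rel_time` (s, 0 at the bleach frame), `mean`,
#'   `sem`, `n_cells`.
#' @export
mean_recovery_curve <- function(curves) {
  if (length(curves) < 2) stop("need at least 2 curves", call. = FALSE)
  rel <- lapply(curves, function(cv) cv$time - cv$time[cv$bleach_index])
  dt <- unique(unlist(lapply(rel, diff)))
  if (length(unique(round(dt, 9))) != 1)
    stop("curves have inconsistent time grids", call. = FALSE)
  pre <- min(vapply(curves, function(cv) cv$bleach_index - 1L, integer(1)))
  post <- min(vapply(curves,
                     function(cv) length(cv$time) - cv$bleach_index,
                     integer(1)))
  idx_rel <- -pre:post
  mat <- vapply(curves, function(cv) {
    cv$intensity[cv$bleach_index + idx_rel]
  }, numeric(length(idx_rel)))
  data.frame(rel_time = idx_rel * dt[1],
             mean = rowMeans(mat),
             sem = apply(mat, 1, stats::sd) / sqrt(ncol(mat)),
             n_cells = ncol(mat))
}

#' Compare mobile fractions between two groups
#'
#' Standard unpaired equal-variance two-sample t test, two-sided.
#'
#' @param group_a,group_b numeric vectors of mobile fractions, or lists of
#'   `mobile_fraction_estimate` objects (each n >= 2).
#' @param labels group labels for reporting.
#' @return object of class `group_comparison`: list with per-group mean,
#'   SEM and n, plus `t`, `df`, `p`.
#' @export
compare_mobile_fractions <- function(group_a, group_b,
                                     labels = c("A", "B")) {
  as_mf <- function(g) {
    if (is.list(g)) vapply(g, function(e) e$mf, numeric(1)) else g
  }
  a <- as_mf(group_a); b <- as_mf(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 mobile fractions", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("zero pooled variance: t is undefined", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  structure(list(labels = labels,
                 mean = c(mean(a), mean(b)),
                 sem = c(stats::sd(a) / sqrt(length(a)),
                         stats::sd(b) / sqrt(length(b))),
                 n = c(length(a), length(b)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: MF %.3f +/- %.3f (n=%d)  vs  %s: MF %.3f +/- %.3f (n=%d)\n",
    x$labels[1], x$mean[1], x$sem[1], x$n[1],
    x$labels[2], x$mean[2], x$sem[2], x$n[2]))
  cat(sprintf("  t = %.3f, df = %g, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Fit a single-exponential recovery model
#'
#' Least-squares fit of `I(t) = I_dip + A * (1 - exp(-k t))` to the
#' post-bleach segment (`t` measured from the bleach frame);
#' `MF_fit = A / (1 - I_dip)` with the fitted dip. Non-convergence or an
#' unidentifiable rate (flat curve) yields a flagged estimate rather than
#' an error.
#'
#' @param curve a normalized `frap_curve` with >= 5 post-bleach frames.
#' @return list with `mf_fit`, `k`, `i_dip`, `converged` (logical) and
#'   `message` (diagnostic when not converged).
#' @export
fit_recovery <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"))
  b <- curve$bleach_index
  tt <- curve$time[b:length(curve$time)] - curve$time[b]
  y <- curve$intensity[b:length(curve$intensity)]
  if (length(tt) < 5)
    stop("need at least 5 post-bleach frames", call. = FALSE)
  amp0 <- utils::tail(y, 1) - y[1]
  if (abs(amp0) < 1e-6 || stats::sd(y) < 1e-8) {
    return(list(mf_fit = 0, k = NA_real_, i_dip = y[1], converged = FALSE,
                message = "flat recovery: rate constant unidentifiable"))
  }
  # crude rate start: time to reach ~63% of the apparent amplitude
  frac <- (y - y[1]) / amp0
  t63 <- tt[which(frac >= 0.632)[1]]
  k0 <- if (is.na(t63) || t63 <= 0) 1 / max(tt) else 1 / t63
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ d + a * (1 - exp(-k * tt)),
                      start = list(d = y[1], a = amp0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(mf_fit = NA_real_, k = NA_real_, i_dip = y[1],
                converged = FALSE, message = conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  list(mf_fit = unname(cf["a"] / (1 - cf["d"])), k = unname(cf["k"]),
       i_dip = unname(cf["d"]), converged = TRUE, message = "")
}
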