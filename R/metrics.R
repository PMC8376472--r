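# Evaluation metrics: FA-map disagreement, white-matter overlap,
# distortion masks, and paired scalar comparisons.

as_arr3 <- function(x) if (inherits(x, "epi_volume")) x$data else x

#' RMS difference between two FA maps inside a mask
#'
#' `sqrt(mean((FA_up - FA_down)^2))` over the mask voxels only: the
#' residual-misalignment summary used to grade distortion correction —
#' perfectly corrected opposite-polarity data should yield identical FA
#' maps.
#'
#' @param fa_up,fa_down FA maps ([epi_volume()] or array).
#' @param wm_mask a non-empty [epi_mask()].
#' @return RMS difference (numeric scalar).
#' @export
rms_fa_difference <- function(fa_up, fa_down, wm_mask) {
  a <- as_arr3(fa_up); b <- as_arr3(fa_down)
  stopifnot(inherits(wm_mask, "epi_mask"))
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(wm_mask$data)))
    epi_stop("maps and mask must share one grid", "epi_argument_error")
  if (!any(wm_mask$data))
    epi_stop("white-matter mask is empty", "epi_domain_error")
  sqrt(mean((a[wm_mask$data] - b[wm_mask$data])^2))
}

#' White-matter mask from a probability map
#'
#' Strict threshold: voxels with probability strictly above `threshold`.
#'
#' @param prob probability map in `[0, 1]`.
#' @param threshold cut-off; the conventional structural-WM value is 0.9.
#' @return An [epi_mask()].
#' @export
wm_mask_from_prob <- function(prob, threshold = 0.9) {
  p <- as_arr3(prob)
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
    epi_stop("probability map must lie in [0, 1]", "epi_domain_error")
  epi_mask(p > threshold, provenance = sprintf("prob > %g", threshold))
}

#' Mask of high-distortion voxels from a Jacobian map
#'
#' Two-sided deviation from unity: `|jac - 1| > deviation`, capturing both
#' squeezed (< 1) and stretched (> 1) tissue. Masks at increasing
#' deviations are nested.
#'
#' @param jac Jacobian map ([epi_volume()] or array), values > 0.
#' @param deviation deviation threshold, e.g. 0.10, 0.20, 0.30.
#' @return An [epi_mask()].
#' @export
distortion_mask <- function(jac, deviation) {
  j <- as_arr3(jac)
  if (min(j) <= 0)
    epi_stop("Jacobian map must be positive", "epi_domain_error")
  epi_mask(abs(j - 1) > deviation,
           provenance = sprintf("|jac - 1| > %g", deviation))
}

#' Percentage overlap of two probability maps
#'
#' Both maps are binarized at `binarize_at`, optionally restricted to a
#' region, and compared. `definition = "coverage"` (the default) reports
#' how much of the structural map the diffusion map covers,
#' `100 * |D & S| / |S|`; `"dice"` and `"jaccard"` are the symmetric
#' alternatives.
#'
#' @param prob_diff diffusion-derived WM probability map.
#' @param prob_struct structural WM probability map (the reference).
#' @param region optional [epi_mask()] restriction.
#' @param definition `"coverage"`, `"dice"` or `"jaccard"`.
#' @param binarize_at binarization threshold.
#' @return Overlap percentage (numeric scalar).
#' @export
overlap_percent <- function(prob_diff, prob_struct, region = NULL,
                            definition = c("coverage", "dice", "jaccard"),
                            binarize_at = 0.5) {
  definition <- match.arg(definition)
  D <- as_arr3(prob_diff) > binarize_at
  S <- as_arr3(prob_struct) > binarize_at
  if (!all(dim(D) == dim(S)))
    epi_stop("maps must share one grid", "epi_argument_error")
  if (!is.null(region)) {
    stopifnot(inherits(region, "epi_mask"))
    D <- D & region$data
    S <- S & region$data
  }
  inter <- sum(D & S)
  val <- switch(definition,
    coverage = {
      if (sum(S) == 0)
        epi_stop("structural map is empty in the region", "epi_domain_error")
      100 * inter / sum(S)
    },
    dice = {
      if (sum(D) + sum(S) == 0)
        epi_stop("both maps empty in the region", "epi_domain_error")
      100 * 2 * inter / (sum(D) + sum(S))
    },
    jaccard = {
      un <- sum(D | S)
      if (un == 0)
        epi_stop("both maps empty in the region", "epi_domain_error")
      100 * inter / un
    })
  val
}

#' Paired comparison of two scalar samples
#'
#' Two-tailed paired t-test plus the repeated-measures standardized effect
#' size: `d_av = mean(a - b) / ((sd(a) + sd(b)) / 2)`, bias-corrected to
#' Hedges `g_av = d_av * (1 - 3 / (4 (n - 1) - 1))`. When the paired
#' differences have zero variance the t statistic is undefined: `t` and
#' `p` are returned as `NA` with a classed warning, while the mean
#' difference and effect sizes are still reported.
#'
#' @param a,b numeric vectors of equal length >= 2 (pairs).
#' @return An object of class `paired_comparison` with fields `n`,
#'   `mean_diff`, `t_stat`, `p_two_tailed`, `d_av`, `hedges_g_av`.
#' @export
paired_compare <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    epi_stop("paired samples must have equal length >= 2",
             "epi_argument_error")
  n <- length(a)
  d <- a - b
  mean_diff <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    epi_warn("zero variance of paired differences: t statistic undefined",
             "epi_degenerate_variance")
    t_stat <- NA_real_
    p <- NA_real_
  } else {
    t_stat <- mean_diff / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  sd_sum <- stats::sd(a) + stats::sd(b)
  if (sd_sum == 0) {
    epi_warn("zero variance in both samples: effect size undefined",
             "epi_degenerate_variance")
    d_av <- NA_real_
  } else {
    d_av <- mean_diff / (sd_sum / 2)
  }
  g_av <- d_av * (1 - 3 / (4 * (n - 1) - 1))
  structure(list(n = n, mean_diff = mean_diff, t_stat = t_stat,
                 p_two_tailed = p, d_av = d_av, hedges_g_av = g_av),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison> n = %d, mean diff = %.4g, t = %.4g, p = %.4g, Hedges g_av = %.4g\n",
    x$n, x$mean_diff, x$t_stat, x$p_two_tailed, x$hedges_g_av))
  invisible(x)
}

#' Summarize combination methods on one phantom run
#'
#' Convenience table builder: RMS b0 error against ground truth and WM
#' overlap percentages inside distortion masks, one row per combination
#' method and deviation threshold.
#'
#' @param results named list of combined-series WM probability
#'   [epi_volume()]s (e.g. `list(am = ..., wa = ...)`).
#' @param prob_struct structural WM probability map.
#' @param jac Jacobian map used to derive the distortion masks.
#' @param deviations deviation thresholds.
#' @param definition overlap definition passed to [overlap_percent()].
#' @return A data.frame with columns `method`, `deviation`, `overlap`.
#' @export
overlap_table <- function(results, prob_struct, jac,
                          deviations = c(0.10, 0.20, 0.30),
                          definition = "coverage") {
  rows <- list()
  for (m in names(results)) {
    for (dev in c(0, deviations)) {
      region <- if (dev == 0) NULL else distortion_mask(jac, dev)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, deviation = dev,
        overlap = overlap_percent(results[[m]], prob_struct, region,
                                  definition = definition))
    }
  }
  do.call(rbind, rows)
}
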