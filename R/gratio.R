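# MR g-ratio mapping. The aggregate MR g-ratio of a voxel is
# g = sqrt(1 - MVF / (MVF + AVF)), with the myelin-volume fraction taken
# proportional to MT saturation (MVF = alpha * MTsat), the axonal-volume
# fraction AVF = (1 - MVF) * AWF, and the axonal-water fraction combined
# from the NODDI-style compartment maps as AWF = (1 - v_iso) * v_icvf.

#' Axonal water fraction from compartment fraction maps
#'
#' `AWF = (1 - v_iso) * v_icvf`, the water fraction attributable to axons
#' once the free-water (isotropic) compartment is removed.
#'
#' @param v_icvf intracellular volume fraction map ([epi_volume()] or
#'   array), values in `[0, 1]`.
#' @param v_iso isotropic (free-water) fraction map, values in `[0, 1]`.
#' @return An [epi_volume()] with values in `[0, 1]`.
#' @export
compute_awf <- function(v_icvf, v_iso) {
  icvf <- if (inherits(v_icvf, "epi_volume")) v_icvf$data else v_icvf
  iso <- if (inherits(v_iso, "epi_volume")) v_iso$data else v_iso
  if (min(icvf) < -1e-9 || max(icvf) > 1 + 1e-9 ||
      min(iso) < -1e-9 || max(iso) > 1 + 1e-9)
    epi_stop("compartment fractions must lie in [0, 1]", "epi_domain_error")
  vs <- if (inherits(v_icvf, "epi_volume")) v_icvf$voxel_size else c(1, 1, 1)
  epi_volume((1 - iso) * icvf, voxel_size = vs)
}

#' Inputs for g-ratio mapping
#'
#' Bundles the structural and diffusion-derived maps entering the g-ratio
#' computation. The default `alpha = 0.217` is a published dataset-specific
#' calibration constant, kept as a documented fallback; recalibrate with
#' [calibrate_alpha()] whenever a reference region is available.
#'
#' @param mt_sat MT saturation map (percent units), [epi_volume()].
#' @param v_icvf,v_iso compartment fraction maps in `[0, 1]`.
#' @param wm_mask_struct structural white-matter mask ([epi_mask()]).
#' @param wm_mask_diff diffusion-derived white-matter mask.
#' @param reference_mask calibration reference region (deep-WM block
#'   standing in for the splenium).
#' @param alpha myelin-volume fraction per MT saturation unit, > 0.
#' @return An object of class `gratio_inputs`.
#' @export
gratio_inputs <- function(mt_sat, v_icvf, v_iso, wm_mask_struct,
                          wm_mask_diff, reference_mask = NULL,
                          alpha = 0.217) {
  stopifnot(inherits(mt_sat, "epi_volume"),
            inherits(wm_mask_struct, "epi_mask"),
            inherits(wm_mask_diff, "epi_mask"))
  if (alpha <= 0)
    epi_stop("alpha must be > 0", "epi_calibration_error")
  d <- dim(mt_sat$data)
  for (m in list(wm_mask_struct, wm_mask_diff)) {
    if (!all(dim(m$data) == d))
      epi_stop("masks must share the map grid", "epi_argument_error")
  }
  mt_wm <- mt_sat$data[wm_mask_struct$data]
  if (length(mt_wm) > 0 && alpha * max(mt_wm) >= 1)
    epi_stop(sprintf(
      "alpha = %.4f puts MVF >= 1 inside the structural WM mask (max MTsat %.3f)",
      alpha, max(mt_wm)), "epi_calibration_error")
  structure(list(mt_sat = mt_sat, v_icvf = v_icvf, v_iso = v_iso,
                 wm_mask_struct = wm_mask_struct,
                 wm_mask_diff = wm_mask_diff,
                 reference_mask = reference_mask, alpha = alpha),
            class = "gratio_inputs")
}

#' Compute the MR g-ratio map
#'
#' Voxelwise: `MVF = alpha * MTsat`, `AVF = (1 - MVF) * AWF`,
#' `g = sqrt(1 - MVF / (MVF + AVF))` on the defined domain — the
#' intersection of the structural and diffusion white-matter masks where
#' `MVF + AVF > 0`. The g-ratio cannot be computed where the two tissue
#' maps disagree, and a value of exactly zero is recorded there (and
#' everywhere outside the defined domain); such zero-filled voxels drag
#' region averages down, which is precisely the blurring footprint the
#' weighted combination is designed to shrink.
#'
#' @param inputs a [gratio_inputs()].
#' @return An object of class `gratio_map` with [epi_volume()] fields `g`,
#'   `mvf`, `avf`, `awf` and an [epi_mask()] `defined_mask`.
#' @export
gratio_map <- function(inputs) {
  stopifnot(inherits(inputs, "gratio_inputs"))
  mt <- inputs$mt_sat$data
  awf <- compute_awf(inputs$v_icvf, inputs$v_iso)$data
  mvf <- inputs$alpha * mt
  wm_s <- inputs$wm_mask_struct$data
  if (any(mvf[wm_s] >= 1))
    epi_stop("alpha puts MVF >= 1 inside the structural WM mask",
             "epi_calibration_error")
  avf <- (1 - mvf) * awf
  den <- mvf + avf
  defined <- wm_s & inputs$wm_mask_diff$data & (den > 0)
  g <- array(0, dim(mt))
  g[defined] <- sqrt(pmax(1 - mvf[defined] / den[defined], 0))
  vs <- inputs$mt_sat$voxel_size
  structure(list(
    g = epi_volume(g, vs),
    mvf = epi_volume(mvf, vs),
    avf = epi_volume(avf, vs),
    awf = epi_volume(awf, vs),
    defined_mask = epi_mask(defined, "wm_struct & wm_diff & MVF+AVF>0")),
    class = "gratio_map")
}

#' @export
print.gratio_map <- function(x, ...) {
  def <- x$g$data[x$defined_mask$data]
  cat("<gratio_map> ", sum(x$defined_mask$data), " defined voxels, mean g ",
      signif(mean(def), 4), "\n", sep = "")
  invisible(x)
}

mean_ref_g <- function(alpha, mt, awf) {
  mvf <- alpha * mt
  avf <- (1 - mvf) * awf
  den <- mvf + avf
  g <- ifelse(den > 0, sqrt(pmax(1 - mvf / den, 0)), 0)
  mean(g)
}

#' Calibrate the MT-saturation-to-myelin scaling factor
#'
#' Finds `alpha` such that the mean voxelwise g-ratio over the reference
#' region equals `target_g`, by bisection on
#' `(0, 0.99 / max(MTsat in region))`. The mean reference g-ratio is
#' strictly decreasing in `alpha` (more myelin per MT unit means a thicker
#' sheath everywhere), so the root is unique when it exists.
#'
#' @param mt_sat MT saturation map ([epi_volume()] or array).
#' @param awf axonal water fraction map.
#' @param reference_mask [epi_mask()] of the reference region.
#' @param target_g reference g-ratio the region mean should attain.
#' @param tol tolerance on the mean g-ratio.
#' @return The calibrated `alpha` (numeric scalar).
#' @export
calibrate_alpha <- function(mt_sat, awf, reference_mask, target_g = 0.7,
                            tol = 1e-6) {
  mt_arr <- if (inherits(mt_sat, "epi_volume")) mt_sat$data else mt_sat
  awf_arr <- if (inherits(awf, "epi_volume")) awf$data else awf
  stopifnot(inherits(reference_mask, "epi_mask"))
  sel <- reference_mask$data
  if (!any(sel))
    epi_stop("reference mask is empty", "epi_calibration_error")
  mt <- mt_arr[sel]
  w <- awf_arr[sel]
  if (mean(mt) <= 0 || mean(w) <= 0)
    epi_stop("reference region needs positive mean MTsat and AWF",
             "epi_calibration_error")
  hi <- 0.99 / max(mt)
  lo <- 0
  g_hi <- mean_ref_g(hi, mt, w)
  g_lo <- mean_ref_g(1e-12, mt, w)
  if (target_g > g_lo || target_g < g_hi)
    epi_stop(sprintf(
      "target g-ratio %.3f unreachable: attainable range is (%.4f, %.4f)",
      target_g, g_hi, g_lo), "epi_calibration_error")
  mid <- (lo + hi) / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    gm <- mean_ref_g(mid, mt, w)
    if (abs(gm - target_g) <= tol) break
    if (gm > target_g) lo <- mid else hi <- mid
  }
  mid
}

#' Mean g-ratio of a region across maps
#'
#' Averages g over the region voxels for each map, then across maps. With
#' `include_zeros = TRUE` (the reporting convention for these maps)
#' zero-filled voxels — where the g-ratio was undefined — count toward the
#' mean and drag it down; with `FALSE` they are dropped first.
#'
#' @param g_maps a [gratio_map()] or list of them.
#' @param region an [epi_mask()].
#' @param include_zeros count zero-filled voxels?
#' @return The group mean g-ratio (numeric scalar).
#' @export
group_mean_gratio <- function(g_maps, region, include_zeros = TRUE) {
  if (inherits(g_maps, "gratio_map")) g_maps <- list(g_maps)
  stopifnot(inherits(region, "epi_mask"))
  if (!any(region$data))
    epi_stop("region mask is empty", "epi_domain_error")
  per_map <- vapply(g_maps, function(gm) {
    stopifnot(inherits(gm, "gratio_map"))
    v <- gm$g$data[region$data]
    if (!include_zeros) v <- v[v != 0]
    mean(v)
  }, numeric(1))
  mean(per_map)
}
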