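#' Susceptibility field map
#'
#' Per-voxel displacement along the phase-encoding (PE) axis caused by B0
#' inhomogeneity, stored in mm and parametrized on the object (corrected)
#' grid: `b` at a voxel is the displacement of the tissue that belongs at
#' that anatomical position, which is why a single field serves both
#' polarities. Blip-up acquisitions displace tissue toward increasing PE
#' index by `+b`, blip-down by `-b`. Conversion to voxel units always
#' uses `voxel_size[pe_axis]`.
#'
#' @param b_mm 3-D numeric array of displacements in mm along the PE axis.
#' @param pe_axis phase-encoding axis (1, 2 or 3).
#' @param voxel_size voxel edge lengths in mm.
#' @return An object of class `field_map`.
#' @export
field_map <- function(b_mm, pe_axis, voxel_size = c(1, 1, 1)) {
  if (!is.array(b_mm) || length(dim(b_mm)) != 3L)
    epi_stop("field data must be a 3-D array", "epi_argument_error")
  if (any(!is.finite(b_mm)))
    epi_stop("field map must be finite everywhere", "epi_argument_error")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  pe_axis <- as.integer(pe_axis)
  if (!pe_axis %in% 1:3)
    epi_stop("pe_axis must be 1, 2 or 3", "epi_argument_error")
  structure(list(b_mm = b_mm, pe_axis = pe_axis,
                 voxel_size = as.numeric(voxel_size)),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat("<field_map> ", paste(dim(x$b_mm), collapse = " x "),
      " voxels, PE axis ", x$pe_axis, ", |b| max ",
      signif(max(abs(x$b_mm)), 4), " mm\n", sep = "")
  invisible(x)
}

field_vox <- function(field) field$b_mm / field$voxel_size[field$pe_axis]

#' Jacobian intensity-modulation maps of a field
#'
#' The blip-up Jacobian is `1 + db/dp` with the derivative of the field
#' (converted to voxel units) taken along the PE axis — central differences
#' in the interior, one-sided at the boundary slices. The blip-down
#' Jacobian is computed literally as `2 - jac_up`, so the pair sums to 2
#' exactly at every voxel. A value above 1 means that polarity sampled
#' the local tissue stretched over more acquired voxels
#' (information-preserving, intensity diluted); below 1 it was squeezed
#' (information-losing, signal pile-up). The maps live on the object
#' grid, the space where corrected images are combined.
#'
#' @param field a [field_map()].
#' @return An object of class `jacobian_pair` with elements `jac_up` and
#'   `jac_down` (3-D arrays) and `pe_axis`.
#' @export
jacobians <- function(field) {
  stopifnot(inherits(field, "field_map"))
  d <- axis_deriv(field_vox(field), field$pe_axis)
  jac_up <- 1 + d
  jac_down <- 2 - jac_up
  worst <- min(jac_up, jac_down)
  if (worst <= 0) {
    idx <- arrayInd(which.min(pmin(jac_up, jac_down)), dim(jac_up))
    epi_stop(sprintf(
      "field is not invertible: Jacobian %.4f <= 0 at voxel (%d, %d, %d)",
      worst, idx[1], idx[2], idx[3]), "epi_invertibility_error")
  }
  structure(list(jac_up = jac_up, jac_down = jac_down,
                 pe_axis = field$pe_axis),
            class = "jacobian_pair")
}

#' @export
print.jacobian_pair <- function(x, ...) {
  cat("<jacobian_pair> jac_up in [", signif(min(x$jac_up), 4), ", ",
      signif(max(x$jac_up), 4), "], PE axis ", x$pe_axis, "\n", sep = "")
  invisible(x)
}

polarity_sign <- function(polarity) {
  polarity <- match.arg(polarity, c("up", "down"))
  if (polarity == "up") 1 else -1
}

# Core sampler: pull back a 3-D array through the map x -> x + sign*b(x)
# along pe_axis (linear interpolation, edge clamp), optionally multiplied
# by the Jacobian 1 + sign*db/dp.
distort_array <- function(arr, b_vox, pe_axis, sign, modulate) {
  p <- perm_to_front(arr, pe_axis)
  pb <- perm_to_front(b_vox, pe_axis)$arr
  n <- dim(p$arr)[1]
  m <- matrix(p$arr, nrow = n)
  bm <- matrix(pb, nrow = n)
  pos <- matrix(rep(seq_len(n), ncol(m)), nrow = n) + sign * bm
  out <- sample_columns_linear(m, pos)
  if (modulate) {
    d <- axis_deriv(b_vox, pe_axis)
    jac <- 1 + sign * matrix(perm_to_front(d, pe_axis)$arr, nrow = n)
    out <- out * jac
  }
  dim(out) <- dim(p$arr)
  perm_back(out, p$inverse)
}

# Core inverse warp: invert the monotone per-column map
# t(x) = x + sign*b(x) and sample `arr/jac` at the inverse — equivalently,
# interpolate the points (t[i], arr[i]/jac[i]) at the integer grid. The
# division makes the operator the exact mass-conserving inverse of
# distort_array. With divide = FALSE the intensities are left untouched
# (pure geometric resampling).
unwarp_array <- function(arr, b_vox, pe_axis, sign, jac_floor = 0.05,
                         divide = TRUE) {
  d <- axis_deriv(b_vox, pe_axis)
  jac <- 1 + sign * d
  worst <- min(jac)
  if (worst < jac_floor) {
    idx <- arrayInd(which.min(jac), dim(jac))
    epi_stop(sprintf(
      "cannot unwarp: Jacobian %.4f below %.2f at voxel (%d, %d, %d)",
      worst, jac_floor, idx[1], idx[2], idx[3]), "epi_invertibility_error")
  }
  p <- perm_to_front(arr, pe_axis)
  n <- dim(p$arr)[1]
  m <- matrix(p$arr, nrow = n)
  bm <- matrix(perm_to_front(b_vox, pe_axis)$arr, nrow = n)
  jm <- matrix(perm_to_front(jac, pe_axis)$arr, nrow = n)
  t <- matrix(rep(seq_len(n), ncol(m)), nrow = n) + sign * bm
  out <- invert_columns_linear(t, if (divide) m / jm else m)
  dim(out) <- dim(p$arr)
  perm_back(out, p$inverse)
}

#' Warp a volume through the distortion field (direct sampling)
#'
#' The output at voxel `x` is the input sampled (linear interpolation,
#' edge clamp) at `x + s * b(x) / voxel_size` along the PE axis, where
#' `s = +1` for blip-up and `-1` for blip-down; with `modulate = TRUE`
#' the sampled value is multiplied by the polarity's Jacobian. Applied to
#' an acquired EPI volume with the field that distorted it, this is the
#' distortion *correction*: it gathers each anatomical voxel's signal
#' from its displaced acquired position and undoes the pile-up/dilution
#' intensity modulation. It is the exact inverse of [unwarp()].
#'
#' @param vol an [epi_volume()].
#' @param field a [field_map()] on the same grid.
#' @param polarity `"up"` or `"down"`.
#' @param modulate multiply by the Jacobian intensity modulation?
#' @return The warped [epi_volume()].
#' @export
apply_distortion <- function(vol, field, polarity, modulate = TRUE) {
  stopifnot(inherits(vol, "epi_volume"), inherits(field, "field_map"))
  if (identical(polarity, "combined"))
    epi_stop("polarity must be 'up' or 'down', not 'combined'",
             "epi_argument_error")
  s <- polarity_sign(polarity)
  if (!all(dim(vol$data) == dim(field$b_mm)))
    epi_stop("volume and field grids differ", "epi_argument_error")
  out <- distort_array(vol$data, field_vox(field), field$pe_axis, s,
                       modulate)
  epi_volume(out, voxel_size = vol$voxel_size, pe_axis = field$pe_axis)
}

#' Warp a volume through the inverse of the distortion field
#'
#' Per PE column the monotone 1-D map `t(x) = x + s * b(x) / voxel_size`
#' is inverted by piecewise-linear root finding, and the input — divided
#' by the polarity's Jacobian — is sampled at the inverse. This is the
#' mass-conserving pushforward: applied to an undistorted object it
#' synthesizes the acquisition that polarity would record (squeezed
#' regions pile up signal, stretched regions dilute it), and
#' `apply_distortion(unwarp(I)) == I` up to interpolation error.
#'
#' @inheritParams apply_distortion
#' @param jac_floor smallest admissible Jacobian; below this the 1-D map
#'   is treated as numerically non-invertible.
#' @return The warped [epi_volume()].
#' @export
unwarp <- function(vol, field, polarity, jac_floor = 0.05) {
  stopifnot(inherits(vol, "epi_volume"), inherits(field, "field_map"))
  if (identical(polarity, "combined"))
    epi_stop("polarity must be 'up' or 'down', not 'combined'",
             "epi_argument_error")
  s <- polarity_sign(polarity)
  if (!all(dim(vol$data) == dim(field$b_mm)))
    epi_stop("volume and field grids differ", "epi_argument_error")
  out <- unwarp_array(vol$data, field_vox(field), field$pe_axis, s,
                      jac_floor)
  epi_volume(out, voxel_size = vol$voxel_size, pe_axis = field$pe_axis)
}

#' Correct every volume of an acquired series
#'
#' Applies the distortion correction ([apply_distortion()] with
#' modulation) volume-wise: each anatomical voxel gathers its signal from
#' the displaced acquired position and the Jacobian undoes the intensity
#' modulation.
#'
#' @param series an [epi_series()].
#' @param field a [field_map()].
#' @param polarity `"up"` or `"down"`; defaults to the series polarity.
#' @return The corrected [epi_series()] (polarity label preserved).
#' @export
correct_series <- function(series, field, polarity = series$polarity) {
  stopifnot(inherits(series, "epi_series"))
  s <- polarity_sign(polarity)
  b_vox <- field_vox(field)
  out <- series$data
  for (q in seq_len(dim(series$data)[4])) {
    out[, , , q] <- distort_array(series$data[, , , q], b_vox,
                                  field$pe_axis, s, modulate = TRUE)
  }
  epi_series(out, series$bvals, series$bvecs, polarity = series$polarity,
             pe_axis = series$pe_axis, voxel_size = series$voxel_size)
}

#' Warp every volume of a series through the inverse map
#'
#' Volume-wise [unwarp()]; the pushforward counterpart of
#' [correct_series()], used e.g. to synthesize distorted acquisitions
#' from an undistorted series.
#'
#' @inheritParams correct_series
#' @param jac_floor smallest admissible Jacobian.
#' @return The warped [epi_series()].
#' @export
unwarp_series <- function(series, field, polarity = series$polarity,
                          jac_floor = 0.05) {
  stopifnot(inherits(series, "epi_series"))
  s <- polarity_sign(polarity)
  b_vox <- field_vox(field)
  out <- series$data
  for (q in seq_len(dim(series$data)[4])) {
    out[, , , q] <- unwarp_array(series$data[, , , q], b_vox,
                                 field$pe_axis, s, jac_floor)
  }
  epi_series(out, series$bvals, series$bvecs, polarity = series$polarity,
             pe_axis = series$pe_axis, voxel_size = series$voxel_size)
}
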