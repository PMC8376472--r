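#' Fermi weighting parameters
#'
#' Parameters of the Fermi function used to turn a Jacobian value into a
#' combination weight. `x0` is the Jacobian offset at which the weight
#' equals 1 (equal weighting); `k0` sets the steepness of the transition.
#' The defaults `x0 = 1, k0 = 10` give equal weighting at unit Jacobian and
#' shift the weights to roughly 88/12 at a 20% Jacobian deviation; both are
#' deliberately configurable since no canonical values exist.
#'
#' @param x0 dimensionless Jacobian offset.
#' @param k0 steepness, dimensionless, must be > 0.
#' @return An object of class `fermi_params`.
#' @export
fermi_params <- function(x0 = 1.0, k0 = 10.0) {
  if (!is.finite(x0) || !is.finite(k0) || k0 <= 0)
    epi_stop("fermi parameters require finite x0 and k0 > 0",
             "epi_argument_error")
  structure(list(x0 = x0, k0 = k0), class = "fermi_params")
}

#' @export
print.fermi_params <- function(x, ...) {
  cat("<fermi_params> x0 =", x$x0, ", k0 =", x$k0, "\n")
  invisible(x)
}

#' Fermi weight of a Jacobian value
#'
#' `f(x) = 2 - 2 / (exp((|x| - x0) * k0) + 1)`: a logistic ramp from 0 to 2
#' that is strictly increasing in `|x|` and equals 1 at `|x| = x0`. Applied
#' to the Jacobian of the distortion field it up-weights locally stretched
#' voxels (Jacobian above 1) and down-weights squeezed ones. The absolute
#' value is retained even though Jacobians are positive by construction.
#'
#' @param x Jacobian value(s); any numeric array.
#' @param params a [fermi_params()].
#' @return Weights in `[0, 2)` with the shape of `x`.
#' @export
fermi_weight <- function(x, params = fermi_params()) {
  stopifnot(inherits(params, "fermi_params"))
  2 - 2 / (exp((abs(x) - params$x0) * params$k0) + 1)
}

#' Arithmetic mean of two volumes
#'
#' The conventional combination of corrected blip-up and blip-down images:
#' the voxelwise average. Blurs wherever one polarity was squeezed.
#'
#' @param s_up,s_down [epi_volume()]s on the same grid.
#' @return The voxelwise mean as an [epi_volume()].
#' @export
arithmetic_mean <- function(s_up, s_down) {
  stopifnot(inherits(s_up, "epi_volume"), inherits(s_down, "epi_volume"))
  if (!all(dim(s_up$data) == dim(s_down$data)))
    epi_stop("input volumes have different shapes", "epi_argument_error")
  epi_volume((s_up$data + s_down$data) / 2, voxel_size = s_up$voxel_size,
             pe_axis = s_up$pe_axis)
}

#' Jacobian-weighted average of a corrected image pair
#'
#' Per voxel, `S = (S_up * f(Jac_up) + S_down * f(Jac_down)) /
#' (f(Jac_up) + f(Jac_down))` with `f` the Fermi weight: the polarity that
#' was locally stretched (higher effective resolution) dominates, reducing
#' the blurring that a plain average inherits from the squeezed polarity.
#' The output is a convex combination, so it is bounded voxelwise by the
#' two inputs, and it equals the arithmetic mean wherever the Jacobians
#' are 1. Both inputs must already be unwarped into the common corrected
#' space; the Jacobians should come from the same (first-pass) field used
#' for correction.
#'
#' @param s_up,s_down corrected [epi_volume()]s on the same grid.
#' @param jac a [jacobian_pair()].
#' @param params a [fermi_params()].
#' @return The combined [epi_volume()].
#' @export
weighted_average <- function(s_up, s_down, jac, params = fermi_params()) {
  stopifnot(inherits(s_up, "epi_volume"), inherits(s_down, "epi_volume"),
            inherits(jac, "jacobian_pair"))
  if (!all(dim(s_up$data) == dim(s_down$data)) ||
      !all(dim(s_up$data) == dim(jac$jac_up)))
    epi_stop("volumes and Jacobians must share one grid",
             "epi_argument_error")
  fu <- fermi_weight(jac$jac_up, params)
  fd <- fermi_weight(jac$jac_down, params)
  den <- fu + fd
  if (min(den) < 1e-12)
    epi_stop("degenerate weights: f(Jac_up) + f(Jac_down) ~ 0",
             "epi_degenerate_weight_error")
  epi_volume((s_up$data * fu + s_down$data * fd) / den,
             voxel_size = s_up$voxel_size, pe_axis = s_up$pe_axis)
}

#' Combine corrected opposite-polarity series
#'
#' Applies the chosen per-volume combination — arithmetic mean (`"am"`) or
#' Fermi-weighted average (`"wa"`) — to every volume of a corrected
#' blip-up/blip-down pair. The two protocols must match volume-by-volume
#' (b-values within 1 s/mm^2, directions within 1 degree). The same
#' Jacobian pair, from the first-pass field estimate, weights every volume.
#'
#' @param up,down corrected [epi_series()]s with polarities `"up"` and
#'   `"down"`.
#' @param jac a [jacobian_pair()] from the first-pass field (required for
#'   `method = "wa"`).
#' @param method `"am"` or `"wa"`.
#' @param params a [fermi_params()].
#' @return An [epi_series()] with polarity `"combined"`.
#' @export
combine_series <- function(up, down, jac = NULL, method = c("wa", "am"),
                           params = fermi_params()) {
  stopifnot(inherits(up, "epi_series"), inherits(down, "epi_series"))
  method <- match.arg(method)
  if (!all(dim(up$data) == dim(down$data)))
    epi_stop("series shapes differ", "epi_argument_error")
  db <- abs(up$bvals - down$bvals)
  cosang <- pmin(abs(colSums(up$bvecs * down$bvecs)), 1)
  ang <- ifelse(up$bvals > 0 & down$bvals > 0, acos(cosang) * 180 / pi, 0)
  bad <- which(db > 1 | ang > 1)
  if (length(bad) > 0)
    epi_stop(sprintf(
      "protocols do not pair volume-by-volume (unmatched volumes: %s)",
      paste(bad, collapse = ", ")), "epi_pairing_error")
  if (method == "wa" && is.null(jac))
    epi_stop("method 'wa' requires a jacobian_pair", "epi_argument_error")
  out <- up$data
  for (q in seq_len(dim(up$data)[4])) {
    su <- series_volume(up, q)
    sd_ <- series_volume(down, q)
    v <- if (method == "am") arithmetic_mean(su, sd_)
         else weighted_average(su, sd_, jac, params)
    out[, , , q] <- v$data
  }
  epi_series(out, up$bvals, up$bvecs, polarity = "combined",
             pe_axis = up$pe_axis, voxel_size = up$voxel_size)
}
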