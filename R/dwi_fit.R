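# Diffusion tensor fitting and derived maps.
#
# The log-linear model per voxel is ln S = ln S0 - b g' D g; the optional
# "dki-linear" design appends the 15 unique fourth-order direction monomials
# b^2 g_i g_j g_k g_l (with permutation multiplicities) as extra regressors,
# which absorbs kurtosis-like signal curvature across shells while keeping
# the fit linear. FA is computed from the tensor eigenvalues.

# Unique symmetric index quadruples (i<=j<=k<=l) with permutation counts.
kurtosis_terms <- function() {
  combs <- list()
  for (i in 1:3) for (j in i:3) for (k in j:3) for (l in k:3)
    combs[[length(combs) + 1L]] <- c(i, j, k, l)
  mult <- vapply(combs, function(q) {
    tab <- tabulate(q, 3)
    factorial(4) / prod(factorial(tab))
  }, numeric(1))
  list(idx = combs, mult = mult)
}

dwi_design_matrix <- function(bvals, bvecs, model = c("dti", "dki-linear")) {
  model <- match.arg(model)
  b <- bvals
  g <- bvecs
  X <- cbind(1,
             -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ],
             -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])
  if (model == "dki-linear") {
    kt <- kurtosis_terms()
    K <- vapply(seq_along(kt$idx), function(m) {
      q <- kt$idx[[m]]
      kt$mult[m] * (b^2 / 6) * g[q[1], ] * g[q[2], ] * g[q[3], ] * g[q[4], ]
    }, numeric(length(b)))
    X <- cbind(X, K)
  }
  X
}

# Vectorized eigenvalues of symmetric 3x3 matrices given the six unique
# entries as columns (xx, yy, zz, xy, xz, yz); rows sorted descending.
sym3_eigenvalues <- function(D) {
  a11 <- D[, 1]; a22 <- D[, 2]; a33 <- D[, 3]
  a12 <- D[, 4]; a13 <- D[, 5]; a23 <- D[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 0
  b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
  b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  l1[!ok] <- q[!ok]; l2[!ok] <- q[!ok]; l3[!ok] <- q[!ok]
  cbind(l1, l2, l3)
}

#' Fractional anisotropy of eigenvalue triples
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`. Negative
#' eigenvalues are clipped to zero before the computation, which keeps FA
#' in `[0, 1]` for noisy fits.
#'
#' @param eigs matrix with three eigenvalue columns.
#' @return FA values in `[0, 1]`.
#' @export
fa_from_eigenvalues <- function(eigs) {
  eigs <- pmax(eigs, 0)
  lbar <- rowMeans(eigs)
  num <- sqrt((eigs[, 1] - lbar)^2 + (eigs[, 2] - lbar)^2 +
                (eigs[, 3] - lbar)^2)
  den <- sqrt(rowSums(eigs^2))
  fa <- sqrt(1.5) * num / den
  fa[den == 0] <- 0
  pmin(pmax(fa, 0), 1)
}

#' Fit the diffusion tensor model to a series
#'
#' Log-linear least squares per voxel within the mask. `model = "dti"`
#' needs at least 7 volumes with 6 or more unique gradient directions;
#' `"dki-linear"` needs at least 22 volumes and two shells. Signals are
#' floored at 1e-6 of the robust maximum before the log. The tensor record
#' keeps the unclipped least-squares values; eigenvalues are clipped at
#' zero only for the FA map.
#'
#' @param series an [epi_series()].
#' @param mask an [epi_mask()] restricting the fit, or `NULL` for all
#'   voxels.
#' @param model `"dti"` or `"dki-linear"`.
#' @return An object of class `tensor_fit` with fields `tensor` (4-D array,
#'   six unique elements xx, yy, zz, xy, xz, yz in mm^2/s), `s0`, `fa`
#'   ([epi_volume()]), and `fit_mask`.
#' @export
fit_tensor <- function(series, mask = NULL, model = c("dti", "dki-linear")) {
  stopifnot(inherits(series, "epi_series"))
  model <- match.arg(model)
  q <- dim(series$data)[4]
  n_min <- if (model == "dti") 7L else 22L
  if (q < n_min)
    epi_stop(sprintf("model '%s' needs >= %d volumes, got %d",
                     model, n_min, q), "epi_protocol_error")
  dwi <- series$bvals > 0
  dirs <- unique(round(t(series$bvecs[, dwi, drop = FALSE]), 3))
  dirs <- dirs[rowSums(dirs^2) > 0, , drop = FALSE]
  if (nrow(dirs) < 6L)
    epi_stop(sprintf("need >= 6 unique gradient directions, got %d",
                     nrow(dirs)), "epi_protocol_error")
  X <- dwi_design_matrix(series$bvals, series$bvecs, model)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    epi_stop("rank-deficient design matrix: gradient scheme cannot resolve the model",
             "epi_protocol_error")
  d3 <- dim(series$data)[1:3]
  if (is.null(mask)) mask <- epi_mask(array(TRUE, d3), "all voxels")
  if (!all(dim(mask$data) == d3))
    epi_stop("mask grid does not match the series", "epi_argument_error")
  vox <- which(mask$data)
  nv <- prod(d3)
  S <- matrix(series$data, nrow = nv)[vox, , drop = FALSE]
  floor_val <- 1e-6 * robust_max(S)
  lnS <- t(log(pmax(S, floor_val)))
  beta <- qr.coef(qrX, lnS)        # coefficients x voxels
  s0 <- exp(beta[1, ])
  Dmat <- t(beta[2:7, , drop = FALSE])
  eigs <- sym3_eigenvalues(Dmat)
  fa_vals <- fa_from_eigenvalues(eigs)
  tensor <- array(0, c(d3, 6))
  for (m in 1:6) {
    plane <- array(0, d3)
    plane[vox] <- Dmat[, m]
    tensor[, , , m] <- plane
  }
  s0_arr <- array(0, d3); s0_arr[vox] <- s0
  fa_arr <- array(0, d3); fa_arr[vox] <- fa_vals
  structure(list(
    tensor = tensor,
    s0 = epi_volume(s0_arr, series$voxel_size, series$pe_axis),
    fa = epi_volume(fa_arr, series$voxel_size, series$pe_axis),
    fit_mask = mask,
    model = model), class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  inmask <- x$fa$data[x$fit_mask$data]
  cat("<tensor_fit> model ", x$model, ", ", sum(x$fit_mask$data),
      " voxels, median FA ", signif(stats::median(inmask), 3), "\n",
      sep = "")
  invisible(x)
}

#' White-matter probability from an FA map
#'
#' A deliberate stand-in for a full tissue segmentation: a linear ramp on
#' FA, `P = clamp((FA - lo) / (hi - lo), 0, 1)`, zero outside the fit mask.
#' The default window 0.20-0.45 assigns probability 0 at cortical-GM-like
#' FA and 1 at coherent-WM-like FA.
#'
#' @param fit a [fit_tensor()] result.
#' @param lo,hi FA ramp endpoints.
#' @return An [epi_volume()] of probabilities in `[0, 1]`.
#' @export
wm_probability <- function(fit, lo = 0.20, hi = 0.45) {
  stopifnot(inherits(fit, "tensor_fit"), hi > lo)
  p <- pmin(pmax((fit$fa$data - lo) / (hi - lo), 0), 1)
  p[!fit$fit_mask$data] <- 0
  epi_volume(p, voxel_size = fit$fa$voxel_size, pe_axis = fit$fa$pe_axis)
}

#' Brain mask from a mean b0 image
#'
#' Threshold at a fraction of the robust maximum, keep the largest
#' 6-connected component, then close with a 6-neighbour structuring
#' element.
#'
#' @param vol an [epi_volume()], typically a mean b0.
#' @param frac threshold as a fraction of the robust maximum.
#' @return An [epi_mask()].
#' @export
brain_mask_from_b0 <- function(vol, frac = 0.1) {
  stopifnot(inherits(vol, "epi_volume"))
  m <- vol$data > frac * robust_max(vol$data)
  m <- largest_component(m)
  m <- binary_closing(m)
  epi_mask(m, provenance = sprintf("b0 > %g robust max, largest component, closed",
                                   frac))
}
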