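# Seeded synthetic phantom: a distorted blip-up/blip-down diffusion
# acquisition of a known object, with ground-truth field and tissue maps.
#
# Tissue and diffusivity constants are literature-typical phantom
# conventions, fixed here: WM axial/radial diffusivity 1.7/0.3 um^2/ms
# (FA 0.80), GM 0.8, CSF 3.0 isotropic; MT saturation ~1.8/0.9/0.2
# percent units for WM/GM/CSF; b0 contrast deliberately mild between WM
# and GM (as in vivo) so that the b0-driven first field-estimation pass
# leaves residuals that the FA-driven second pass can resolve.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Phantom specification
#'
#' Describes the synthetic acquisition: grid geometry, distortion field
#' strength, diffusion protocol, and noise level. The default is a
#' desk-scale version of a two-polarity brain protocol: a 48 x 48 x 32
#' grid at 1.7 mm isotropic, one b = 1000 s/mm^2 shell with 12 directions
#' and 2 interleaved b0 volumes per polarity, peak distortion of 4 voxels
#' (6.8 mm) along the second (anterior-posterior) axis, and Rician noise
#' at b0 SNR 30. `full_protocol = TRUE` switches to the full two-shell
#' scheme (b = 1000 and 2500 s/mm^2, 60 directions each, 6 interleaved
#' b0s).
#'
#' @param grid_shape 3 integers; the PE dimension must be >= 32 so the
#'   multiresolution estimator has room.
#' @param voxel_size voxel edge length in mm (scalar or length 3).
#' @param pe_axis phase-encoding axis (1-based).
#' @param field_amplitude_mm peak |displacement| of the ground-truth field.
#' @param n_field_blobs number of focal distortion bumps.
#' @param shells data.frame with columns `bval`, `n_dir`.
#' @param n_b0 interleaved b0 volumes per polarity.
#' @param snr_b0 Rician SNR referenced to the WM b0 mean; `Inf` disables
#'   noise.
#' @param seed RNG seed (R's default Mersenne-Twister generator).
#' @param full_protocol use the full two-shell 60-direction protocol.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 32L), voxel_size = 1.7,
                         pe_axis = 2L, field_amplitude_mm = 6.8,
                         n_field_blobs = 3L,
                         shells = data.frame(bval = 1000, n_dir = 12),
                         n_b0 = 2L, snr_b0 = 30, seed = 1L,
                         full_protocol = FALSE) {
  if (full_protocol) {
    shells <- data.frame(bval = c(1000, 2500), n_dir = c(60, 60))
    n_b0 <- 6L
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  pe_axis <- as.integer(pe_axis)
  if (grid_shape[pe_axis] < 32L)
    epi_stop("grid must span >= 32 voxels along the PE axis",
             "epi_spec_error")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size), pe_axis = pe_axis,
                 field_amplitude_mm = field_amplitude_mm,
                 n_field_blobs = as.integer(n_field_blobs),
                 shells = shells, n_b0 = as.integer(n_b0),
                 snr_b0 = snr_b0, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Deterministic, well-spread hemisphere directions (spherical Fibonacci).
fibonacci_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(1 - z^2)
  rbind(rho * cos(phi), rho * sin(phi), z)
}

tissue_codes <- c(background = 0L, csf = 1L, gm = 2L, wm = 3L)

#' Generate the structural phantom
#'
#' Deterministic given the seed: an ellipsoidal "brain" with a bright CSF
#' rim, a white-matter skeleton of bars stacked along the PE axis (so WM
#' edges are sharp in the direction distortion acts), and a deep-WM
#' reference block standing in for the splenium. Produces tissue labels,
#' a WM probability map, MT saturation, and NODDI-style compartment maps
#' with ±5% seeded jitter.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth` (fields `tissue`, `wm_prob`,
#'   `mt_sat`, `v_icvf`, `v_iso`, `fiber_dirs`, `reference_mask`, `s0`;
#'   `field` and `clean_dwi` are filled by [make_field()] /
#'   [simulate_dwi()]).
#' @export
make_structural <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  ctr <- (d + 1) / 2
  semi <- 0.42 * d
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  X <- array(x, d)
  Y <- array(rep(y, each = d[1]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  r2 <- ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
    ((Z - ctr[3]) / semi[3])^2
  brain <- r2 <= 1
  interior <- r2 <= 0.78
  tissue <- array(tissue_codes["background"], d)
  tissue[brain] <- tissue_codes["csf"]
  tissue[interior] <- tissue_codes["gm"]

  # WM bars: slabs perpendicular to the PE axis, clipped to the interior,
  # so WM edges are sharp along the direction distortion acts.
  coords <- list(X, Y, Z)
  pe <- spec$pe_axis
  ortho <- setdiff(1:3, pe)
  o1 <- ortho[1]; o2 <- ortho[2]
  bar_centers <- c(0.22, 0.31, 0.40, 0.49, 0.58, 0.67, 0.76, 0.85)
  half_th <- max(1L, round(0.025 * d[pe]))
  in_plane <- abs(coords[[o1]] - ctr[o1]) <= 0.32 * d[o1] &
    abs(coords[[o2]] - ctr[o2]) <= 0.20 * d[o2]
  fiber <- array(0, c(d, 3))
  wm <- array(FALSE, d)
  for (k in seq_along(bar_centers)) {
    yc <- bar_centers[k] * d[pe]
    bar <- abs(coords[[pe]] - yc) <= half_th & in_plane & interior
    wm <- wm | bar
    ax <- if (k %% 2L == 1L) o1 else o2
    for (cmp in 1:3) {
      plane <- fiber[, , , cmp]
      plane[bar] <- as.numeric(cmp == ax)
      fiber[, , , cmp] <- plane
    }
  }
  ref <- abs(X - ctr[1]) <= 0.10 * d[1] &
    abs(Y - ctr[2]) <= 0.08 * d[2] &
    abs(Z - ctr[3]) <= 0.08 * d[3]
  wm <- wm | ref
  for (cmp in 1:3) {
    plane <- fiber[, , , cmp]
    plane[ref] <- as.numeric(cmp == o1)
    fiber[, , , cmp] <- plane
  }
  tissue[wm] <- tissue_codes["wm"]
  if (sum(wm) < 100L)
    epi_stop("degenerate phantom geometry: fewer than 100 WM voxels",
             "epi_spec_error")

  with_seed(spec$seed, {
    jit <- function() array(stats::runif(prod(d), -1, 1), d)
    lvl <- function(vals) {
      out <- array(0, d)
      for (t in names(vals)) out[tissue == tissue_codes[t]] <- vals[[t]]
      out
    }
    mt_sat <- lvl(c(wm = 1.8, gm = 0.9, csf = 0.2)) * (1 + 0.05 * jit())
    v_icvf <- pmin(pmax(lvl(c(wm = 0.65, gm = 0.40, csf = 0.02)) *
                          (1 + 0.05 * jit()), 0), 1)
    v_iso <- pmin(pmax(lvl(c(wm = 0.05, gm = 0.20, csf = 0.95)) *
                         (1 + 0.05 * jit()), 0), 1)
    wm_prob <- pmin(pmax(lvl(c(wm = 0.98, gm = 0.05, csf = 0.01)) +
                           0.01 * jit(), 0), 1)
    # Smooth multiplicative texture: real b0 tissue is not piecewise
    # constant, and the field estimator relies on intensity structure.
    # White matter is kept nearly homogeneous (as in T2-weighted EPI),
    # which leaves the b0-driven first pass under-constrained inside WM —
    # the situation the FA-driven second pass exists to repair.
    tex <- gaussian_smooth3(jit(), 2.5)
    tex <- tex / stats::sd(tex)
    tex_amp <- lvl(c(wm = 0.03, gm = 0.15, csf = 0.15))
    s0 <- lvl(c(wm = 0.85, gm = 1.0, csf = 1.6)) * (1 + tex_amp * tex)
    vs <- spec$voxel_size
    structure(list(
      tissue = tissue,
      wm_prob = epi_volume(wm_prob, vs, spec$pe_axis),
      mt_sat = epi_volume(mt_sat, vs, spec$pe_axis),
      v_icvf = epi_volume(v_icvf, vs, spec$pe_axis),
      v_iso = epi_volume(v_iso, vs, spec$pe_axis),
      s0 = epi_volume(s0, vs, spec$pe_axis),
      fiber_dirs = fiber,
      brain_mask = epi_mask(brain, "phantom brain ellipsoid"),
      reference_mask = epi_mask(ref, "deep-WM reference block"),
      field = NULL, clean_dwi = NULL), class = "phantom_truth")
  })
}

#' Generate the ground-truth distortion field
#'
#' A sum of `n_field_blobs` Gaussian bumps with alternating sign, centred
#' near the "frontal" and "temporal" edges of the brain (seeded jitter),
#' scaled so the peak |displacement| equals `field_amplitude_mm`. The
#' default amplitude of 4 voxels keeps the field invertible while leaving
#' a non-empty |Jac - 1| > 0.2 high-distortion region.
#'
#' @param spec a [phantom_spec()].
#' @return A [field_map()].
#' @export
make_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  ctr <- (d + 1) / 2
  semi <- 0.42 * d
  pe <- spec$pe_axis
  if (spec$field_amplitude_mm == 0)
    return(field_map(array(0, d), pe, spec$voxel_size))
  ortho <- setdiff(1:3, pe)
  offs <- function(along_pe, along_o1, along_o2) {
    v <- numeric(3)
    v[pe] <- along_pe; v[ortho[1]] <- along_o1; v[ortho[2]] <- along_o2
    ctr + v * semi
  }
  base_centers <- list(   # "frontal" pole and "temporal" flanks
    offs(0.74, 0, 0),
    offs(-0.45, -0.66, -0.2),
    offs(-0.45, 0.66, -0.2),
    offs(-0.74, 0, 0.2),
    offs(0.5, -0.5, 0.2))
  with_seed(spec$seed + 1L, {
    b <- array(0, d)
    for (k in seq_len(spec$n_field_blobs)) {
      cen <- base_centers[[(k - 1L) %% length(base_centers) + 1L]] +
        stats::runif(3, -2, 2)
      sg <- stats::runif(1, 3.4, 4.4)
      amp <- (if (k %% 2L == 1L) 1 else -1) * stats::runif(1, 0.7, 1)
      gx <- exp(-((seq_len(d[1]) - cen[1])^2) / (2 * sg^2))
      gy <- exp(-((seq_len(d[2]) - cen[2])^2) / (2 * sg^2))
      gz <- exp(-((seq_len(d[3]) - cen[3])^2) / (2 * sg^2))
      b <- b + amp * array(outer(outer(gx, gy), gz), d)
    }
    amp_vox <- spec$field_amplitude_mm / spec$voxel_size[pe]
    b <- b * amp_vox / max(abs(b))
    fm <- field_map(b * spec$voxel_size[pe], pe, spec$voxel_size)
    jp <- tryCatch(jacobians(fm), error = function(e) NULL)
    if (is.null(jp) || min(jp$jac_up, jp$jac_down) <= 0.2)
      epi_stop(
        "generated field violates the invertibility margin (min Jacobian <= 0.2); lower field_amplitude_mm",
        "epi_spec_error")
    fm
  })
}

#' Simulate the distorted blip-up/blip-down diffusion acquisition
#'
#' Per voxel the noiseless signal is `S0 * exp(-b g' D g)` with an
#' anisotropic tensor along the local fiber direction in WM (axial
#' 1.7e-3, radial 0.3e-3 mm^2/s), isotropic 0.8e-3 in GM and 3.0e-3 in
#' CSF. Each volume is then pushed through the ground-truth field
#' ([unwarp()], the mass-conserving pushforward: tissue at object
#' position `p` lands at acquired position displaced by `+b(p)` for
#' blip-up and `-b(p)` for blip-down, with signal pile-up in squeezed
#' regions and dilution in stretched ones), and Rician noise at `snr_b0`
#' (referenced to the WM b0 mean) is added. Volumes are ordered with the
#' b0s interleaved between direction blocks.
#'
#' @param truth a [make_structural()] result with `field` set.
#' @param spec the same [phantom_spec()].
#' @return A list with elements `up`, `down` (distorted [epi_series()])
#'   and `truth` (with `clean_dwi` filled in).
#' @export
simulate_dwi <- function(truth, spec) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(spec, "phantom_spec"))
  if (is.null(truth$field))
    epi_stop("truth$field is not set; run make_field() first",
             "epi_spec_error")
  d <- spec$grid_shape
  # protocol: interleave n_b0 b0 volumes between equal direction blocks
  bvals_dwi <- numeric(0)
  dirs_dwi <- matrix(0, 3, 0)
  for (s in seq_len(nrow(spec$shells))) {
    g <- fibonacci_dirs(spec$shells$n_dir[s])
    dirs_dwi <- cbind(dirs_dwi, g)
    bvals_dwi <- c(bvals_dwi, rep(spec$shells$bval[s], spec$shells$n_dir[s]))
  }
  nd <- length(bvals_dwi)
  grp <- sort(rep_len(seq_len(spec$n_b0), nd))
  bvals <- numeric(0); bvecs <- matrix(0, 3, 0)
  for (k in seq_len(spec$n_b0)) {
    bvals <- c(bvals, 0, bvals_dwi[grp == k])
    bvecs <- cbind(bvecs, c(0, 0, 0), dirs_dwi[, grp == k, drop = FALSE])
  }
  q <- length(bvals)

  wm <- truth$tissue == tissue_codes["wm"]
  gm <- truth$tissue == tissue_codes["gm"]
  csf <- truth$tissue == tissue_codes["csf"]
  lam_par <- 1.7e-3; lam_perp <- 0.3e-3
  fx <- truth$fiber_dirs[, , , 1]
  fy <- truth$fiber_dirs[, , , 2]
  fz <- truth$fiber_dirs[, , , 3]
  S0 <- truth$s0$data
  clean <- array(0, c(d, q))
  for (j in seq_len(q)) {
    if (bvals[j] == 0) {
      clean[, , , j] <- S0
      next
    }
    g <- bvecs[, j]
    dot <- fx * g[1] + fy * g[2] + fz * g[3]
    adc <- array(0, d)
    adc[wm] <- lam_perp + (lam_par - lam_perp) * dot[wm]^2
    adc[gm] <- 0.8e-3
    adc[csf] <- 3.0e-3
    clean[, , , j] <- S0 * exp(-bvals[j] * adc)
  }
  b_vox <- field_vox(truth$field)
  pe <- truth$field$pe_axis
  up <- clean; down <- clean
  for (j in seq_len(q)) {
    up[, , , j] <- unwarp_array(clean[, , , j], b_vox, pe, +1)
    down[, , , j] <- unwarp_array(clean[, , , j], b_vox, pe, -1)
  }
  if (is.finite(spec$snr_b0)) {
    sigma <- mean(S0[wm]) / spec$snr_b0
    with_seed(spec$seed + 2L, {
      rician <- function(arr) {
        e1 <- array(stats::rnorm(length(arr), sd = sigma), dim(arr))
        e2 <- array(stats::rnorm(length(arr), sd = sigma), dim(arr))
        sqrt((arr + e1)^2 + e2^2)
      }
      up <- rician(up)
      down <- rician(down)
    })
  }
  vs <- spec$voxel_size
  truth$clean_dwi <- epi_series(clean, bvals, bvecs, "combined", pe, vs)
  list(up = epi_series(up, bvals, bvecs, "up", pe, vs),
       down = epi_series(down, bvals, bvecs, "down", pe, vs),
       truth = truth)
}

#' Generate a complete phantom
#'
#' Convenience wrapper: structural maps, ground-truth field, and the
#' distorted noisy blip-up/blip-down acquisition, all deterministic given
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `up`, `down` ([epi_series()]) and `truth`
#'   (`phantom_truth` including `field` and `clean_dwi`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  truth <- make_structural(spec)
  truth$field <- make_field(spec)
  simulate_dwi(truth, spec)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> ", paste(dim(x$tissue), collapse = " x "),
      " voxels, ", sum(x$tissue == tissue_codes["wm"]), " WM voxels",
      if (!is.null(x$field)) sprintf(", |b| max %.2f mm",
                                     max(abs(x$field$b_mm))),
      "\n", sep = "")
  invisible(x)
}
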