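# Shared fixtures. Everything is generated in code; the expensive phantom
# pipeline runs are memoized so several test files can share one run.

vol_of <- function(arr, vox = 1.7, pe = 2L) {
  epi_volume(arr, voxel_size = vox, pe_axis = pe)
}

rand_volume <- function(dim = c(12, 16, 8), seed = 1, pe = 2L) {
  set.seed(seed)
  vol_of(array(runif(prod(dim)), dim), pe = pe)
}

# Smooth random field with bounded PE slope (voxel units -> mm).
rand_smooth_field <- function(dim = c(16, 20, 10), pe = 2L, vox = 1.7,
                              max_slope = 0.5, seed = 1) {
  set.seed(seed)
  raw <- array(rnorm(prod(dim)), dim)
  for (i in 1:2) raw <- epicombine:::gaussian_smooth3(raw, 1.5)
  d <- epicombine:::axis_deriv(raw, pe)
  raw <- raw * max_slope / max(abs(d))
  field_map(raw * vox, pe_axis = pe, voxel_size = vox)
}

field_in_vox <- function(field) {
  field$b_mm / field$voxel_size[field$pe_axis]
}

# Noiseless single-tensor diffusion signals for a direction scheme.
tensor_signals <- function(D, bvals, bvecs, s0 = 1) {
  q <- length(bvals)
  vapply(seq_len(q), function(j) {
    g <- bvecs[, j]
    s0 * exp(-bvals[j] * drop(t(g) %*% D %*% g))
  }, numeric(1))
}

# Series with every voxel sharing one diffusion tensor.
uniform_tensor_series <- function(D, n_dir = 30, bval = 1000,
                                  dim = c(4, 4, 2), s0 = 1, n_b0 = 2) {
  dirs <- epicombine:::fibonacci_dirs(n_dir)
  bvals <- c(rep(0, n_b0), rep(bval, n_dir))
  bvecs <- cbind(matrix(0, 3, n_b0), dirs)
  sig <- tensor_signals(D, bvals, bvecs, s0)
  data <- array(rep(sig, each = prod(dim)), c(dim, length(bvals)))
  epi_series(data, bvals, bvecs, polarity = "combined", pe_axis = 2L,
             voxel_size = 1.7)
}

# Memoized full pipeline runs on the default phantom (shared by the
# estimator tests and the acceptance suite).
.run_cache <- new.env(parent = emptyenv())

phantom_run <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  spec <- phantom_spec(seed = seed)
  ph <- make_phantom(spec)
  res <- consecutive_pipeline(ph$up, ph$down)
  am <- combine_series(res$corrected_up, res$corrected_down,
                       res$jacobians_step1, method = "am")
  fit2_up <- fit_tensor(res$corrected_up, res$brain_mask)
  fit2_down <- fit_tensor(res$corrected_down, res$brain_mask)
  prob_wa <- wm_probability(fit_tensor(res$combined, res$brain_mask))
  prob_am <- wm_probability(fit_tensor(am, res$brain_mask))
  out <- list(spec = spec, ph = ph, res = res, am = am,
              fit2_up = fit2_up, fit2_down = fit2_down,
              prob_wa = prob_wa, prob_am = prob_am)
  .run_cache[[key]] <- out
  out
}
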