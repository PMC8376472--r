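test_that("mean_b0 averages exactly the b = 0 volumes", {
  d <- c(4, 4, 2)
  dirs <- epicombine:::fibonacci_dirs(2)
  data <- array(0, c(d, 4))
  data[, , , 1] <- 2; data[, , , 3] <- 4
  data[, , , 2] <- 9; data[, , , 4] <- 9
  ser <- epi_series(data, c(0, 1000, 0, 1000),
                    cbind(c(0, 0, 0), dirs[, 1], c(0, 0, 0), dirs[, 2]),
                    "up", 2, 1.7)
  expect_equal(mean_b0(ser)$data, array(3, d))
  one <- epi_series(data[, , , 1:2, drop = FALSE], c(0, 1000),
                    cbind(c(0, 0, 0), dirs[, 1]), "up", 2, 1.7)
  expect_equal(mean_b0(one)$data, array(2, d))
  none <- epi_series(data[, , , 2, drop = FALSE], 1000, dirs[, 1, drop = FALSE],
                     "up", 2, 1.7)
  expect_error(mean_b0(none), class = "epi_protocol_error")
})

test_that("rigid_align recovers translations and defaults to identity", {
  set.seed(31)
  d <- c(24, 24, 12)
  base <- epicombine:::gaussian_smooth3(array(runif(prod(d)), d), 1.5)
  fixed <- vol_of(base, vox = 1)
  expect_equal(rigid_align(fixed, fixed, "off")$shift, c(0, 0, 0))
  same <- rigid_align(fixed, fixed, "translation")
  expect_equal(same$shift, c(0, 0, 0), tolerance = 1e-6)
  moved <- vol_of(epicombine:::shift_trilinear(base, c(2, 0, 0)), vox = 1)
  # moved(x) = base(x + 2): content displaced by -2 along axis 1
  al <- rigid_align(moved, fixed, "translation")
  expect_equal(abs(al$shift[1]), 2, tolerance = 0.25)
  expect_equal(al$shift[2:3], c(0, 0), tolerance = 0.25)
  core <- al$resampled$data[5:20, 5:20, 3:10]
  expect_lt(sqrt(mean((core - base[5:20, 5:20, 3:10])^2)), 0.05)
})

test_that("identical inputs give a (near) zero field without complaint", {
  v <- vol_of(epicombine:::gaussian_smooth3(
    array(runif(48 * 48 * 32), c(48, 48, 32)), 2))
  expect_no_warning(f <- estimate_field(v, v))
  expect_lt(sqrt(mean(field_in_vox(f)^2)), 0.05)
  expect_true(attr(f, "converged"))
})

test_that("the logged objective never increases across accepted steps", {
  run <- phantom_run(1)
  lg <- attr(run$res$field_step1, "log")
  acc <- Filter(function(r) r$accepted, lg)
  obj <- vapply(acc, `[[`, numeric(1), "objective")
  grp <- vapply(acc, function(r) paste(r$level, r$pass_sigma), "")
  for (g in unique(grp))
    expect_true(all(diff(obj[grp == g]) <= 1e-9))
})

test_that("the first-pass field is recovered to subvoxel accuracy", {
  run <- phantom_run(1)
  err <- field_in_vox(run$res$field_step1) -
    field_in_vox(run$ph$truth$field)
  bm <- run$ph$truth$brain_mask$data
  expect_lt(sqrt(mean(err[bm]^2)), 0.5)
})

test_that("the pipeline is deterministic", {
  run <- phantom_run(1)
  rerun <- consecutive_pipeline(run$ph$up, run$ph$down)
  expect_identical(rerun$field_step1$b_mm, run$res$field_step1$b_mm)
  expect_identical(rerun$combined$data, run$res$combined$data)
})

test_that("a zero-field noiseless phantom passes through unchanged", {
  spec <- phantom_spec(seed = 2, field_amplitude_mm = 0, snr_b0 = Inf)
  ph <- make_phantom(spec)
  expect_equal(ph$up$data, ph$down$data)
  res <- consecutive_pipeline(ph$up, ph$down)
  expect_lt(max(abs(field_in_vox(res$field_step1))), 0.05)
  expect_lt(max(abs(field_in_vox(res$field_step2))), 0.05)
  am <- combine_series(res$corrected_up, res$corrected_down,
                       res$jacobians_step1, method = "am")
  expect_equal(res$combined$data, am$data, tolerance = 1e-6)
})

test_that("consecutive correction improves on the single pass", {
  run <- phantom_run(1)
  truth_vox <- field_in_vox(run$ph$truth$field)
  bm <- run$res$brain_mask$data
  e1 <- sqrt(mean((truth_vox - field_in_vox(run$res$field_step1))[bm]^2))
  etot <- sqrt(mean((truth_vox - field_in_vox(total_field(run$res)))[bm]^2))
  expect_lt(etot, e1)
  wm <- wm_mask_from_prob(run$ph$truth$wm_prob)
  rms1 <- rms_fa_difference(run$res$fa_step1_up, run$res$fa_step1_down, wm)
  rms2 <- rms_fa_difference(run$fit2_up$fa, run$fit2_down$fa, wm)
  expect_lt(rms2, rms1)
})

test_that("composed application agrees with sequential resampling", {
  run <- phantom_run(1)
  comp <- consecutive_pipeline(run$ph$up, run$ph$down,
                               apply_mode = "composed")
  seq_b0 <- mean_b0(run$res$combined)$data
  comp_b0 <- mean_b0(comp$combined)$data
  rng <- diff(range(seq_b0))
  expect_lt(sqrt(mean((seq_b0 - comp_b0)^2)) / rng, 0.03)
  # the single interpolation never does worse against the ground truth
  truth_b0 <- mean_b0(run$ph$truth$clean_dwi)$data
  bm <- run$res$brain_mask$data
  err_seq <- sqrt(mean((seq_b0 - truth_b0)[bm]^2))
  err_comp <- sqrt(mean((comp_b0 - truth_b0)[bm]^2))
  expect_lt(err_comp, err_seq * 1.02)
})

test_that("estimator configuration is validated", {
  expect_error(estimator_config(lambda_reg = 0), class = "epi_argument_error")
  expect_error(estimator_config(tol = 1), class = "epi_argument_error")
  expect_error(estimator_config(levels = 0), class = "epi_argument_error")
})
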