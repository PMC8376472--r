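test_that("zero field gives unit Jacobians and identity warps", {
  f0 <- field_map(array(0, c(10, 12, 6)), pe_axis = 2, voxel_size = 1.7)
  jp <- jacobians(f0)
  expect_true(all(jp$jac_up == 1) && all(jp$jac_down == 1))
  v <- rand_volume(c(10, 12, 6), seed = 3)
  for (pol in c("up", "down")) {
    expect_equal(apply_distortion(v, f0, pol)$data, v$data)
    expect_equal(apply_distortion(v, f0, pol, modulate = FALSE)$data, v$data)
    expect_equal(unwarp(v, f0, pol)$data, v$data)
  }
})

test_that("linear field reproduces the exact interior Jacobians", {
  d <- c(8, 20, 6)
  vox <- 1.7
  idx <- array(rep(seq_len(d[2]), each = d[1]), d)
  f <- field_map(0.2 * idx * vox, pe_axis = 2, voxel_size = vox)
  jp <- jacobians(f)
  interior <- idx > 1 & idx < d[2]
  expect_equal(unique(round(jp$jac_up[interior], 12)), 1.2)
  expect_equal(unique(round(jp$jac_down[interior], 12)), 0.8)
})

test_that("jac_up + jac_down == 2 exactly for arbitrary smooth fields", {
  for (s in 1:20) {
    jp <- jacobians(rand_smooth_field(seed = s, max_slope = 0.7))
    expect_identical(max(abs(jp$jac_up + jp$jac_down - 2)), 0)
    expect_true(min(jp$jac_up) > 0 && min(jp$jac_down) > 0)
  }
})

test_that("non-invertible fields are rejected with the worst voxel", {
  d <- c(6, 12, 4)
  idx <- array(rep(seq_len(d[2]), each = d[1]), d)
  f <- field_map(1.2 * idx * 1.7, pe_axis = 2, voxel_size = 1.7)
  expect_error(jacobians(f), "Jacobian", class = "epi_invertibility_error")
  v <- rand_volume(d)
  expect_error(unwarp(v, f, "down"), class = "epi_invertibility_error")
})

test_that("constant field is a pure translation and modulation a no-op", {
  d <- c(8, 24, 6)
  vox <- 1.7
  set.seed(5)
  v <- vol_of(array(runif(prod(d)), d))
  f <- field_map(array(3 * vox, d), pe_axis = 2, voxel_size = vox)
  warped <- apply_distortion(v, f, "up", modulate = TRUE)
  # analytic oracle: integer translation by 3 voxels with edge clamp
  shifted <- epicombine:::shift_replicate(v$data, 2, -3L)
  expect_equal(warped$data, shifted, tolerance = 1e-12)
  expect_equal(apply_distortion(v, f, "up", modulate = FALSE)$data,
               warped$data)
  # unwarp cancels the translation away from the clamped edge
  back <- unwarp(warped, f, "up")$data
  interior <- 4:(d[2] - 4)
  expect_equal(back[, interior, ], v$data[, interior, ], tolerance = 1e-10)
})

test_that("the acquisition pushforward conserves total intensity", {
  d <- c(16, 32, 8)
  ctr <- (d + 1) / 2
  X <- array(seq_len(d[1]), d)
  Y <- array(rep(seq_len(d[2]), each = d[1]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  blob <- exp(-((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2) / 18)
  v <- vol_of(blob)
  f <- rand_smooth_field(d, max_slope = 0.5, seed = 11)
  for (pol in c("up", "down")) {
    acq <- unwarp(v, f, pol)
    expect_lt(abs(sum(acq$data) - sum(blob)) / sum(blob), 0.01)
  }
})

test_that("warp and inverse warp compose to the identity", {
  spec <- phantom_spec(seed = 4)
  tr <- make_structural(spec)
  tr$field <- make_field(spec)
  v <- tr$s0
  rng <- diff(range(v$data))
  # evaluate away from the object boundary (2-voxel erosion); what
  # remains is linear-interpolation error at interior tissue edges
  interior <- epicombine:::erode6(epicombine:::erode6(tr$brain_mask$data))
  for (pol in c("up", "down")) {
    acq <- unwarp(v, tr$field, pol)
    back <- apply_distortion(acq, tr$field, pol)
    err <- (back$data - v$data)[interior]
    expect_lt(sqrt(mean(err^2)) / rng, 0.025)
    # and in the opposite composition order
    w <- apply_distortion(v, tr$field, pol)
    back2 <- unwarp(w, tr$field, pol)
    expect_lt(sqrt(mean(((back2$data - v$data)[interior])^2)) / rng, 0.025)
  }
})

test_that("squeezed regions shrink a bar in the acquisition, stretched ones widen it", {
  d <- c(4, 64, 4)
  vox <- 1
  bar <- array(0, d)
  bar[, 25:40, ] <- 1
  # positive slope across the bar: jac_up > 1 there (up acquisition
  # stretches the bar), jac_down < 1 (down squeezes it)
  y <- array(rep(seq_len(d[2]), each = d[1]), d)
  b <- 0.4 * 8 * tanh((y - 32) / 8)
  f <- field_map(b * vox, pe_axis = 2, voxel_size = vox)
  jp <- jacobians(f)
  expect_gt(mean(jp$jac_up[, 25:40, ]), 1)
  width <- function(a) sum(a[2, , 2] > 0.5)
  w_up <- width(unwarp(vol_of(bar, vox), f, "up")$data)
  w_dn <- width(unwarp(vol_of(bar, vox), f, "down")$data)
  expect_gt(w_up, width(bar))    # stretched polarity: wider apparent bar
  expect_lt(w_dn, width(bar))    # squeezed polarity: narrower
})

test_that("series-level warps match the volume-level operators", {
  dirs <- epicombine:::fibonacci_dirs(3)
  data <- array(rnorm(10 * 12 * 6 * 4), c(10, 12, 6, 4))
  ser <- epi_series(data, c(0, 1000, 1000, 1000),
                    cbind(c(0, 0, 0), dirs), "up", 2, 1.7)
  f <- rand_smooth_field(c(10, 12, 6), seed = 9, max_slope = 0.4)
  cor <- correct_series(ser, f)
  acq <- unwarp_series(ser, f)
  for (q in 1:4) {
    expect_equal(cor$data[, , , q],
                 apply_distortion(series_volume(ser, q), f, "up")$data)
    expect_equal(acq$data[, , , q],
                 unwarp(series_volume(ser, q), f, "up")$data)
  }
})
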