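mk_masks <- function(d, on = TRUE) epi_mask(array(on, d))

test_that("axonal water fraction follows (1 - v_iso) * v_icvf", {
  d <- c(3, 3, 2)
  expect_equal(compute_awf(array(1, d), array(0, d))$data, array(1, d))
  expect_equal(compute_awf(array(0.7, d), array(1, d))$data, array(0, d))
  expect_equal(compute_awf(array(0.6, d), array(0.2, d))$data,
               array(0.48, d))
  expect_error(compute_awf(array(1.2, d), array(0, d)),
               class = "epi_domain_error")
})

test_that("the g-ratio map matches closed forms and the zero-fill rule", {
  d <- c(4, 1, 1)
  # voxels: (MVF=0, AVF>0), (AVF=0, MVF>0), worked value, outside mask
  mt <- vol_of(array(c(0, 1.5, 1.5, 1.5), d), vox = 1, pe = NA)
  alpha <- 0.2
  # choose fractions so AVF is 0 / positive / the worked value
  v_icvf <- array(c(0.8, 0, 0.5, 0.5), d)
  v_iso <- array(0, d)
  wm <- epi_mask(array(c(TRUE, TRUE, TRUE, FALSE), d))
  inputs <- gratio_inputs(mt, v_icvf, v_iso, wm, wm, alpha = alpha)
  gm <- gratio_map(inputs)
  # unmyelinated limit: g = 1
  expect_equal(gm$g$data[1, 1, 1], 1)
  # axon-free voxel: g = 0 but still defined
  expect_equal(gm$g$data[2, 1, 1], 0)
  expect_true(gm$defined_mask$data[2, 1, 1])
  # closed form sqrt(1 - MVF/(MVF+AVF))
  mvf <- alpha * 1.5
  avf <- (1 - mvf) * 0.5
  expect_equal(gm$g$data[3, 1, 1], sqrt(1 - mvf / (mvf + avf)),
               tolerance = 1e-12)
  # zero-filled outside the joint mask
  expect_identical(gm$g$data[4, 1, 1], 0)
  expect_false(gm$defined_mask$data[4, 1, 1])
})

test_that("worked g value sqrt(0.35/0.65) is reproduced", {
  # MVF 0.3, AVF 0.35 -> g = 0.733799
  d <- c(1, 1, 1)
  mt <- vol_of(array(1, d), vox = 1, pe = NA)
  awf <- 0.35 / 0.7    # so that (1 - 0.3) * awf = 0.35
  inputs <- gratio_inputs(mt, array(awf, d), array(0, d),
                          mk_masks(d), mk_masks(d), alpha = 0.3)
  gm <- gratio_map(inputs)
  expect_equal(gm$g$data[1, 1, 1], 0.733799, tolerance = 1e-6)
})

test_that("alpha calibration recovers the closed-form uniform solution", {
  d <- c(6, 6, 3)
  mt <- array(1.5, d)
  awf <- array(0.5, d)
  ref <- mk_masks(d)
  a <- calibrate_alpha(mt, awf, ref, target_g = 0.7)
  # closed form: g^2 = (1-M)/(1+M) = 0.49 -> M = 0.51/1.49, alpha = M/1.5
  expect_equal(a, (0.51 / 1.49) / 1.5, tolerance = 1e-5)
  expect_equal(a, 0.228188, tolerance = 1e-5)
  # unreachable target reports the attainable range
  expect_error(calibrate_alpha(mt, awf, ref, target_g = 0.01),
               "attainable", class = "epi_calibration_error")
  expect_error(calibrate_alpha(mt, awf, epi_mask(array(FALSE, d))),
               class = "epi_calibration_error")
})

test_that("calibration on phantom maps pins the reference-region mean g", {
  spec <- phantom_spec(seed = 3)
  tr <- make_structural(spec)
  awf <- compute_awf(tr$v_icvf, tr$v_iso)
  a <- calibrate_alpha(tr$mt_sat, awf, tr$reference_mask, target_g = 0.7)
  wm_all <- mk_masks(dim(tr$tissue))
  gm <- gratio_map(gratio_inputs(tr$mt_sat, tr$v_icvf, tr$v_iso,
                                 wm_all, wm_all, alpha = a))
  expect_equal(mean(gm$g$data[tr$reference_mask$data]), 0.7,
               tolerance = 1e-4)
})

test_that("increasing alpha strictly decreases g on defined voxels", {
  spec <- phantom_spec(seed = 5)
  tr <- make_structural(spec)
  wm_all <- mk_masks(dim(tr$tissue))
  g1 <- gratio_map(gratio_inputs(tr$mt_sat, tr$v_icvf, tr$v_iso,
                                 wm_all, wm_all, alpha = 0.15))
  g2 <- gratio_map(gratio_inputs(tr$mt_sat, tr$v_icvf, tr$v_iso,
                                 wm_all, wm_all, alpha = 0.25))
  sel <- g1$defined_mask$data & g2$defined_mask$data & g1$g$data > 0 &
    tr$mt_sat$data > 0
  expect_true(all(g2$g$data[sel] < g1$g$data[sel]))
})

test_that("group means honour the include_zeros convention", {
  d <- c(4, 4, 2)
  g <- array(0.8, d)
  g[1:2, , ] <- 0
  gm <- structure(list(g = vol_of(g, vox = 1),
                       defined_mask = epi_mask(g > 0)),
                  class = "gratio_map")
  region <- mk_masks(d)
  expect_equal(group_mean_gratio(gm, region, include_zeros = TRUE), 0.4)
  expect_equal(group_mean_gratio(gm, region, include_zeros = FALSE), 0.8)
  const <- structure(list(g = vol_of(array(0.7, d), vox = 1),
                          defined_mask = mk_masks(d)),
                     class = "gratio_map")
  expect_equal(group_mean_gratio(const, region), 0.7)
  expect_equal(group_mean_gratio(list(gm, const), region), (0.4 + 0.7) / 2)
  expect_error(group_mean_gratio(gm, epi_mask(array(FALSE, d))),
               class = "epi_domain_error")
})

test_that("input validation guards the MVF < 1 invariant and defaults", {
  d <- c(2, 2, 2)
  mt <- vol_of(array(5, d), vox = 1)
  expect_error(gratio_inputs(mt, array(0.5, d), array(0, d),
                             mk_masks(d), mk_masks(d), alpha = 0.5),
               class = "epi_calibration_error")
  ok <- gratio_inputs(mt, array(0.5, d), array(0, d),
                      mk_masks(d), mk_masks(d), alpha = 0.1)
  expect_equal(ok$alpha, 0.1)
  # documented fallback constant when nothing is supplied
  def <- gratio_inputs(vol_of(array(1.5, d), vox = 1), array(0.5, d),
                       array(0, d), mk_masks(d), mk_masks(d))
  expect_equal(def$alpha, 0.217)
})
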