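test_that("rms_fa_difference is masked and exact", {
  d <- c(4, 4, 2)
  a <- vol_of(array(0.5, d), vox = 1)
  mask <- epi_mask(array(c(TRUE, FALSE), d))
  expect_equal(rms_fa_difference(a, a, mask), 0)
  b <- vol_of(array(0.55, d), vox = 1)
  expect_equal(rms_fa_difference(a, b, mask), 0.05, tolerance = 1e-12)
  # a wild voxel outside the mask changes nothing
  b2 <- b
  out_idx <- which(!mask$data)[1]
  b2$data[out_idx] <- 1.5
  expect_equal(rms_fa_difference(a, b2, mask), 0.05, tolerance = 1e-12)
  expect_error(rms_fa_difference(a, b, epi_mask(array(FALSE, d))),
               class = "epi_domain_error")
})

test_that("wm_mask_from_prob thresholds strictly above", {
  p <- vol_of(array(c(0.9, 0.95, 0.89, 0), c(4, 1, 1)), vox = 1, pe = NA)
  m <- wm_mask_from_prob(p, 0.9)
  expect_equal(as.vector(m$data), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(sum(wm_mask_from_prob(vol_of(array(0, c(3, 3, 3)),
                                            vox = 1))$data), 0)
  expect_error(wm_mask_from_prob(vol_of(array(1.5, c(2, 2, 2)), vox = 1)),
               class = "epi_domain_error")
})

test_that("distortion masks are two-sided and nested", {
  j <- vol_of(array(c(1, 1.25, 0.75, 1.05), c(4, 1, 1)), vox = 1, pe = NA)
  expect_equal(as.vector(distortion_mask(j, 0.20)$data),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_false(distortion_mask(j, 0.30)$data[2, 1, 1])
  expect_equal(sum(distortion_mask(vol_of(array(1, c(3, 3, 3)), vox = 1),
                                   0.1)$data), 0)
  # nesting over random positive Jacobian maps
  for (s in 1:5) {
    jp <- jacobians(rand_smooth_field(seed = s, max_slope = 0.6))
    m10 <- distortion_mask(jp$jac_up, 0.10)$data
    m20 <- distortion_mask(jp$jac_up, 0.20)$data
    m30 <- distortion_mask(jp$jac_up, 0.30)$data
    expect_true(all(m30 <= m20) && all(m20 <= m10))
  }
  expect_error(distortion_mask(vol_of(array(c(-1, 1), c(2, 1, 1)),
                                      vox = 1, pe = NA), 0.1),
               class = "epi_domain_error")
})

test_that("overlap definitions agree on the boundary cases", {
  d <- c(10, 10, 4)
  S <- array(0, d); S[3:8, 3:8, 2:3] <- 1
  same <- vol_of(S, vox = 1)
  for (def in c("coverage", "dice", "jaccard"))
    expect_equal(overlap_percent(same, same, definition = def), 100)
  # D covering exactly half of S, D inside S
  D <- array(0, d); D[3:8, 3:5, 2:3] <- 1
  expect_equal(overlap_percent(vol_of(D, vox = 1), same), 50)
  # disjoint maps
  E <- array(0, d); E[9:10, 9:10, 1] <- 1
  expect_equal(overlap_percent(vol_of(E, vox = 1), same), 0)
  # coverage is asymmetric, dice/jaccard symmetric
  expect_equal(overlap_percent(vol_of(D, vox = 1), same, definition = "dice"),
               overlap_percent(same, vol_of(D, vox = 1), definition = "dice"))
  expect_false(isTRUE(all.equal(
    overlap_percent(vol_of(D, vox = 1), same),
    overlap_percent(same, vol_of(D, vox = 1)))))
  expect_error(overlap_percent(same, vol_of(array(0, d), vox = 1)),
               class = "epi_domain_error")
  # region restriction
  reg <- epi_mask(array(FALSE, d)); reg$data[3:8, 3:5, 2:3] <- TRUE
  expect_equal(overlap_percent(vol_of(D, vox = 1), same, region = reg), 100)
})

test_that("paired_compare reproduces the repeated-measures formulas", {
  # a = b: zero mean difference and zero effect size, t undefined
  expect_warning(pc0 <- paired_compare(c(1, 2, 3), c(1, 2, 3)),
                 class = "epi_degenerate_variance")
  expect_equal(pc0$mean_diff, 0)
  expect_equal(pc0$hedges_g_av, 0)
  expect_true(is.na(pc0$t_stat))
  # constant shift: effect sizes defined, t degenerate
  expect_warning(pc <- paired_compare(c(1, 2, 3), c(2, 3, 4)),
                 class = "epi_degenerate_variance")
  expect_equal(pc$mean_diff, -1)
  expect_equal(pc$d_av, -1)
  expect_equal(pc$hedges_g_av, -1 * (1 - 3 / 7), tolerance = 1e-12)
  expect_equal(pc$hedges_g_av, -0.571429, tolerance = 1e-6)
  expect_error(paired_compare(1, 2), class = "epi_argument_error")
})

test_that("t and p agree with the reference implementation", {
  set.seed(123)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    a <- rnorm(n, mean = 0.2)
    b <- rnorm(n)
    pc <- paired_compare(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(pc$t_stat, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(pc$p_two_tailed, ref$p.value, tolerance = 1e-8)
    expect_equal(pc$mean_diff, unname(ref$estimate), tolerance = 1e-10)
  }
})

test_that("overlap_table assembles one row per method and deviation", {
  d <- c(8, 8, 4)
  S <- array(0, d); S[2:6, 2:6, 2:3] <- 1
  jp <- jacobians(rand_smooth_field(d, seed = 2, max_slope = 0.5))
  tab <- overlap_table(list(am = vol_of(S, vox = 1), wa = vol_of(S, vox = 1)),
                       vol_of(S, vox = 1), vol_of(jp$jac_up, vox = 1))
  expect_equal(nrow(tab), 8)
  expect_setequal(unique(tab$method), c("am", "wa"))
  expect_true(all(tab$overlap == 100))
})
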