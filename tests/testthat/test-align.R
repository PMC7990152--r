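test_that("rigid transforms compose, invert and serialize consistently", {
  set.seed(21)
  for (i in 1:20) {
    tr <- rigid_transform(runif(3, -20, 20), runif(3, -5, 5))
    R <- rotation_matrix(tr)
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
    inv <- invert_transform(tr)
    # composing forward and inverse about a shared center gives identity
    cen <- c(3, -2, 7)
    p <- matrix(runif(15, -10, 10), ncol = 3)
    back <- transform_points(inv, transform_points(tr, p, cen), cen)
    expect_lt(max(abs(back - p)), 1e-9)
  }
  tr <- rigid_transform(c(2, -1.5, 1), c(1.5, -1, 0.8))
  path <- file.path(withr::local_tempdir(), "t.json")
  write_transform(tr, path)
  back <- read_transform(path)
  expect_equal(back$rotation_deg, tr$rotation_deg)
  expect_equal(back$translation_mm, tr$translation_mm)
})

test_that("identity resampling reproduces the input", {
  vol <- make_blob_volume(24, seed = 5)
  out_n <- resample_volume(vol, rigid_transform(), vol, "nearest")
  expect_identical(out_n$values, vol$values)
  out_l <- resample_volume(vol, rigid_transform(), vol, "linear")
  expect_lt(max(abs(out_l$values - vol$values)), 1e-6)
})

test_that("integer voxel translations shift the grid exactly", {
  vol <- make_blob_volume(16, seed = 6, spacing = 0.25)
  # transform maps moving -> fixed with +2 voxels along x, so the content
  # appears shifted by +2 in the output array
  tr <- rigid_transform(translation_mm = c(2 * 0.25, 0, 0))
  out <- resample_volume(vol, tr, vol, "nearest", fill = -99)
  expect_identical(out$values[3:16, , ], vol$values[1:14, , ])
  expect_true(all(out$values[1:2, , ] == -99))
})

test_that("nearest-neighbor resampling never invents intensities", {
  vol <- make_blob_volume(20, seed = 8)
  vol$values <- round(vol$values / 100) * 100 # coarse value set
  tr <- rigid_transform(c(4, -3, 7), c(0.6, -0.4, 0.9))
  out <- resample_volume(vol, tr, vol, "nearest", fill = 0)
  expect_true(all(out$values %in% c(0, unique(as.vector(vol$values)))))
})

test_that("resampling by a transform then its inverse restores the image", {
  vol <- make_blob_volume(32, seed = 9)
  tr <- rigid_transform(c(5, -4, 3), c(1.1, -0.7, 0.9))
  fwd <- resample_volume(vol, tr, vol, "linear")
  back <- resample_volume(fwd, invert_transform(tr), vol, "linear")
  core <- 3:30 # interior, away from the resampling margin
  rng <- diff(range(vol$values))
  mae <- mean(abs(back$values[core, core, core] -
                    vol$values[core, core, core]))
  expect_lt(mae, 0.02 * rng)
})

test_that("masks demand nearest-neighbor interpolation", {
  m <- ball_mask(10, 3)
  expect_error(resample_mask(m, rigid_transform(), m, "linear"),
               "nearest")
})

test_that("self-registration returns the identity", {
  vol <- make_blob_volume(32, seed = 10)
  r <- register_rigid(vol, vol, levels = c(2, 1),
                      max_iterations = c(200, 100))
  expect_lt(max(abs(r$transform$rotation_deg)), 0.05)
  expect_lt(max(abs(r$transform$translation_mm)), 0.05)
})

test_that("registration recovers a known misalignment on smooth content", {
  fixed <- make_blob_volume(40, seed = 11, spacing = 0.25)
  tru <- rigid_transform(c(4, -2, 3), c(0.8, -0.6, 0.5))
  # moving sampled from fixed under the inverse, so moving -> fixed = tru
  moving <- resample_volume(fixed, invert_transform(tru), fixed, "linear")
  r <- register_rigid(moving, fixed, levels = c(2, 1),
                      max_iterations = c(400, 200))
  expect_lt(max(abs(r$transform$rotation_deg - tru$rotation_deg)), 0.5)
  expect_lt(max(abs(r$transform$translation_mm - tru$translation_mm)),
            0.5 * 0.25)
  expect_lte(r$loss_final, r$loss_init)
})

test_that("registration reports its loss so poor optima are detectable", {
  fixed <- make_blob_volume(24, seed = 12)
  moving <- resample_volume(fixed,
                            rigid_transform(translation_mm = c(-1, 0.5, 0)),
                            fixed, "linear")
  far <- rigid_transform(translation_mm = c(15, 15, 15))
  r <- register_rigid(moving, fixed, init = far, levels = 2,
                      max_iterations = 30)
  expect_true(is.finite(r$loss_final))
  expect_true(is.finite(r$loss_init))
  # monotone acceptance: never worse than the init it was given
  expect_lte(r$loss_final, r$loss_init)
  expect_error(register_rigid(volume_image(array(1, c(4, 4, 4)), 1),
                              volume_image(array(1, c(4, 4, 4)), 1)),
               "constant")
})
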