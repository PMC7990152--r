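test_that("parameter validation pins the CFL bound and window order", {
  p <- level_set_params()
  expect_equal(p$time_step, 0.45 / 1.6)
  expect_error(level_set_params(low = 600, high = 300), "below")
  expect_error(level_set_params(time_step = 0.5), "CFL")
  expect_error(level_set_params(curvature_weight = -1), ">= 0")
  p0 <- level_set_params(curvature_weight = 0)
  expect_equal(p0$time_step, 0.45)
})

test_that("the speed field is the min-of-ramps threshold profile", {
  grid <- volume_image(array(c(450, 300, 600, 700, 250, 150, 440, 460),
                             c(2, 2, 2)), 0.16)
  grid$unit_state <- "normalized"
  f <- feature_speed(grid, 300, 600)
  expect_equal(f$values[1, 1, 1], 150) # window midpoint, maximal speed
  expect_equal(f$values[2, 1, 1], 0)   # exactly at low
  expect_equal(f$values[1, 2, 1], 0)   # exactly at high
  expect_equal(f$values[2, 2, 1], -100) # above high
  expect_equal(f$values[1, 1, 2], -50)  # below low
  expect_true(all((f$values > 0) ==
                    (grid$values > 300 & grid$values < 600)))
})

test_that("initialization gives a signed distance to the in-window set", {
  ball <- make_ball(31, 9)
  field <- initialize_level_set(ball, 300, 600)
  inside <- field$values < 0
  # the 1-voxel opening may reassign a few corner voxels of the digital
  # ball; the classification must otherwise match the in-window set
  expect_lt(mean(xor(inside, ball$values == 450)), 0.01)
  # |grad phi| ~ 1 in the band after reinitialization (0.8 - 1.2)
  g <- array(0, dim(field$values))
  phi <- field$values
  gx <- (phi[c(2:31, 31), , ] - phi[c(1, 1:30), , ]) / 2
  gy <- (phi[, c(2:31, 31), ] - phi[, c(1, 1:30), ]) / 2
  gz <- (phi[, , c(2:31, 31)] - phi[, , c(1, 1:30)]) / 2
  gm <- sqrt(gx^2 + gy^2 + gz^2)
  band <- abs(phi) > 0.6 & abs(phi) < 3 # interior stencil region
  # central differences kink where the nearest surface voxel switches;
  # the bulk of the band must still have unit gradient
  expect_gt(quantile(gm[band], 0.05), 0.7)
  expect_lt(quantile(gm[band], 0.95), 1.2)
  expect_true(median(gm[band]) > 0.8 && median(gm[band]) < 1.2)
  expect_lt(abs(mean(gm[band]) - 1), 0.1)
  # out-of-window volume raises the dedicated error condition
  flat <- volume_image(array(0, c(8, 8, 8)), 0.16)
  flat$unit_state <- "normalized"
  expect_error(initialize_level_set(flat, 300, 600),
               class = "graftquant_empty_window")
})

test_that("opening removes isolated in-window voxels at initialization", {
  vol <- make_ball(21, 6)
  vol$values[2, 2, 2] <- 450 # isolated speck
  field <- initialize_level_set(vol, 300, 600)
  expect_false(field$values[2, 2, 2] < 0)
  expect_true(field$values[11, 11, 11] < 0)
})

test_that("zero curvature reduces the level set to double thresholding", {
  # two blobs and a hole: classification must match the window exactly
  vol <- make_ball(35, 10)
  vol$values[26:32, 26:32, 26:32] <- 450
  vol$values[16:18, 16:18, 16:18] <- 700 # out-of-window core
  seg <- segment_bone(vol, params = level_set_params(curvature_weight = 0))
  expect_identical(seg$mask$values,
                   vol$values >= 300 & vol$values <= 600)
})

test_that("spheres are recovered within 3 percent at default parameters", {
  for (r in c(10, 12, 15)) {
    vol <- make_ball(2 * r + 15, r)
    seg <- segment_bone(vol, params = level_set_params())
    analytic <- 4 / 3 * pi * r^3 * voxel_volume(vol)
    expect_lt(abs(measure_volume(seg$mask) - analytic) / analytic, 0.03,
              label = paste("radius", r))
  }
})

test_that("a uniformly negative speed retreats the front to nothing", {
  m <- ball_mask(25, 8)
  phi <- array(graftquant:::cpp_signed_distance(as.logical(m$values),
                                                dim(m$values)),
               dim(m$values))
  field <- structure(list(values = phi, spacing = rep(0.16, 3),
                          origin = c(0, 0, 0)), class = "level_set_field")
  speed <- volume_image(array(-1, dim(m$values)), 0.16)
  prev <- sum(m$values)
  shrinking <- TRUE
  for (iters in c(20, 40, 80, 160, 400)) {
    out <- evolve_level_set(field, speed,
                            level_set_params(curvature_weight = 0,
                                             max_iterations = iters),
                            speed_scale = 1)
    cnt <- sum(out$values < 0)
    shrinking <- shrinking && cnt <= prev
    prev <- cnt
  }
  expect_true(shrinking)
  expect_identical(prev, 0L)
})

test_that("curvature weighting smooths a noisy sphere surface", {
  set.seed(41)
  vol <- make_ball(37, 12)
  vol$values <- vol$values + array(rnorm(length(vol$values), 0, 80),
                                   dim(vol$values))
  s_smooth <- segment_bone(vol, params = level_set_params())
  s_rough <- segment_bone(vol,
                          params = level_set_params(curvature_weight = 0))
  expect_lte(face_count(s_smooth$mask$values),
             face_count(s_rough$mask$values))
})

test_that("evolution stays finite over a battery of random scenes", {
  for (s in 1:5) {
    set.seed(50 + s)
    vol <- make_blob_volume(24, k = 4, seed = 50 + s, spacing = 0.16)
    vol$values <- vol$values - 200 # put part of the range in-window
    vol$unit_state <- "normalized"
    seg <- tryCatch(
      segment_bone(vol, params = level_set_params(max_iterations = 150)),
      graftquant_empty_window = function(e) NULL)
    if (!is.null(seg)) expect_true(all(is.finite(seg$field$values)))
  }
})

test_that("the interior mask is the strict negative set of phi", {
  vol <- make_ball(25, 8)
  seg <- segment_bone(vol, params = level_set_params())
  m <- level_set_mask(seg$field)
  expect_identical(m$values, seg$field$values < 0)
  expect_identical(sum(m$values) + sum(seg$field$values >= 0),
                   length(m$values))
})
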