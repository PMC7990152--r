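test_that("normalization maps to mean 0 / SD 1000 with population SD", {
  vals <- array(rep(c(-1, 1), 32), c(4, 4, 4))
  out <- normalize_intensity(volume_image(vals, 0.16))
  expect_identical(sort(unique(as.vector(out$values))), c(-1000, 1000))
  set.seed(31)
  vol <- volume_image(array(rnorm(8^3, 50, 7), c(8, 8, 8)), 0.16)
  n <- normalize_intensity(vol)
  expect_lt(abs(mean(n$values)), 1e-6 * 1000)
  sd_pop <- sqrt(mean((n$values - mean(n$values))^2))
  expect_lt(abs(sd_pop - 1000) / 1000, 1e-6)
  expect_identical(n$unit_state, "normalized")
})

test_that("normalization is affine-invariant and idempotent", {
  set.seed(32)
  vol <- volume_image(array(rnorm(6^3, 120, 40), c(6, 6, 6)), 0.16)
  n1 <- normalize_intensity(vol)
  shifted <- volume_image(3.7 * vol$values + 250, vol$spacing)
  n2 <- normalize_intensity(shifted)
  expect_lt(max(abs(n1$values - n2$values)), 1e-6 * 1000)
  n11 <- normalize_intensity(n1)
  expect_lt(max(abs(n11$values - n1$values)) / 1000, 1e-9)
  expect_error(normalize_intensity(volume_image(array(5, c(3, 3, 3)), 1)),
               "constant")
})

test_that("normalization scope can be restricted to a mask", {
  set.seed(33)
  vol <- volume_image(array(rnorm(6^3, 0, 10), c(6, 6, 6)), 1)
  mask <- binary_mask(array(rep(c(TRUE, FALSE), length.out = 6^3),
                            c(6, 6, 6)), 1)
  n <- normalize_intensity(vol, mask = mask)
  inm <- n$values[mask$values]
  expect_lt(abs(mean(inm)), 1e-3)
  expect_lt(abs(sqrt(mean((inm - mean(inm))^2)) - 1000) / 1000, 1e-6)
})

test_that("integer-factor downsampling is block averaging", {
  const <- volume_image(array(7, c(8, 8, 8)), 0.08)
  down <- downsample_volume(const, 0.16)
  expect_identical(dim(down$values), c(4L, 4L, 4L))
  expect_true(all(down$values == 7))
  expect_equal(down$spacing, rep(0.16, 3))
  # checkerboard averages to the midpoint
  co <- expand.grid(1:8, 1:8, 1:8)
  chk <- array(ifelse((co[, 1] + co[, 2] + co[, 3]) %% 2 == 0, 0, 1000),
               c(8, 8, 8))
  d2 <- downsample_volume(volume_image(chk, 0.08), 0.16)
  expect_true(all(d2$values == 500))
  expect_error(downsample_volume(const, 0.04), "finer")
})

test_that("downsampling conserves total intensity mass", {
  vol <- make_blob_volume(32, seed = 34, spacing = 0.08)
  down <- downsample_volume(vol, 0.16)
  mass_in <- sum(vol$values) * voxel_volume(vol)
  mass_out <- sum(down$values) * voxel_volume(down)
  expect_lt(abs(mass_out - mass_in) / mass_in, 0.005)
  # non-integer factor path stays finite and near the right extent
  d3 <- downsample_volume(vol, 0.20)
  expect_true(all(is.finite(d3$values)))
  expect_equal(d3$spacing, rep(0.20, 3))
})

test_that("metal detection flags the screw and only the screw", {
  spec <- phantom_spec(noise_sigma = 0)
  lab <- build_labels(spec)
  nb <- normalize_intensity(simulate_scan(lab, spec, "baseline"))
  metal <- detect_metal(nb)
  truth <- lab$values == phantom_label_codes()[["metal"]]
  expect_true(all(metal$values[truth]))
  expect_lte(sum(metal$values) / sum(truth), 3)
  # plain thresholding without dilation
  m0 <- detect_metal(nb, dilate_mm = 0)
  expect_lte(sum(m0$values), sum(metal$values))
  # no screw, nothing detected
  spec2 <- phantom_spec(noise_sigma = 0, screw_radius = 0)
  lab2 <- build_labels(spec2)
  nb2 <- normalize_intensity(simulate_scan(lab2, spec2, "baseline"))
  expect_identical(sum(detect_metal(nb2)$values), 0L)
  expect_error(detect_metal(simulate_scan(lab, spec, "baseline")),
               "normalized")
})

test_that("ROI assembly honors exclusion geometry and metal masks", {
  vol <- volume_image(array(0, c(10, 10, 10)), 1)
  full <- build_roi_mask(vol)
  expect_true(all(full$values))
  half <- build_roi_mask(vol, exclusions = list(
    list(type = "halfspace", normal = c(1, 0, 0), offset = 4)))
  expect_identical(sum(half$values), 5L * 100L) # x in {5..9} survives
  box <- build_roi_mask(vol, exclusions = list(
    list(type = "box", min = c(0, 0, 0), max = c(9, 9, 4))))
  expect_identical(sum(box$values), 5L * 100L) # z in {5..9} survives
  expect_error(build_roi_mask(vol, exclusions = list(
    list(type = "halfspace", normal = c(1, 0, 0), offset = 100))),
    "empty")
})

test_that("level-set upscaling preserves volume within 2 percent", {
  m <- ball_mask(41, 14, spacing = 0.16)
  phi <- array(graftquant:::cpp_signed_distance(as.logical(m$values),
                                                dim(m$values)),
               dim(m$values))
  field <- structure(list(values = phi, spacing = m$spacing,
                          origin = m$origin), class = "level_set_field")
  fine <- upsample_mask(field, 0.08)
  expect_lt(abs(measure_volume(fine) - measure_volume(m)) /
              measure_volume(m), 0.02)
})

test_that("nearest-neighbor mask upscaling replicates voxels in blocks", {
  m <- binary_mask(array(FALSE, c(5, 5, 5)), 0.16)
  m$values[3, 3, 3] <- TRUE
  fine <- upsample_mask(m, 0.08)
  expect_identical(dim(fine$values), c(10L, 10L, 10L))
  expect_identical(sum(fine$values), 8L) # a 2 x 2 x 2 block
  empty <- binary_mask(array(FALSE, c(5, 5, 5)), 0.16)
  expect_identical(sum(upsample_mask(empty, 0.08)$values), 0L)
  expect_error(upsample_mask(m, 0.32), "coarser")
})
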