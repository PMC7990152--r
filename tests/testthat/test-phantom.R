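test_that("label grid realizes the mandible-angle scene", {
  spec <- small_spec()
  lab <- build_labels(spec)
  codes <- phantom_label_codes()
  expect_setequal(unique(as.vector(lab$values)), unname(codes))
  # graft volume close to the analytic block volume
  vg <- sum(lab$values == codes[["graft"]]) * voxel_volume(lab)
  # screw removes a small core from the block; compare against the block
  # minus the embedded screw cylinder
  analytic <- prod(spec$graft_size) -
    pi * spec$screw_radius^2 * spec$graft_size[1]
  expect_lt(abs(vg - analytic) / analytic, 0.10)
  # graft touches the slab's cortical face: some graft voxel has a -x
  # neighbor labeled cortical
  g <- which(lab$values == codes[["graft"]], arr.ind = TRUE)
  face_touch <- lab$values[cbind(g[, 1] - 1, g[, 2], g[, 3])]
  expect_true(any(face_touch == codes[["cortical"]]))
  # screw intersects both graft region and slab
  s <- which(lab$values == codes[["metal"]], arr.ind = TRUE)
  xs <- (s[, 1] - 1) * spec$spacing
  expect_true(any(xs <= spec$slab_thickness))
  expect_true(any(xs > spec$slab_thickness))
  # determinism
  expect_identical(build_labels(spec)$values, lab$values)
})

test_that("degenerate phantom geometry is rejected", {
  expect_error(small_spec(graft_size = c(0, 5, 5)), "positive")
  expect_error(small_spec(graft_size = c(9, 5, 5)), "field of view")
  expect_error(phantom_spec(mu = c(soft = 10, trabecular = 5,
                                   cortical = 60, metal = 100)),
               "metal > cortical")
  expect_error(phantom_spec(followup_volume_fraction = -0.1), ">= 0")
})

test_that("volume change hits any target fraction on a ball", {
  m <- ball_mask(61, 25)
  n0 <- sum(m$values)
  half <- apply_volume_change(m, 0.5)
  expect_lt(abs(sum(half$values) / n0 - 0.5), 0.01)
  # shrinkage by uniform offset: result is close to the ball of radius
  # 25 / 2^(1/3) (continuum scaling)
  r_expect <- 25 / 2^(1 / 3)
  idx <- which(half$values, arr.ind = TRUE)
  rr <- sqrt(rowSums(sweep(idx, 2, 31)^2))
  expect_lt(max(rr), r_expect + 1.8)
  expect_true(all(half$values[m$values == FALSE] == FALSE)) # subset
  # identity and emptying
  expect_identical(apply_volume_change(m, 1)$values, m$values)
  expect_identical(sum(apply_volume_change(m, 0)$values), 0L)
  # growth
  grown <- apply_volume_change(m, 1.4)
  expect_lt(abs(sum(grown$values) / n0 - 1.4), 0.01)
  expect_true(all(grown$values[m$values]))
  # growth constrained to an impossible region errors
  allowed <- binary_mask(array(FALSE, dim(m$values)), m$spacing)
  expect_error(apply_volume_change(m, 1.4, allowed = allowed),
               "unreachable")
  expect_error(apply_volume_change(m, -1), ">= 0")
})

test_that("noiseless blur-free scans reproduce the class attenuations", {
  spec <- small_spec()
  lab <- build_labels(spec)
  scan <- simulate_scan(lab, spec, "baseline")
  mu <- spec$mu
  by_code <- c(mu[["soft"]], mu[["trabecular"]], mu[["cortical"]],
               mu[["cortical"]], mu[["metal"]])
  for (k in 0:4) {
    vox <- scan$values[lab$values == k]
    if (length(vox)) expect_identical(unique(vox), by_code[k + 1])
  }
})

test_that("scan simulation is deterministic under a fixed seed", {
  spec <- small_spec(noise_sigma = 3, seed = 42L)
  lab <- build_labels(spec)
  a <- simulate_scan(lab, spec, "baseline")
  b <- simulate_scan(lab, spec, "baseline")
  expect_identical(a$values, b$values)
  # the two timepoints draw different noise
  f <- simulate_scan(lab, spec, "followup")
  expect_false(identical(a$values, f$values))
})

test_that("per-scan gain/offset vanishes after intensity normalization", {
  spec1 <- small_spec(noise_sigma = 2, blur_sigma = 0.3)
  spec2 <- small_spec(noise_sigma = 2, blur_sigma = 0.3,
                      gain = c(2, 2), offset = c(500, 500))
  lab <- build_labels(spec1)
  n1 <- normalize_intensity(simulate_scan(lab, spec1, "baseline"))
  n2 <- normalize_intensity(simulate_scan(lab, spec2, "baseline"))
  expect_lt(max(abs(n1$values - n2$values)), 1e-6 * 1000)
})

test_that("generated pairs carry exact ground-truth volume arithmetic", {
  spec <- small_spec(followup_volume_fraction = 0.5)
  pair <- generate_pair(spec)
  vv <- voxel_volume(pair$truth$labels_baseline)
  codes <- phantom_label_codes()
  expect_identical(pair$truth$graft_volume_baseline,
                   sum(pair$truth$labels_baseline$values ==
                         codes[["graft"]]) * vv)
  expect_identical(pair$truth$graft_volume_followup,
                   sum(pair$truth$labels_followup$values ==
                         codes[["graft"]]) * vv)
  ratio <- pair$truth$graft_volume_followup /
    pair$truth$graft_volume_baseline
  expect_lt(abs(ratio - 0.5), 0.01)
  # apposition regime
  pg <- generate_pair(small_spec(followup_volume_fraction = 1.4))
  expect_lt(abs(pg$truth$graft_volume_followup /
                  pg$truth$graft_volume_baseline - 1.4), 0.01)
})

test_that("identity misalignment changes labels only in the graft class", {
  spec <- small_spec(followup_volume_fraction = 0.6)
  pair <- generate_pair(spec)
  l0 <- pair$truth$labels_baseline$values
  l6 <- pair$truth$labels_followup$values
  differs <- l0 != l6
  expect_true(all(l0[differs] %in% c(0L, 3L)))
  expect_true(all(l6[differs] %in% c(0L, 3L)))
})

test_that("the ROI isolates the graft from slab and screw", {
  spec <- small_spec(followup_volume_fraction = 1)
  pair <- generate_pair(spec)
  codes <- phantom_label_codes()
  lab <- pair$truth$labels_baseline$values
  roi <- pair$roi$values
  # the graft lies inside the ROI except for the shell the dilated screw
  # exclusion removes around the hardware
  graft <- lab == codes[["graft"]]
  expect_gt(mean(roi[graft]), 0.90)
  d2_metal <- array(graftquant:::cpp_edt_sq(
    as.logical(lab == codes[["metal"]]), dim(lab),
    pair$truth$labels_baseline$spacing), dim(lab))
  expect_true(all(d2_metal[graft & !roi] <= 0.5^2 + 1e-9))
  slab <- lab %in% codes[c("trabecular", "cortical")]
  expect_gte(mean(!roi[slab]), 0.99)
  expect_true(all(!roi[lab == codes[["metal"]]]))
})

test_that("measurement-level trial simulation is valid and seeded", {
  tab <- simulate_trial_measurements(n_patients = 6, seed = 3L)
  expect_identical(nrow(tab), 24L)
  expect_silent(validate_measurements(tab))
  expect_identical(simulate_trial_measurements(n_patients = 6, seed = 3L),
                   tab)
  expect_false(identical(
    simulate_trial_measurements(n_patients = 6, seed = 4L), tab))
  expect_true(all(tab$volume_mm3 >= 0))
})
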