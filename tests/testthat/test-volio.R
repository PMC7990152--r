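test_that("volume round-trips bit-exactly through MetaImage and NIfTI", {
  set.seed(11)
  arr <- array(rnorm(3 * 4 * 5, 100, 50), c(3, 4, 5)) # asymmetric extents
  vol <- volume_image(arr, c(0.08, 0.08, 0.08), origin = c(1, 2, 3))
  for (ext in c(".mha", ".mhd", ".nii", ".nii.gz")) {
    path <- file.path(withr::local_tempdir(), paste0("vol", ext))
    write_volume(vol, path)
    back <- read_volume(path)
    expect_identical(dim(back$values), c(3L, 4L, 5L), label = ext)
    expect_identical(back$values, vol$values, label = ext)
    expect_lt(max(abs(back$spacing - vol$spacing)), 1e-6)
    expect_lt(max(abs(back$origin - vol$origin)), 1e-6)
    expect_identical(back$unit_state, "raw")
  }
})

test_that("MetaImage and NIfTI encodings of one volume agree", {
  set.seed(12)
  vol <- volume_image(array(runif(64, -500, 2000), c(4, 4, 4)), 0.16)
  dir <- withr::local_tempdir()
  write_volume(vol, file.path(dir, "a.mha"))
  write_volume(vol, file.path(dir, "a.nii.gz"))
  a <- read_volume(file.path(dir, "a.mha"))
  b <- read_volume(file.path(dir, "a.nii.gz"))
  expect_lt(max(abs(a$values - b$values)), 1e-9)
  expect_lt(max(abs(a$spacing - b$spacing)), 1e-6)
})

test_that("masks round-trip through 8-bit storage", {
  set.seed(13)
  m <- binary_mask(array(runif(60) > 0.5, c(3, 4, 5)), 0.16)
  dir <- withr::local_tempdir()
  for (ext in c(".mha", ".nii.gz")) {
    path <- file.path(dir, paste0("m", ext))
    write_mask(m, path)
    back <- read_mask(path)
    expect_identical(back$values, m$values, label = ext)
    expect_true(is.logical(back$values))
  }
})

test_that("normalized unit state survives a write/read cycle via sidecar", {
  vol <- volume_image(array(rnorm(27), c(3, 3, 3)), 0.16)
  nvol <- normalize_intensity(vol)
  path <- file.path(withr::local_tempdir(), "n.mha")
  write_volume(nvol, path)
  expect_identical(read_volume(path)$unit_state, "normalized")
  # overwriting with a raw volume clears the flag
  write_volume(vol, path)
  expect_identical(read_volume(path)$unit_state, "raw")
})

test_that("invalid volumes and headers are rejected explicitly", {
  dir <- withr::local_tempdir()
  expect_error(read_volume(file.path(dir, "absent.mha")), "not found")
  writeLines("junk", file.path(dir, "vol.xyz"))
  expect_error(read_volume(file.path(dir, "vol.xyz")), "format")
  # header with zero spacing on one axis
  bad <- file.path(dir, "bad.mha")
  payload <- writeBin(as.double(1:8), raw(), size = 8)
  header <- paste0("ObjectType = Image\nNDims = 3\nBinaryData = True\n",
                   "ElementSpacing = 0.08 0 0.08\nDimSize = 2 2 2\n",
                   "ElementType = MET_DOUBLE\nElementDataFile = LOCAL\n")
  con <- file(bad, "wb")
  writeChar(header, con, eos = NULL)
  writeBin(as.double(1:8), con, size = 8)
  close(con)
  expect_error(read_volume(bad), "spacing")
  # non-identity direction matrix
  rot <- file.path(dir, "rot.mha")
  header2 <- sub("ElementSpacing = 0.08 0 0.08",
                 paste("TransformMatrix = 0 1 0 -1 0 0 0 0 1\n",
                       "ElementSpacing = 0.08 0.08 0.08"), header)
  con <- file(rot, "wb")
  writeChar(header2, con, eos = NULL)
  writeBin(as.double(1:8), con, size = 8)
  close(con)
  expect_error(read_volume(rot), "axis-aligned")
  expect_error(volume_image(array(1, c(2, 2)), 0.1), "3D")
  expect_error(volume_image(array(c(1, NA), c(2, 1, 1)), 0.1), "finite")
  expect_error(volume_image(array(1, c(2, 2, 2)), c(0.1, -1, 0.1)),
               "spacing")
})

test_that("trial volume fixture loads with the published structure", {
  tab <- load_graft_volumes()
  expect_identical(nrow(tab), 38L) # 9 complete patients + 8606 baselines
  nine <- tab[tab$patient_id != "8606", ]
  expect_identical(nrow(nine), 36L)
  expect_identical(
    tab$volume_mm3[tab$patient_id == "8096" & tab$side == "Dx" &
                     tab$timepoint == "baseline"], 159)
  expect_setequal(unique(tab$timepoint), c("baseline", "6mo"))
})

test_that("measurement table validation catches malformed input", {
  tab <- load_graft_volumes()
  expect_silent(validate_measurements(tab))
  expect_error(validate_measurements(rbind(tab, tab[1, ])), "duplicate")
  bad <- tab; bad$volume_mm3[3] <- -1
  expect_error(validate_measurements(bad), "non-negative")
  bad <- tab; bad$treated_side[1] <- "Sin"
  expect_error(validate_measurements(bad), "treated_side")
  bad <- tab; bad$side[2] <- "left"
  expect_error(validate_measurements(bad), "side")
  # header-only CSV reads as an empty table
  p <- file.path(withr::local_tempdir(), "empty.csv")
  writeLines("patient_id,treated_side,side,timepoint,volume_mm3", p)
  expect_identical(nrow(read_measurements(p)), 0L)
})

test_that("measurement tables round-trip through CSV", {
  tab <- load_graft_volumes()
  p <- file.path(withr::local_tempdir(), "vols.csv")
  write_measurements(tab, p)
  back <- read_measurements(p)
  expect_equal(back, tab)
})
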