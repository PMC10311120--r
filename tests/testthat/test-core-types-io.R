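test_that("image_plane enforces its invariants", {
  expect_error(image_plane(matrix(1, 8, 8), 25), "16 x 16")
  m <- matrix(1, 32, 32); m[5, 5] <- NA
  expect_error(image_plane(m, 25), "finite")
  expect_error(image_plane(matrix(1, 32, 32), -1), "positive")
  p <- image_plane(matrix(1.5, 32, 32), 25, modality = "FLUO", channel_name = "ch")
  expect_identical(dim(p), c(32L, 32L))
  expect_equal(p$pixel_size_nm, 25)
})

test_that("TIFF write/read round-trips pixels and pixel size", {
  p <- ramp_plane()
  f <- withr::local_tempfile(fileext = ".tif")
  write_image(p, f)
  r <- read_image(f, modality = "EM")
  expect_equal(r$pixels, p$pixels, tolerance = 1e-7)  # float32 storage
  expect_equal(r$pixel_size_nm, 25)
  # integer-valued data round-trips exactly through 32-bit float
  pi_ <- image_plane(matrix(as.numeric(0:1023), 32), 10, modality = "FLUO")
  write_image(pi_, f)
  expect_identical(read_image(f)$pixels, pi_$pixels)
})

test_that("16-bit integer TIFFs load unrescaled", {
  f <- withr::local_tempfile(fileext = ".tif")
  vals <- matrix(c(0L, 1L, 1000L, 65535L)[sample.int(4, 1024, TRUE)], 32)
  tiff::writeTIFF(vals / 65535, f, bits.per.sample = 16L)
  r <- read_image(f, pixel_size_nm_override = 25)
  expect_identical(sort(unique(as.integer(r$pixels))), sort(unique(as.integer(vals))))
  expect_equal(max(r$pixels), 65535)
  # histogram identical to the stored data
  expect_identical(tabulate(as.integer(r$pixels) + 1L, 65536L),
                   tabulate(as.integer(vals) + 1L, 65536L))
})

test_that("resolution tags are read with unit conversion (40 px/um -> 25 nm)", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(1024), 32), f, bits.per.sample = 32L,
                  compression = "none")
  # 40 px/um = 400000 px/cm
  clemsim:::tiff_set_resolution(f, px_per_cm = 400000)
  r <- read_image(f)
  expect_equal(r$pixel_size_nm, 1e3 / 40, tolerance = 1e-6)
})

test_that("missing pixel size and non-grayscale input are hard errors", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(1024), 32), f, bits.per.sample = 32L)
  expect_error(read_image(f), "pixel_size_nm_override")
  expect_equal(read_image(f, pixel_size_nm_override = 30)$pixel_size_nm, 30)
  rgb <- array(runif(32 * 32 * 3), c(32, 32, 3))
  tiff::writeTIFF(rgb, f)
  expect_error(read_image(f, pixel_size_nm_override = 25), "grayscale")
  expect_error(read_image("no/such/file.tif"), "no such file")
})

test_that("transform XML round-trips losslessly and errors are informative", {
  f <- withr::local_tempfile(fileext = ".xml")
  r0 <- transform_record(0, 1, 0, 0, 25)
  write_transform_xml(r0, f)
  expect_equal(read_transform_xml(f)[1:5], r0[1:5])

  r1 <- transform_record(90, 1.02, 12.5, -3.25, 25.0,
                         moving_name = "sim", fixed_name = "em")
  write_transform_xml(r1, f)
  back <- read_transform_xml(f)
  for (fld in c("theta_deg", "scale", "tx_px", "ty_px", "pixel_size_nm"))
    expect_lt(abs(back[[fld]] - r1[[fld]]) / max(1, abs(r1[[fld]])), 1e-9)
  expect_equal(back$moving_name, "sim")

  # irrational parameters still round-trip to <= 1e-9 relative
  r2 <- transform_record(180 / pi * 0.7, sqrt(2), pi * 10, -exp(1), 25)
  write_transform_xml(r2, f)
  back2 <- read_transform_xml(f)
  for (fld in c("theta_deg", "scale", "tx_px", "ty_px"))
    expect_lt(abs(back2[[fld]] - r2[[fld]]) / abs(r2[[fld]]), 1e-9)

  writeLines('<similarity_transform theta_deg="1" tx_px="0" ty_px="0" pixel_size_nm="25"/>', f)
  expect_error(read_transform_xml(f), "scale")
  writeLines("<not_a_transform/>", f)
  expect_error(read_transform_xml(f), "similarity_transform")
})

test_that("overlay composes EM base and tinted channels", {
  f <- withr::local_tempfile(fileext = ".png")
  em <- ramp_plane()
  # EM only: grayscale RGB
  write_overlay(em, list(), f)
  rgb <- png::readPNG(f)
  expect_equal(rgb[, , 1], rgb[, , 2])
  expect_equal(rgb[, , 2], rgb[, , 3])

  # all-zero channel leaves the EM base untouched
  zero_ch <- image_plane(matrix(0, 32, 32), 25, "FLUO")
  write_overlay(em, list(zero_ch), f)
  rgb2 <- png::readPNG(f)
  expect_equal(rgb2, rgb, tolerance = 1 / 255)

  # single bright punctum on constant EM: overlay max sits at the punctum
  emc <- image_plane(matrix(0.5, 32, 32), 25, "EM")
  ch <- matrix(0, 32, 32); ch[20, 11] <- 5
  write_overlay(emc, list(image_plane(ch, 25, "FLUO")), f)
  rgb3 <- png::readPNG(f)
  total <- rgb3[, , 1] + rgb3[, , 2] + rgb3[, , 3]
  expect_equal(as.integer(which(total == max(total), arr.ind = TRUE)[1, ]),
               c(20L, 11L))
  # shape mismatch is an error
  expect_error(write_overlay(em, list(image_plane(matrix(0, 64, 64), 25, "FLUO")), f),
               "shape")
})
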