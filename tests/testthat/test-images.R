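test_that("en_face_image and roi_mask enforce their invariants", {
  expect_error(en_face_image(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(en_face_image(matrix(0, 3, 3), nominal_pixel_size = 0),
               "positive")
  expect_error(en_face_image(matrix(0, 3, 3), axial_length = 19),
               "axial_length")
  expect_error(en_face_image(matrix(0, 3, 3), axial_length = 40),
               "axial_length")
  img <- en_face_image(matrix(0, 4, 6))
  expect_error(roi_mask(matrix(FALSE, 4, 6), img), "no TRUE")
  expect_error(roi_mask(matrix(TRUE, 3, 6), img), "do not match")
  expect_error(binary_mask(matrix(TRUE, 2, 2), pixel_size = -1), "positive")
  roi <- roi_mask(matrix(c(TRUE, rep(FALSE, 23)), 4, 6), img)
  m <- matrix(FALSE, 4, 6); m[2, 2] <- TRUE
  expect_error(binary_mask(m, 9.87, roi), "outside the ROI")
})

test_that("magnification correction follows the axial-length scaling", {
  img <- en_face_image(matrix(0, 4, 4), nominal_pixel_size = 9.87,
                       axial_length = 29.20)
  px <- correct_magnification(img, reference_axial_length = 23.95)
  expect_equal(attr(px, "factor"), (29.20 - 1.82) / (23.95 - 1.82),
               tolerance = 1e-12)
  expect_equal(as.numeric(px), 9.87 * 1.23724, tolerance = 1e-4)
  # identity when AL equals the reference
  img0 <- en_face_image(matrix(0, 4, 4), 9.87, 23.95)
  expect_equal(as.numeric(correct_magnification(img0)), 9.87)
  # the formula's singular point sits outside the plausible bounds
  expect_error(en_face_image(matrix(0, 4, 4), 9.87, axial_length = 1.82),
               "axial_length")
  expect_error(
    correct_magnification(img, reference_axial_length = 1.82),
    "reference_axial_length")
})

test_that("raster I/O round-trips PGM and CSV", {
  m <- matrix(sample(0:255, 30, TRUE), 5, 6)
  for (ext in c("pgm", "csv")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_raster(m, f)
    expect_equal(read_raster(f), m, ignore_attr = TRUE)
    unlink(f)
  }
  lg <- matrix(c(TRUE, FALSE), 4, 4)
  f <- tempfile(fileext = ".pgm")
  write_raster(lg, f)
  expect_equal(read_raster(f) > 0, lg, ignore_attr = TRUE)
  unlink(f)
  expect_error(read_raster(tempfile(fileext = ".bmp")), "not found")
})
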