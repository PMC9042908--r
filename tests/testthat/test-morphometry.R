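test_that("lesion size follows pixel count and corrected pixel size", {
  roi <- roi_mask(matrix(TRUE, 100, 100))
  bm <- binary_mask(matrix(TRUE, 100, 100), pixel_size = 10, roi = roi)
  expect_equal(cnv_size(bm, roi), 1.0)
  # 3300 px at 9.87 um/px
  r2 <- matrix(FALSE, 100, 100); r2[seq_len(3300)] <- TRUE
  roi2 <- roi_mask(r2)
  bm2 <- binary_mask(r2, pixel_size = 9.87, roi = roi2)
  expect_equal(cnv_size(bm2, roi2), 3300 * 0.00987^2, tolerance = 1e-10)
})

test_that("vessel density is the vessel/ROI pixel ratio", {
  roi <- roi_mask(matrix(TRUE, 10, 10))
  full <- binary_mask(matrix(TRUE, 10, 10), 9.87, roi)
  expect_equal(vessel_density(full, roi), 100)
  checker <- binary_mask(outer(1:10, 1:10, function(i, j)
    (i + j) %% 2 == 0), 9.87, roi)
  expect_equal(vessel_density(checker, roi), 50)
})

test_that("VLD and diameter index respect their identities", {
  roi <- roi_mask(matrix(TRUE, 10, 10))
  line <- matrix(FALSE, 10, 10); line[5, 1:5] <- TRUE
  expect_equal(vessel_length_density(line, roi), 5)
  empty <- matrix(FALSE, 10, 10)
  expect_equal(vessel_length_density(empty, roi), 0)
  expect_equal(vessel_diameter_index(42, 21), 2)
  expect_equal(vessel_diameter_index(33, 33), 1)
  expect_warning(v <- vessel_diameter_index(10, 0), "undefined")
  expect_true(is.na(v))
})

test_that("tortuosity is 1 for straight branches and pi/2 for a semicircle", {
  bar <- matrix(FALSE, 10, 40); bar[5, 3:37] <- TRUE
  expect_equal(as.numeric(vessel_tortuosity(skeletonize(bar))), 1,
               tolerance = 0.02)
  arc <- raster_arc(radius = 30, angle = pi)
  tor <- vessel_tortuosity(skeletonize(arc))
  expect_equal(as.numeric(tor), pi / 2, tolerance = 0.1)
  expect_identical(attr(tor, "n_eligible"), 1L)
})

test_that("loops and short stubs are excluded with a QC count", {
  t <- seq(0, 2 * pi, length.out = 720)
  m <- matrix(FALSE, 60, 60)
  m[cbind(round(30 + 15 * sin(t)), round(30 + 15 * cos(t)))] <- TRUE
  sk <- skeletonize(m)
  expect_warning(tor <- vessel_tortuosity(sk), "no eligible branch")
  expect_true(is.na(as.numeric(tor)))
  expect_gte(attr(tor, "n_excluded_loops"), 1L)
})

test_that("fractal dimension matches known fixtures", {
  expect_equal(as.numeric(fractal_dimension(make_fractal("line"))), 1,
               tolerance = 0.05)
  expect_equal(as.numeric(fractal_dimension(make_fractal("filled_square"))),
               2, tolerance = 0.05)
  fd_s <- as.numeric(fractal_dimension(make_fractal("sierpinski", 7)))
  expect_equal(fd_s, log(3) / log(2), tolerance = 0.03)
  # monotone in complexity: line < sierpinski < filled square
  expect_lt(as.numeric(fractal_dimension(make_fractal("line"))), fd_s)
  expect_lt(fd_s,
            as.numeric(fractal_dimension(make_fractal("filled_square"))))
  expect_error(fractal_dimension(matrix(c(TRUE, rep(FALSE, 63)), 8, 8)),
               "foreground")
  expect_error(fractal_dimension(make_fractal("line", size = 16)),
               "box sizes")
})

test_that("lacunarity: homogeneous 0, single pixel n-1, clumped > dispersed", {
  expect_equal(as.numeric(lacunarity(matrix(TRUE, 32, 32))), 0)
  one <- matrix(FALSE, 8, 8); one[3, 5] <- TRUE
  expect_equal(as.numeric(lacunarity(one, sizes = 1)), 63)
  set.seed(7)
  n <- 64
  clump <- matrix(FALSE, n, n)
  ctr <- cbind(sample(10:54, 8, TRUE), sample(10:54, 8, TRUE))
  for (i in 1:8)
    clump[cbind(ctr[i, 1] + sample(-3:3, 32, TRUE),
                ctr[i, 2] + sample(-3:3, 32, TRUE))] <- TRUE
  disp <- matrix(FALSE, n, n); disp[sample(n * n, sum(clump))] <- TRUE
  expect_gt(as.numeric(lacunarity(clump)), as.numeric(lacunarity(disp)))
})

test_that("compute_biomarkers satisfies the cross-metric invariants", {
  net <- make_vessel_network(vessel_network_spec(
    image_size = 200, n_branches = 4, noise_sd = 8, seed = 3))
  img <- en_face_image(net$image, axial_length = 27)
  roi <- full_roi(img)
  bm <- compute_biomarkers(img, roi)
  expect_s3_class(bm, "biomarker_set")
  expect_lte(bm$vessel_length_density, bm$vessel_density)
  expect_lte(bm$vessel_density, 100)
  expect_gte(bm$vessel_diameter_index, 1)
  expect_gte(bm$vessel_tortuosity, 1)
  qc <- attr(bm, "qc")
  expect_true(is.numeric(qc$otsu_threshold))
  expect_true(qc$fd_r_squared > 0.9)
})

test_that("ratio metrics are invariant to axial length; area scales squared", {
  net <- make_vessel_network(vessel_network_spec(
    image_size = 160, n_branches = 3, noise_sd = 0, seed = 2))
  roiM <- matrix(TRUE, 160, 160)
  b1 <- compute_biomarkers(en_face_image(net$image, axial_length = 24),
                           roi_mask(roiM))
  b2 <- compute_biomarkers(en_face_image(net$image, axial_length = 30),
                           roi_mask(roiM))
  for (f in c("vessel_density", "vessel_length_density",
              "vessel_diameter_index", "vessel_tortuosity",
              "fractal_dimension", "lacunarity"))
    expect_equal(b1[[f]], b2[[f]], tolerance = 1e-12)
  fac <- (30 - 1.82) / (24 - 1.82)
  expect_equal(b2$cnv_size / b1$cnv_size, fac^2, tolerance = 1e-9)
})

test_that("stage errors name the failing stage", {
  img <- en_face_image(matrix(5, 40, 40))
  expect_error(compute_biomarkers(img, full_roi(img)), "\\[binarize\\]")
})
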