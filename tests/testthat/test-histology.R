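test_that("a single drawn bar is segmented with the right orientation", {
  for (theta in c(0, 30, 77, 120, 165)) {
    img <- bar_image(theta = theta, length_px = 90, width_px = 10)
    b <- segment_bundles(img)
    expect_equal(nrow(b), 1)
    expect_lt(axial_diff(b$orientation, theta), 2)
  }
  expect_equal(nrow(segment_bundles(matrix(0, 50, 50))), 0)
  expect_error(segment_bundles(array(0, c(4, 4, 2))), "2-D")
})

test_that("segmentation recovers synthetic truth bundles one-to-one", {
  sl <- generate_slide(orientation_mixture_spec(45, 135, 8, 0.5),
                       n_bundles = 200, canvas = c(800, 1100), seed = 13)
  b <- segment_bundles(sl$image)
  m <- match_bundles(b, sl$truth_bundles)
  expect_gte(attr(m, "recovery"), 0.95)
  expect_true(all(m$angle_err <= 5))
})

test_that("orientation estimation is equivariant under rotation of the bundle", {
  # the same bar drawn at theta and theta + delta shifts the recovered
  # orientation by delta (axially), within resampling tolerance
  base <- 20
  b0 <- segment_bundles(bar_image(theta = base))
  for (delta in c(15, 40, 85)) {
    b1 <- segment_bundles(bar_image(theta = base + delta))
    expect_lt(abs(axial_diff(b1$orientation, b0$orientation) - delta), 3)
  }
})

test_that("epidermis extraction measures straight and curved contours", {
  # straight top edge: contour length = width exactly (pixel extent)
  mask <- matrix(FALSE, 50, 200)
  mask[11:50, ] <- TRUE
  g <- extract_epidermis(mask)
  expect_equal(g$contour_length, 200, tolerance = 1)
  expect_equal(g$dermis_area, 40 * 200)
  # semicircular epidermis bulging up: contour ~ pi * r
  r <- 80; cx <- 100; H <- 140; W <- 200
  xs <- matrix(rep(1:W, each = H), H, W)
  ys <- matrix(rep(1:H, W), H, W)
  ycurve <- 100 - sqrt(pmax(r^2 - (xs - cx)^2, 0))
  m2 <- ys >= ycurve & abs(xs - cx) <= r
  g2 <- extract_epidermis(m2)
  expect_equal(g2$contour_length, pi * r, tolerance = 0.02)
  # disconnected mask errors, naming the fallback
  m3 <- mask
  m3[, 90:110] <- FALSE
  expect_error(extract_epidermis(m3), "largest_component")
  expect_silent(extract_epidermis(m3, largest_component = TRUE))
})

test_that("extracted polyline tracks the generator's epidermis", {
  sl <- generate_slide(orientation_mixture_spec(45, 135, 8, 0.5),
                       n_bundles = 30, canvas = c(300, 400), seed = 6)
  g <- extract_epidermis(sl$dermis_mask)
  truth_y <- sl$epidermis_polyline$y[match(g$epidermis_polyline$x,
                                           sl$epidermis_polyline$x)]
  expect_true(all(abs(g$epidermis_polyline$y - truth_y) <= 2))
})

test_that("bundle angles are epidermis-relative, axial, and rotation invariant", {
  mask <- matrix(FALSE, 50, 200); mask[11:50, ] <- TRUE
  g <- extract_epidermis(mask)  # straight horizontal epidermis
  b <- data.frame(bundle_id = 1:3, cx = c(50, 100, 150), cy = 30,
                  area = 100, orientation = c(30, 170, 95), eccentricity = 0.9)
  ang <- bundle_angles(b, g)
  expect_equal(ang, c(30, 10, 85))   # folded to [0, 90]
  # relabeling theta -> theta + 180 leaves the output unchanged
  b2 <- b; b2$orientation <- fold_axial(b$orientation + 180)
  expect_equal(bundle_angles(b2, g), ang)
  # local reference agrees with global on a straight epidermis
  expect_equal(bundle_angles(b, g, reference = "local"), ang)
  # rotating bundles and epidermis together leaves angles unchanged:
  # a sloped epidermis polyline at 15 deg with orientations shifted by 15
  poly <- data.frame(x = 1:200, y = 100 - (1:200) * tan(15 * pi / 180))
  gr <- structure(list(dermis_mask = mask, epidermis_polyline = poly,
                       contour_length = 200, dermis_area = 1),
                  class = "dermis_geometry")
  br <- b; br$orientation <- fold_axial(b$orientation + 15)
  expect_equal(bundle_angles(br, gr), ang, tolerance = 1e-6)
})

test_that("thickness and collagen fraction follow their definitions", {
  mask <- matrix(FALSE, 50, 200); mask[1:50, ] <- TRUE
  g <- extract_epidermis(mask)
  expect_equal(dermis_thickness(g), 50 * 200 / g$contour_length)
  expect_equal(dermis_thickness(g), 50, tolerance = 0.5)
  # scaling the mask x2 doubles the thickness
  mask2 <- matrix(FALSE, 100, 400); mask2[1:100, ] <- TRUE
  expect_equal(dermis_thickness(extract_epidermis(mask2)), 100, tolerance = 1)
  # synthetic slide: band height within 2%
  sl <- generate_slide(orientation_mixture_spec(45, 135, 8, 0.5),
                       n_bundles = 20, canvas = c(400, 500), seed = 9,
                       epidermis_y = 50, epidermis_amp = 4)
  th <- dermis_thickness(extract_epidermis(sl$dermis_mask))
  expect_equal(th, 350, tolerance = 0.02 * 350)
  # collagen fraction: full, empty, checkerboard
  expect_equal(collagen_fraction(g, mask), 1.0)
  expect_equal(collagen_fraction(g, matrix(FALSE, 50, 200)), 0.0)
  chk <- (outer(1:50, 1:200, `+`) %% 2) == 0
  expect_identical(collagen_fraction(g, chk), 0.5)
  expect_error(collagen_fraction(g, matrix(FALSE, 10, 10)), "shape")
})
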