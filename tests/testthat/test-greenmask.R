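test_that("RGB to HSV follows the max-branch formulas", {
  px <- function(r, g, b) raster_image(array(c(r, g, b), dim = c(1, 1, 3)))
  red <- rgb_to_hsv_grid(px(1, 0, 0))
  expect_equal(c(red$h, red$s, red$v), c(0, 1, 1))
  green <- rgb_to_hsv_grid(px(0, 1, 0))
  expect_equal(c(green$h, green$s, green$v), c(120, 1, 1))
  gray <- rgb_to_hsv_grid(px(0.5, 0.5, 0.5))
  expect_equal(c(gray$h, gray$s, gray$v), c(0, 0, 0.5))
  black <- rgb_to_hsv_grid(px(0, 0, 0))
  expect_equal(black$s[1, 1], 0)
})

test_that("HSV conversion agrees with the grDevices oracle on random pixels", {
  withr::with_seed(99, {
    img <- random_raster(20, 20, 3)
    got <- rgb_to_hsv_grid(img)
    ref <- grDevices::rgb2hsv(rbind(as.vector(img_band(img, 1)),
                                    as.vector(img_band(img, 2)),
                                    as.vector(img_band(img, 3))),
                              maxColorValue = 1)
    expect_equal(as.vector(got$h), ref["h", ] * 360, tolerance = 1e-9)
    expect_equal(as.vector(got$s), ref["s", ], tolerance = 1e-9)
    expect_equal(as.vector(got$v), ref["v", ], tolerance = 1e-9)
  })
})

test_that("HSV round-trips back to RGB within 1e-6", {
  withr::with_seed(7, {
    img <- random_raster(15, 15, 3)
    back <- hsv_to_rgb_grid(rgb_to_hsv_grid(img))
    expect_lt(max(abs(unclass(back) - unclass(img))), 1e-6)
  })
})

test_that("the green mask keys on hue window plus saturation/value floors", {
  px <- function(r, g, b) raster_image(array(c(r, g, b), dim = c(1, 1, 3)))
  w <- hue_window(70, 170, 0.15, 0.10)
  expect_equal(green_mask(rgb_to_hsv_grid(px(0, 1, 0)), w)[1, 1], 1L)
  expect_equal(green_mask(rgb_to_hsv_grid(px(1, 0, 0)), w)[1, 1], 0L)
  # gray has S = 0, rejected by the saturation floor whatever its hue
  expect_equal(green_mask(rgb_to_hsv_grid(px(0.5, 0.5, 0.5)), w)[1, 1], 0L)
  expect_error(hue_window(200, 100), "hue_lo")
})

test_that("enlarging the window never removes mask pixels (monotonicity)", {
  withr::with_seed(13, {
    hsv <- rgb_to_hsv_grid(random_raster(25, 25, 3))
    base <- green_mask(hsv, hue_window(70, 170, 0.15, 0.10))
    wider <- green_mask(hsv, hue_window(50, 200, 0.05, 0.02))
    expect_true(all(wider[base == 1L] == 1L))
  })
})

test_that("the negation mask keeps exactly the masked pixels", {
  withr::with_seed(3, {
    img <- random_raster(6, 6, 3)
    expect_equal(unclass(apply_negation_mask(img, matrix(1L, 6, 6))),
                 unclass(img), ignore_attr = TRUE)
    expect_true(all(apply_negation_mask(img, matrix(0L, 6, 6)) == 0))
  })
  b <- generate_scene(scene_spec(width = 64, height = 64,
                                 n_green_patches = 1, n_buildings = 0,
                                 n_roads = 0, seed = 2))
  iso <- apply_negation_mask(b$hires_rgb, b$truth_mask)
  lit <- img_band(iso, 1) + img_band(iso, 2) + img_band(iso, 3) > 0
  expect_equal(matrix(as.integer(lit), 64, 64), b$truth_mask)
  expect_error(apply_negation_mask(b$hires_rgb, matrix(1L, 2, 2)),
               "dimensions")
})

test_that("area converts pixel counts through the ground scale", {
  expect_equal(area_acres(matrix(0L, 10, 10), 1)$area_acres, 0)
  full <- area_acres(matrix(1L, 100, 100), 1)
  expect_equal(full$area_m2, 10000)
  expect_equal(full$area_acres, 2.47105, tolerance = 1e-5)
  # linear in the pixel count
  half <- area_acres(rbind(matrix(1L, 50, 100), matrix(0L, 50, 100)), 1)
  expect_equal(half$area_acres, full$area_acres / 2)
  expect_equal(half$green_fraction, 0.5)
})

test_that("speckles below the blob threshold are dropped", {
  mask <- matrix(0L, 10, 10)
  mask[2:5, 2:5] <- 1L     # 16-px blob
  mask[9, 9] <- 1L         # 1-px speckle
  img <- apply_negation_mask(
    raster_image(array(0.5, dim = c(10, 10, 3))), mask)
  # route through green_area's blob filter via its mask argument path
  cleaned <- cropsight:::drop_small_blobs(mask, 4)
  expect_equal(sum(cleaned), 16L)
  expect_equal(cleaned[2:5, 2:5], matrix(1L, 4, 4))
})
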