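test_that("high-pass response to constants and ramps is zero", {
  flat <- raster_image(matrix(0.7, 6, 6))
  expect_true(all(high_pass(flat) == 0))
  expect_true(all(abs(high_pass(flat, "dog")) < 1e-12))
  ramp <- raster_image(matrix(rep(seq(0, 1, length.out = 8), each = 8), 8, 8))
  interior <- high_pass(ramp)[3:6, 3:6]
  expect_true(all(abs(interior) < 1e-12))
})

test_that("laplacian high-pass of an impulse matches the convolution oracle", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  img <- raster_image(m)
  k <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
  expect_equal(high_pass(img), oracle_conv2(m, k))
  withr::with_seed(5, {
    rnd <- matrix(stats::runif(36), 6, 6)
    expect_equal(high_pass(raster_image(rnd)), oracle_conv2(rnd, k),
                 tolerance = 1e-12)
  })
})

test_that("hpf sharpening is the identity at lambda 0 and for constant pan", {
  withr::with_seed(21, {
    for (i in 1:5) {
      M <- random_raster(7, 9)
      P <- random_raster(7, 9)
      out0 <- hpf_sharpen(M, P, fusion_config(lambda_weight = 0))
      expect_equal(unclass(out0), unclass(M), ignore_attr = TRUE)
      flat <- raster_image(matrix(0.4, 7, 9))
      expect_equal(unclass(hpf_sharpen(M, flat)), unclass(M),
                   ignore_attr = TRUE)
    }
  })
  expect_error(hpf_sharpen(random_raster(3, 3), random_raster(4, 4)),
               "dimensions")
})

test_that("hpf sharpening stamps scaled high-pass detail onto the base", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  M <- raster_image(matrix(0.5, 5, 5))
  out <- hpf_sharpen(M, raster_image(m), fusion_config(lambda_weight = 1))
  k <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
  expected <- pmin(pmax(0.5 + oracle_conv2(m, k), 0), 1)
  expect_equal(img_band(out, 1), expected)
})

test_that("brovey handles the cancelling, equal-band and all-black cases", {
  px <- function(r, g, b) raster_image(array(c(r, g, b), dim = c(1, 1, 3)))
  pan <- function(v) raster_image(matrix(v, 1, 1))
  # pan equal to the band sum: ratio cancels
  out <- brovey(px(0.1, 0.2, 0.3), pan(0.6))
  expect_equal(as.vector(unclass(out)), c(0.1, 0.2, 0.3), tolerance = 1e-12)
  # equal bands: each output band is pan/3
  out <- brovey(px(0.2, 0.2, 0.2), pan(0.9))
  expect_equal(as.vector(unclass(out)), rep(0.3, 3), tolerance = 1e-12)
  # all-black ms: epsilon guard keeps the output at zero
  out <- brovey(px(0, 0, 0), pan(1))
  expect_equal(as.vector(unclass(out)), c(0, 0, 0))
})

test_that("brovey conserves pan intensity and is 1-homogeneous in pan", {
  withr::with_seed(33, {
    for (i in 1:10) {
      # keep band sums <= 1 so no clipping interferes with conservation
      ms <- raster_image(array(stats::runif(75, 0.05, 0.9) / 3,
                               dim = c(5, 5, 3)))
      pan <- random_raster(5, 5)
      y <- brovey(ms, pan)
      band_sum <- img_band(y, 1) + img_band(y, 2) + img_band(y, 3)
      expect_lt(max(abs(band_sum - img_band(pan, 1)) / pmax(band_sum, 1e-12)),
                1e-9)
      c_ <- stats::runif(1)
      yc <- brovey(ms, raster_image(c_ * unclass(pan)[, , 1]))
      expect_equal(unclass(yc), c_ * unclass(y), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("the sharpening pipeline composes resampling and fusion", {
  withr::with_seed(8, {
    b <- generate_scene(scene_spec(width = 64, height = 64, seed = 8))
    fused <- sharpen_pipeline(b$ms_lowres, b$pan, method = "brovey")
    expect_identical(dim(fused)[1:2], dim(b$pan)[1:2])
    # conservation holds against the pan band wherever the sum is unclipped
    bs <- img_band(fused, 1) + img_band(fused, 2) + img_band(fused, 3)
    ok <- bs < 0.999
    expect_lt(max(abs(bs[ok] - img_band(b$pan, 1)[ok])), 1e-9)
    # brovey output carries at least the edge energy of the blurry upsample
    k <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
    energy <- function(img) mean(abs(oracle_conv2(
      img_band(to_grayscale(img), 1), k)))
    up <- resample(b$ms_lowres, 64, 64, "bilinear")
    expect_gte(energy(fused), energy(up))
    # hpf path with lambda 0 is just the resampled grayscale
    out <- sharpen_pipeline(b$ms_lowres, b$pan, method = "hpf",
                            cfg = fusion_config(lambda_weight = 0))
    expect_equal(unclass(out), unclass(to_grayscale(up)),
                 ignore_attr = TRUE)
  })
  expect_error(sharpen_pipeline(random_raster(8, 8, 3), random_raster(4, 4)),
               "resolution")
})

test_that("the HSV route keeps hue and saturation but takes fused brightness", {
  withr::with_seed(14, {
    b <- generate_scene(scene_spec(width = 32, height = 32, seed = 14))
    routed <- sharpen_pipeline(b$ms_lowres, b$pan, method = "brovey",
                               hsv_route = TRUE)
    fused <- sharpen_pipeline(b$ms_lowres, b$pan, method = "brovey")
    up <- resample(b$ms_lowres, 32, 32, "bilinear")
    got <- rgb_to_hsv_grid(routed)
    want_hs <- rgb_to_hsv_grid(up)
    # compare hue only where saturation is meaningful (hue is undefined
    # for near-achromatic pixels)
    sat_ok <- want_hs$s > 0.05 & got$s > 0.05
    expect_lt(max(abs(got$h[sat_ok] - want_hs$h[sat_ok])), 1e-6)
    expect_lt(max(abs(got$v - img_band(to_grayscale(fused), 1))), 1e-9)
  })
})
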