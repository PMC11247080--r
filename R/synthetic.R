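#' Scene specification for the synthetic satellite-scene generator
#'
#' @param width,height scene dimensions in pixels.
#' @param n_green_patches number of elliptical vegetation patches.
#' @param n_buildings number of gray-roofed rectangles.
#' @param n_roads number of dark road strips.
#' @param noise_sigma std dev of additive Gaussian intensity noise (>= 0).
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(width = 256, height = 256, n_green_patches = 6,
                       n_buildings = 8, n_roads = 3, noise_sigma = 0,
                       seed = 1) {
  stopifnot(width > 0, height > 0, n_green_patches >= 0, n_buildings >= 0,
            n_roads >= 0, noise_sigma >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_green_patches = as.integer(n_green_patches),
                 n_buildings = as.integer(n_buildings),
                 n_roads = as.integer(n_roads),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_spec")
}

# paint a constant HSV colour over a logical pixel set in three band matrices
paint_hsv <- function(bands, sel, h, s, v) {
  hsv1 <- structure(list(h = matrix(h, 1, 1), s = matrix(s, 1, 1),
                         v = matrix(v, 1, 1)), class = "hsv_grid")
  rgb1 <- hsv_to_rgb_grid(hsv1)
  for (k in 1:3) bands[[k]][sel] <- img_band(rgb1, k)[1, 1]
  bands
}

ellipse_pixels <- function(w, h, cx, cy, ax, ay) {
  cols <- pmax(1L, floor(cx - ax)):pmin(w, ceiling(cx + ax))
  rows <- pmax(1L, floor(cy - ay)):pmin(h, ceiling(cy + ay))
  grid <- expand.grid(r = rows, c = cols)
  inside <- ((grid$c - cx) / ax)^2 + ((grid$r - cy) / ay)^2 <= 1
  cbind(grid$r[inside], grid$c[inside])
}

#' Generate a synthetic satellite-style scene with known green ground truth
#'
#' Paints a tan soil background, warm-gray building rectangles and dark road
#' strips, then elliptical vegetation patches (hue drawn uniformly in
#' 80-150 degrees, saturation >= 0.55, value >= 0.45) painted last so the
#' recorded truth mask reflects final pixel ownership. Every non-vegetation
#' element carries a warm hue (20-40 degrees) and moderate saturation so
#' that small additive noise cannot move it into the green hue window. The
#' panchromatic band is the grayscale of the (noisy) high-resolution scene;
#' the low-resolution multispectral image is a Gaussian-blurred
#' (sigma = 1.5), factor-4 downsampled copy.
#'
#' @param spec a [scene_spec()].
#' @return a list of class `scene_bundle`: `hires_rgb`, `pan`, `ms_lowres`
#'   (`raster_image`s), `truth_mask` (0/1 matrix), `truth_green_px`
#'   (integer), `patches` (tibble of ellipse centres/semi-axes), `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, {
    w <- spec$width; h <- spec$height
    bands <- replicate(3, matrix(0, h, w), simplify = FALSE)
    # soil background
    bands <- paint_hsv(bands, rep(TRUE, h * w),
                       h = stats::runif(1, 32, 40),
                       s = stats::runif(1, 0.28, 0.38),
                       v = stats::runif(1, 0.65, 0.80))
    # buildings: axis-aligned rectangles with warm-gray roofs
    for (i in seq_len(spec$n_buildings)) {
      bw <- sample(8:24, 1); bh <- sample(8:24, 1)
      c0 <- sample.int(max(w - bw, 1), 1)
      r0 <- sample.int(max(h - bh, 1), 1)
      sel <- matrix(FALSE, h, w)
      sel[r0:(r0 + bh - 1), c0:(c0 + bw - 1)] <- TRUE
      bands <- paint_hsv(bands, sel, h = stats::runif(1, 25, 35),
                         s = stats::runif(1, 0.20, 0.28),
                         v = stats::runif(1, 0.45, 0.62))
    }
    # roads: straight strips, horizontal or vertical, dark warm gray
    for (i in seq_len(spec$n_roads)) {
      thick <- sample(2:4, 1)
      sel <- matrix(FALSE, h, w)
      if (stats::runif(1) < 0.5) {
        r0 <- sample.int(max(h - thick, 1), 1)
        sel[r0:(r0 + thick - 1), ] <- TRUE
      } else {
        c0 <- sample.int(max(w - thick, 1), 1)
        sel[, c0:(c0 + thick - 1)] <- TRUE
      }
      bands <- paint_hsv(bands, sel, h = stats::runif(1, 18, 26),
                         s = stats::runif(1, 0.25, 0.32),
                         v = stats::runif(1, 0.22, 0.30))
    }
    # vegetation last: ownership of overlapped pixels goes to the patch
    truth <- matrix(0L, h, w)
    patches <- vector("list", spec$n_green_patches)
    for (i in seq_len(spec$n_green_patches)) {
      ax <- stats::runif(1, 6, min(25, w / 4))
      ay <- stats::runif(1, 6, min(25, h / 4))
      cx <- stats::runif(1, ax + 1, w - ax)
      cy <- stats::runif(1, ay + 1, h - ay)
      patches[[i]] <- tibble::tibble(cx = cx, cy = cy, ax = ax, ay = ay)
      px <- ellipse_pixels(w, h, cx, cy, ax, ay)
      sel <- matrix(FALSE, h, w)
      sel[px] <- TRUE
      bands <- paint_hsv(bands, sel, h = stats::runif(1, 80, 150),
                         s = stats::runif(1, 0.55, 0.85),
                         v = stats::runif(1, 0.45, 0.80))
      truth[sel] <- 1L
    }
    if (spec$noise_sigma > 0) {
      for (k in 1:3) {
        bands[[k]] <- bands[[k]] +
          matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
      }
    }
    hires <- rebuild_raster(bands)
    pan <- to_grayscale(hires)
    blurred <- lapply(1:3, function(k)
      conv2_reflect(img_band(hires, k), gaussian_kernel(1.5)))
    ms <- resample(rebuild_raster(blurred), max(1L, w %/% 4L),
                   max(1L, h %/% 4L), method = "nearest")
    structure(list(hires_rgb = hires, pan = pan, ms_lowres = ms,
                   truth_mask = truth, truth_green_px = sum(truth),
                   patches = dplyr::bind_rows(patches), spec = spec),
              class = "scene_bundle")
  })
}

#' Generate an attribute suite covering every rule branch
#'
#' Emits one record per reachable categorical combination the rulebase
#' branches on (hot/dry, hot/humid, hot with moderate humidity, moderate on
#' plain and hilly terrain, cool, and high/low levels of wind,
#' precipitation, UV and soil moisture), with continuous values sampled
#' uniformly inside each band. Deterministic per seed.
#'
#' @param seed integer seed.
#' @return attribute tibble (see [load_attributes()] for the schema).
#' @export
generate_attribute_suite <- function(seed = 1) {
  withr::with_seed(seed, {
    u <- function(lo, hi) stats::runif(1, lo, hi)
    rec <- function(name, temp, hum, wind, precip, uv, soil,
                    terrain = "plain") {
      tibble::tibble(location_name = name, temperature_c = temp,
                     humidity_pct = hum, wind_kmh = wind,
                     precip_mm_day = precip, uv_index = uv,
                     soil_moisture_vwc = soil, terrain = terrain)
    }
    dplyr::bind_rows(
      rec("hot-dry plain",        u(31, 40), u(15, 39), u(0, 19), u(0, 9), u(0, 5), u(0.05, 0.29)),
      rec("hot-humid lowland",    u(31, 40), u(71, 95), u(0, 19), u(11, 30), u(0, 5), u(0.31, 0.6)),
      rec("hot mid-humidity",     u(31, 40), u(45, 65), u(0, 19), u(0, 9), u(0, 5), u(0.05, 0.29)),
      rec("temperate plain",      u(20, 30), u(45, 65), u(0, 19), u(0, 9), u(0, 5), u(0.05, 0.29)),
      rec("temperate hills",      u(20, 30), u(45, 65), u(0, 19), u(0, 9), u(0, 5), u(0.05, 0.29), "hilly"),
      rec("cool uplands",         u(5, 19),  u(45, 65), u(0, 19), u(0, 9), u(0, 5), u(0.05, 0.29)),
      rec("windy coast",          u(20, 30), u(45, 65), u(21, 50), u(0, 9), u(0, 5), u(0.05, 0.29)),
      rec("monsoon belt",         u(20, 30), u(71, 95), u(0, 19), u(11, 40), u(0, 5), u(0.31, 0.6)),
      rec("high-uv plateau",      u(20, 30), u(45, 65), u(0, 19), u(0, 9), u(6, 11), u(0.05, 0.29)),
      rec("wet paddy basin",      u(20, 30), u(71, 95), u(0, 19), u(11, 40), u(0, 5), u(0.31, 0.6)),
      rec("dry scrubland",        u(31, 40), u(15, 39), u(0, 19), u(0, 9), u(6, 11), u(0.05, 0.29)),
      rec("windy hot flats",      u(31, 40), u(15, 39), u(21, 50), u(0, 9), u(0, 5), u(0.05, 0.29))
    )
  })
}
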