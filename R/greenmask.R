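#' Convert an RGB raster to HSV components
#'
#' Per pixel: `V = max(R, G, B)`, `S = (max - min) / max` (0 when `V = 0`),
#' and hue from the branch of the channel attaining the maximum, in degrees
#' with a `+360` wrap when negative. Achromatic pixels (`max = min`) get
#' `H = 0` by convention.
#'
#' @param img a 3-band `raster_image` with intensities in `[0, 1]`.
#' @return an `hsv_grid`: list of matrices `h` (degrees in `[0, 360)`),
#'   `s`, `v` (both in `[0, 1]`).
#' @examples
#' px <- raster_image(array(c(0, 1, 0), dim = c(1, 1, 3)))
#' rgb_to_hsv_grid(px)$h   # 120
#' @export
rgb_to_hsv_grid <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img_bands(img) != 3L) {
    stop("rgb_to_hsv_grid() needs a 3-band image", call. = FALSE)
  }
  r <- img_band(img, 1); g <- img_band(img, 2); b <- img_band(img, 3)
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  v <- mx
  s <- ifelse(mx > 0, d / mx, 0)
  h <- matrix(0, nrow(r), ncol(r))
  chrom <- d > 0
  # ties resolved in R, G, B precedence; branch choice only matters at d = 0
  isr <- chrom & (mx == r)
  isg <- chrom & !isr & (mx == g)
  isb <- chrom & !isr & !isg
  h[isr] <- 60 * ((g[isr] - b[isr]) / d[isr])
  h[isg] <- 60 * (2 + (b[isg] - r[isg]) / d[isg])
  h[isb] <- 60 * (4 + (r[isb] - g[isb]) / d[isb])
  h[h < 0] <- h[h < 0] + 360
  structure(list(h = h, s = s, v = v), class = "hsv_grid")
}

#' Convert HSV components back to an RGB raster
#'
#' Inverse of [rgb_to_hsv_grid()]; exact for any valid HSV triple.
#'
#' @param hsv an `hsv_grid`.
#' @return a 3-band `raster_image`.
#' @export
hsv_to_rgb_grid <- function(hsv) {
  stopifnot(inherits(hsv, "hsv_grid"))
  h <- hsv$h / 60
  c_ <- hsv$v * hsv$s
  x <- c_ * (1 - abs(h %% 2 - 1))
  m <- hsv$v - c_
  sector <- pmin(floor(h), 5)
  r <- g <- b <- matrix(0, nrow(h), ncol(h))
  pick <- function(sec) sector == sec
  r[pick(0) | pick(5)] <- c_[pick(0) | pick(5)]
  r[pick(1) | pick(4)] <- x[pick(1) | pick(4)]
  g[pick(0) | pick(3)] <- x[pick(0) | pick(3)]
  g[pick(1) | pick(2)] <- c_[pick(1) | pick(2)]
  b[pick(2) | pick(5)] <- x[pick(2) | pick(5)]
  b[pick(3) | pick(4)] <- c_[pick(3) | pick(4)]
  rebuild_raster(list(r + m, g + m, b + m))
}

#' Green hue window
#'
#' Thresholds for vegetation masking: a closed hue interval plus saturation
#' and value floors (the floors reject gray roofs/roads and near-black
#' shadow, which carry arbitrary hue). Defaults select the green band of the
#' hue circle; all four are tunable to the shades of interest.
#'
#' @param hue_lo,hue_hi hue bounds in degrees, `0 <= hue_lo < hue_hi < 360`.
#' @param sat_min,val_min saturation / value floors in `[0, 1]`.
#' @return a list of class `hue_window`.
#' @export
hue_window <- function(hue_lo = 70, hue_hi = 170, sat_min = 0.15,
                       val_min = 0.10) {
  stopifnot(hue_lo >= 0, hue_lo < hue_hi, hue_hi < 360,
            sat_min >= 0, sat_min <= 1, val_min >= 0, val_min <= 1)
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi, sat_min = sat_min,
                 val_min = val_min), class = "hue_window")
}

#' Binary vegetation mask from an HSV grid
#'
#' A pixel is green (1) iff its hue lies in the closed window and saturation
#' and value are at or above their floors.
#'
#' @param hsv an `hsv_grid`.
#' @param window a [hue_window()].
#' @return integer 0/1 matrix with the grid's dimensions.
#' @export
green_mask <- function(hsv, window = hue_window()) {
  stopifnot(inherits(hsv, "hsv_grid"), inherits(window, "hue_window"))
  m <- (hsv$h >= window$hue_lo) & (hsv$h <= window$hue_hi) &
    (hsv$s >= window$sat_min) & (hsv$v >= window$val_min)
  matrix(as.integer(m), nrow(hsv$h), ncol(hsv$h))
}

#' Keep only masked pixels of an image
#'
#' Pixels where the mask is 1 keep their original colour; everything else is
#' set to black, isolating the green regions from buildings, roads and soil.
#'
#' @param img a 3-band `raster_image`.
#' @param mask 0/1 matrix with the image's dimensions.
#' @return a 3-band `raster_image`.
#' @export
apply_negation_mask <- function(img, mask) {
  stopifnot(inherits(img, "raster_image"))
  if (!identical(dim(mask), dim(img)[1:2])) {
    stop("mask dimensions do not match the image", call. = FALSE)
  }
  bands <- lapply(seq_len(img_bands(img)), function(k)
    img_band(img, k) * mask)
  rebuild_raster(bands, template = img)
}

#' Green area from a mask and a ground scale
#'
#' `acres = n_green_pixels * ground_m_per_px^2 / 4046.8564224`.
#'
#' @param mask 0/1 matrix.
#' @param ground_m_per_px metres of ground per pixel side (> 0); see
#'   [ground_scale()].
#' @return a one-row tibble: `green_pixels`, `total_pixels`,
#'   `green_fraction`, `area_m2`, `area_acres`.
#' @export
area_acres <- function(mask, ground_m_per_px) {
  stopifnot(ground_m_per_px > 0, all(mask %in% c(0L, 1L)))
  n <- sum(mask == 1L)
  m2 <- n * ground_m_per_px^2
  tibble::tibble(
    green_pixels = n,
    total_pixels = length(mask),
    green_fraction = n / length(mask),
    area_m2 = m2,
    area_acres = m2 / 4046.8564224
  )
}

#' Measure green area in an RGB image
#'
#' Convenience composition: HSV conversion, hue-window masking, optional
#' speckle removal, and acreage. This is the single-image workflow the
#' `greenarea` CLI subcommand wraps.
#'
#' @param img a 3-band `raster_image`.
#' @param window a [hue_window()].
#' @param ground_m_per_px metres per pixel (defaults to the image's attached
#'   scale, else [ground_scale()]).
#' @param min_blob_px connected components (4-neighbour) smaller than this
#'   many pixels are dropped from the mask; 0 disables the filter.
#' @return list with `mask` (0/1 matrix) and `report` (the [area_acres()]
#'   tibble).
#' @export
green_area <- function(img, window = hue_window(), ground_m_per_px = NULL,
                       min_blob_px = 0) {
  if (is.null(ground_m_per_px)) {
    ground_m_per_px <- attr(img, "ground_m_per_px")
    if (is.null(ground_m_per_px)) ground_m_per_px <- ground_scale()
  }
  mask <- green_mask(rgb_to_hsv_grid(img), window)
  if (min_blob_px > 0) mask <- drop_small_blobs(mask, min_blob_px)
  list(mask = mask, report = area_acres(mask, ground_m_per_px))
}

# 4-connected component labelling by flood fill; adequate for speckle removal
drop_small_blobs <- function(mask, min_px) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextlab <- 0L
  sizes <- integer(0)
  idx <- which(mask == 1L & lab == 0L)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    count <- 0L
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- nextlab
      count <- count + 1L
      r <- (p - 1L) %% h + 1L
      cc <- (p - 1L) %/% h + 1L
      for (q in c(if (r > 1) p - 1L, if (r < h) p + 1L,
                  if (cc > 1) p - h, if (cc < w) p + h)) {
        if (mask[q] == 1L && lab[q] == 0L) stack <- c(stack, q)
      }
    }
    sizes[nextlab] <- count
  }
  small <- which(sizes < min_px)
  mask[lab %in% small] <- 0L
  mask
}
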