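#' Raster image container
#'
#' A `raster_image` is a numeric array of shape `height x width x bands`
#' (bands = 1 for panchromatic/grayscale, 3 for RGB) holding intensities in
#' `[0, 1]`, row-major with the origin at the top-left corner. An optional
#' ground scale (metres of ground distance per pixel side) rides along as an
#' attribute so area estimates can be made downstream.
#'
#' @param data numeric matrix (taken as a single band) or `h x w x {1,3}` array
#'   of intensities in `[0, 1]`.
#' @param ground_m_per_px optional ground scale, metres per pixel (> 0).
#' @return a `raster_image` object.
#' @examples
#' img <- raster_image(matrix(runif(12), 3, 4))
#' dim(img)
#' @export
raster_image <- function(data, ground_m_per_px = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a matrix or a h x w x bands array", call. = FALSE)
  }
  if (!dim(data)[3] %in% c(1L, 3L)) {
    stop("band count must be 1 or 3, got ", dim(data)[3], call. = FALSE)
  }
  if (anyNA(data) || min(data) < 0 || max(data) > 1) {
    stop("intensities must lie in [0, 1] with no missing values", call. = FALSE)
  }
  if (!is.null(ground_m_per_px)) {
    stopifnot(is.numeric(ground_m_per_px), length(ground_m_per_px) == 1L,
              ground_m_per_px > 0)
  }
  structure(data, ground_m_per_px = ground_m_per_px, class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  scale <- attr(x, "ground_m_per_px")
  cat(sprintf("<raster_image> %d x %d px, %d band%s", d[2], d[1], d[3],
              if (d[3] > 1) "s" else ""))
  if (!is.null(scale)) cat(sprintf(", %.4g m/px", scale))
  cat(sprintf(", intensity range [%.3f, %.3f]\n", min(x), max(x)))
  invisible(x)
}

img_width <- function(img) dim(img)[2]
img_height <- function(img) dim(img)[1]
img_bands <- function(img) dim(img)[3]

#' Band accessor
#' @param img a `raster_image`.
#' @param k band index.
#' @return numeric matrix of that band.
#' @export
img_band <- function(img, k) {
  d <- dim(img)
  matrix(unclass(img)[, , k], d[1], d[2])
}

# rebuild a raster_image from band matrices, carrying the scale over
rebuild_raster <- function(bands, template = NULL) {
  if (is.matrix(bands)) bands <- list(bands)
  arr <- array(unlist(bands), dim = c(dim(bands[[1]]), length(bands)))
  arr <- pmin(pmax(arr, 0), 1)
  raster_image(arr, ground_m_per_px = if (!is.null(template))
    attr(template, "ground_m_per_px"))
}

#' Read a PNG or TIFF file as a raster image
#'
#' 8- and 16-bit files are rescaled to `[0, 1]` (the png/tiff readers already
#' divide by the sample maximum). An alpha channel, if present, is dropped.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param ground_m_per_px optional ground scale to attach, metres per pixel.
#' @return a `raster_image` with 1 or 3 bands.
#' @export
read_raster <- function(path, ground_m_per_px = NULL) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '.", ext, "' (PNG or TIFF expected)",
         call. = FALSE)
  )
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  nb <- dim(arr)[3]
  if (nb %in% c(2L, 4L)) {            # grayscale+alpha / RGBA: drop alpha
    arr <- arr[, , seq_len(nb - 1L), drop = FALSE]
    nb <- dim(arr)[3]
  }
  if (!nb %in% c(1L, 3L)) {
    stop("unsupported channel count ", nb, " in ", path, call. = FALSE)
  }
  raster_image(pmin(pmax(arr, 0), 1), ground_m_per_px = ground_m_per_px)
}

#' Write a raster image to PNG or TIFF
#'
#' Intensities are quantized to the file bit depth (8-bit by default), so a
#' read-back reproduces the image to within one quantization step (1/255).
#'
#' @param img a `raster_image`.
#' @param path destination path ending in `.png`, `.tif` or `.tiff`.
#' @param bits sample depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path, bits = 8L) {
  stopifnot(inherits(img, "raster_image"), bits %in% c(8L, 16L))
  arr <- unclass(img)
  if (dim(arr)[3] == 1L) arr <- arr[, , 1L]
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    png  = try(png::writePNG(arr, target = path), silent = TRUE),
    tif  = ,
    tiff = try(tiff::writeTIFF(arr, where = path, bits.per.sample = bits),
               silent = TRUE),
    stop("unsupported raster format '.", ext, "'", call. = FALSE)
  )
  if (inherits(ok, "try-error")) {
    stop("cannot write raster to ", path, call. = FALSE)
  }
  invisible(path)
}

#' Convert an RGB raster to grayscale luminance
#'
#' Uses the ITU-R BT.601 luminance weights 0.299/0.587/0.114, a convex
#' combination of the channels, so the output stays in `[0, 1]`.
#'
#' @param img a 3-band `raster_image`.
#' @return a 1-band `raster_image`.
#' @examples
#' px <- array(c(1, 0, 0), dim = c(1, 1, 3))
#' img_band(to_grayscale(raster_image(px)), 1)   # 0.299
#' @export
to_grayscale <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img_bands(img) != 3L) {
    stop("to_grayscale() needs a 3-band image", call. = FALSE)
  }
  g <- 0.299 * img_band(img, 1) + 0.587 * img_band(img, 2) +
    0.114 * img_band(img, 3)
  rebuild_raster(as.matrix(g), template = img)
}

# map destination pixel centres to source coordinates (0-based, pixel-centre)
src_coords <- function(n_dst, n_src) {
  (seq_len(n_dst) - 0.5) * (n_src / n_dst) - 0.5
}

# Keys cubic convolution kernel, a = -0.5
keys_weight <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

resample_band <- function(m, tw, th, method) {
  sh <- nrow(m); sw <- ncol(m)
  ys <- src_coords(th, sh)
  xs <- src_coords(tw, sw)
  clampr <- function(i) pmin(pmax(i, 1L), sh)
  clampc <- function(i) pmin(pmax(i, 1L), sw)
  if (method == "nearest") {
    ri <- clampr(as.integer(floor(ys + 0.5)) + 1L)
    ci <- clampc(as.integer(floor(xs + 0.5)) + 1L)
    return(m[ri, ci, drop = FALSE])
  }
  if (method == "bilinear") {
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0;  fx <- xs - x0
    r0 <- clampr(as.integer(y0) + 1L); r1 <- clampr(as.integer(y0) + 2L)
    c0 <- clampc(as.integer(x0) + 1L); c1 <- clampc(as.integer(x0) + 2L)
    top <- m[r0, c0, drop = FALSE] * outer(1 - fy, 1 - fx) +
      m[r0, c1, drop = FALSE] * outer(1 - fy, fx)
    bot <- m[r1, c0, drop = FALSE] * outer(fy, 1 - fx) +
      m[r1, c1, drop = FALSE] * outer(fy, fx)
    return(top + bot)
  }
  # cubic: separable 4-tap Keys kernel, border samples replicated
  y0 <- as.integer(floor(ys)); x0 <- as.integer(floor(xs))
  fy <- ys - y0; fx <- xs - x0
  out <- matrix(0, th, tw)
  for (dy in -1:2) {
    wy <- keys_weight(fy - dy)
    rows <- clampr(y0 + dy + 1L)
    acc <- matrix(0, th, tw)
    for (dx in -1:2) {
      wx <- keys_weight(fx - dx)
      cols <- clampc(x0 + dx + 1L)
      acc <- acc + m[rows, cols, drop = FALSE] * outer(rep(1, th), wx)
    }
    out <- out + acc * outer(wy, rep(1, tw))
  }
  out
}

#' Resample a raster image to new dimensions
#'
#' Pixel-centre convention: destination pixel centre `(i + 0.5)` maps to
#' source coordinate `(i + 0.5) * scale - 0.5`. `cubic` is Keys cubic
#' convolution with `a = -0.5`. Results are clipped to `[0, 1]`, and all
#' three methods reproduce constant images exactly.
#'
#' @param img a `raster_image`.
#' @param target_w,target_h target dimensions in pixels (> 0).
#' @param method one of `"nearest"`, `"bilinear"`, `"cubic"`.
#' @return a `raster_image` with the target dimensions.
#' @export
resample <- function(img, target_w, target_h,
                     method = c("nearest", "bilinear", "cubic")) {
  stopifnot(inherits(img, "raster_image"), target_w >= 1, target_h >= 1)
  method <- match.arg(method)
  bands <- lapply(seq_len(img_bands(img)), function(k)
    resample_band(img_band(img, k), as.integer(target_w),
                  as.integer(target_h), method))
  rebuild_raster(bands, template = img)
}

#' Ground scale from a map-scale convention
#'
#' Converts a printed map scale ("so many yards of ground per centimetre of
#' screen") and a screen pixel density into metres of ground per image pixel:
#' `ground_m_per_px = yards_per_cm * 0.9144 / pixels_per_cm`. Alternatively
#' pass `m_per_px` to set the scale directly.
#'
#' @param yards_per_cm map scale in yards of ground per on-screen centimetre
#'   (default 126, the zoom level the area workflow assumes).
#' @param pixels_per_cm screen pixel density (default 37.795 px/cm, i.e. 96 dpi).
#' @param m_per_px direct override, metres per pixel.
#' @return metres per pixel (scalar, > 0).
#' @examples
#' ground_scale()                 # the default 126 yards/cm at 96 dpi
#' ground_scale(m_per_px = 2.5)
#' @export
ground_scale <- function(yards_per_cm = 126, pixels_per_cm = 37.795,
                         m_per_px = NULL) {
  if (!is.null(m_per_px)) {
    stopifnot(m_per_px > 0)
    return(m_per_px)
  }
  stopifnot(yards_per_cm > 0, pixels_per_cm > 0)
  yards_per_cm * 0.9144 / pixels_per_cm
}
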