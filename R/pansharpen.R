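#' Fusion configuration
#'
#' Parameters shared by the pan-sharpening routines: the high-pass weighting
#' factor lambda, the high-pass kernel choice, the Difference-of-Gaussians
#' sigmas, and the epsilon guard for the Brovey denominator.
#'
#' @param lambda_weight weight on the high-pass detail added back to the
#'   grayscale multispectral image (>= 0; default 1).
#' @param kernel `"laplacian3"` (the 3x3 4-neighbour Laplacian) or `"dog"`
#'   (difference of two Gaussians).
#' @param dog_sigmas numeric pair `c(sigma1, sigma2)` with `sigma1 < sigma2`.
#' @param epsilon positive guard used where the multispectral band sum would
#'   otherwise divide by zero.
#' @return a list of class `fusion_config`.
#' @export
fusion_config <- function(lambda_weight = 1, kernel = c("laplacian3", "dog"),
                          dog_sigmas = c(1, 2), epsilon = 1e-6) {
  kernel <- match.arg(kernel)
  stopifnot(lambda_weight >= 0, epsilon > 0, length(dog_sigmas) == 2,
            dog_sigmas[1] > 0, dog_sigmas[1] < dog_sigmas[2])
  structure(list(lambda_weight = lambda_weight, kernel = kernel,
                 dog_sigmas = dog_sigmas, epsilon = epsilon),
            class = "fusion_config")
}

laplacian3_kernel <- function() {
  matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
}

#' High-pass filter a single-band image
#'
#' Convolves with a zero-sum kernel (3x3 Laplacian or a Difference of
#' Gaussians) under reflect padding. The result is the unclipped signed
#' detail field `F(P)`; a constant image maps to an all-zero field.
#'
#' @param img a 1-band `raster_image`.
#' @param kernel `"laplacian3"` or `"dog"`.
#' @param dog_sigmas sigmas for the DoG kernel.
#' @return a numeric matrix (signed, not a `raster_image`).
#' @export
high_pass <- function(img, kernel = c("laplacian3", "dog"),
                      dog_sigmas = c(1, 2)) {
  stopifnot(inherits(img, "raster_image"))
  if (img_bands(img) != 1L) stop("high_pass() needs a 1-band image",
                                 call. = FALSE)
  kernel <- match.arg(kernel)
  k <- if (kernel == "laplacian3") {
    laplacian3_kernel()
  } else {
    gaussian_kernel(dog_sigmas[1]) |>
      pad_to_match(gaussian_kernel(dog_sigmas[2]))
  }
  conv2_reflect(img_band(img, 1), k)
}

# centre-pad the smaller Gaussian so the DoG difference is a single kernel
pad_to_match <- function(k1, k2) {
  if (nrow(k1) < nrow(k2)) {
    d <- (nrow(k2) - nrow(k1)) %/% 2L
    big <- matrix(0, nrow(k2), ncol(k2))
    big[d + seq_len(nrow(k1)), d + seq_len(ncol(k1))] <- k1
    k1 <- big
  }
  k1 - k2
}

#' Sharpen by adding high-pass detail (HPF fusion)
#'
#' `sharpened = clip(M + lambda * F(P), 0, 1)` where `M` is the grayscale
#' multispectral image and `F(P)` the high-pass-filtered panchromatic band.
#' With `lambda = 0`, or a constant `P`, the output equals `M` exactly.
#'
#' @param M grayscale multispectral image (1-band `raster_image`).
#' @param P panchromatic image, already resampled to `M`'s grid.
#' @param cfg a [fusion_config()].
#' @return a 1-band `raster_image`.
#' @export
hpf_sharpen <- function(M, P, cfg = fusion_config()) {
  stopifnot(inherits(M, "raster_image"), inherits(P, "raster_image"))
  if (!identical(dim(M)[1:2], dim(P)[1:2])) {
    stop("M and P dimensions differ; resample P first", call. = FALSE)
  }
  fp <- high_pass(P, kernel = cfg$kernel, dog_sigmas = cfg$dog_sigmas)
  rebuild_raster(img_band(M, 1) + cfg$lambda_weight * fp, template = M)
}

#' Brovey ratio fusion
#'
#' Each multispectral band is rescaled by the panchromatic intensity over the
#' band sum: `Y_k = X_k * X_p / max(X_R + X_G + X_B, epsilon)`, then clipped
#' to `[0, 1]`. Wherever the band sum exceeds epsilon the fused band sum
#' equals the panchromatic intensity (intensity modulation).
#'
#' @param ms 3-band `raster_image`.
#' @param pan 1-band `raster_image` on the same grid.
#' @param cfg a [fusion_config()] (only `epsilon` is used).
#' @return a 3-band `raster_image`.
#' @export
brovey <- function(ms, pan, cfg = fusion_config()) {
  stopifnot(inherits(ms, "raster_image"), inherits(pan, "raster_image"))
  if (img_bands(ms) != 3L) stop("brovey() needs a 3-band ms image", call. = FALSE)
  if (!identical(dim(ms)[1:2], dim(pan)[1:2])) {
    stop("ms and pan dimensions differ; resample first", call. = FALSE)
  }
  r <- img_band(ms, 1); g <- img_band(ms, 2); b <- img_band(ms, 3)
  denom <- pmax(r + g + b, cfg$epsilon)
  ratio <- img_band(pan, 1) / denom
  rebuild_raster(list(r * ratio, g * ratio, b * ratio), template = ms)
}

#' End-to-end pan-sharpening pipeline
#'
#' Brings the low-resolution multispectral image and the panchromatic band
#' onto the panchromatic grid and fuses them. The `"brovey"` path upsamples
#' the multispectral image and applies the ratio transform; the `"hpf"` path
#' converts the upsampled multispectral image to grayscale and adds
#' high-pass panchromatic detail.
#'
#' @param ms_lowres 3-band `raster_image`, lower resolution.
#' @param pan 1-band `raster_image` at the target resolution (each dimension
#'   >= the multispectral one).
#' @param method `"brovey"` or `"hpf"`.
#' @param resampling interpolation used to upsample `ms_lowres`.
#' @param cfg a [fusion_config()].
#' @param hsv_route if `TRUE` (brovey only), the fused luminance is injected
#'   as the value channel of the upsampled multispectral image in HSV space
#'   and converted back, preserving the original hue/saturation while taking
#'   sharpness from the fusion. Off by default; one plausible reading of an
#'   HSV-mediated sharpening step, flagged as such.
#' @return a `raster_image` at the panchromatic resolution (3-band for
#'   brovey, 1-band for hpf).
#' @export
sharpen_pipeline <- function(ms_lowres, pan, method = c("brovey", "hpf"),
                             resampling = c("bilinear", "nearest", "cubic"),
                             cfg = fusion_config(), hsv_route = FALSE) {
  method <- match.arg(method)
  resampling <- match.arg(resampling)
  stopifnot(inherits(ms_lowres, "raster_image"), inherits(pan, "raster_image"))
  if (img_width(pan) < img_width(ms_lowres) ||
      img_height(pan) < img_height(ms_lowres)) {
    stop("pan resolution must be >= multispectral resolution", call. = FALSE)
  }
  ms_up <- resample(ms_lowres, img_width(pan), img_height(pan),
                    method = resampling)
  if (method == "brovey") {
    fused <- brovey(ms_up, pan, cfg)
    if (!hsv_route) return(fused)
    hsv <- rgb_to_hsv_grid(ms_up)
    hsv$v <- img_band(to_grayscale(fused), 1)
    hsv_to_rgb_grid(hsv)
  } else {
    hpf_sharpen(to_grayscale(ms_up), pan, cfg)
  }
}
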