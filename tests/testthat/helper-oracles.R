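# Independent oracles used across the suite. These deliberately re-derive
# results by the dumbest possible route (nested loops, direct tallies) so
# they share no code with the implementation they check.

# direct 2-D convolution with reflect padding, scalar loops
oracle_conv2 <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ry <- (kh - 1) %/% 2; rx <- (kw - 1) %/% 2
  h <- nrow(m); w <- ncol(m)
  refl <- function(i, n) {
    if (i < 1) return(2 - i)
    if (i > n) return(2 * n - i)
    i
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    acc <- 0
    for (dy in -ry:ry) for (dx in -rx:rx) {
      # convolution: kernel index mirrored relative to the offset
      acc <- acc + kernel[ry + 1 - dy, rx + 1 - dx] *
        m[refl(r + dy, h), refl(cc + dx, w)]
    }
    out[r, cc] <- acc
  }
  out
}

# per-class precision/recall/F1 tallied straight from records
oracle_report <- function(truth, pred) {
  classes <- sort(union(truth, pred))
  do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(crop = cl, precision = p, recall = r, f1 = f,
               support = sum(truth == cl))
  }))
}

# random labeled-record tibble over a small crop alphabet
random_records <- function(n, n_classes = 4) {
  crops <- crop_canon()[seq_len(n_classes)]
  tibble::tibble(
    district = paste0("d", seq_len(n)),
    dominant_crop = sample(crops, n, replace = TRUE),
    predicted_crops = purrr::map(seq_len(n),
                                 ~ sample(crops, sample.int(n_classes, 1)))
  )
}

table4_path <- function() {
  system.file("extdata", "table4_records.csv", package = "cropsight")
}

random_raster <- function(h, w, bands = 1) {
  raster_image(array(stats::runif(h * w * bands), dim = c(h, w, bands)))
}

# one-row categorized table, neutral defaults overridable per field
cat_row <- function(temp_band = "moderate", humidity_level = "moderate",
                    wind_level = "low", precip_level = "low",
                    uv_level = "low", soil_level = "low",
                    terrain = "plain") {
  tibble::tibble(temp_band = temp_band, humidity_level = humidity_level,
                 wind_level = wind_level, precip_level = precip_level,
                 uv_level = uv_level, soil_level = soil_level,
                 terrain = terrain)
}

all_category_combos <- function() {
  expand.grid(temp_band = c("hot", "moderate", "cool"),
              humidity_level = c("low", "moderate", "high"),
              wind_level = c("low", "high"),
              precip_level = c("low", "high"),
              uv_level = c("low", "high"),
              soil_level = c("low", "high"),
              terrain = c("plain", "hilly"),
              stringsAsFactors = FALSE)
}
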