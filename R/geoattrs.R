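#' Threshold configuration for attribute categorization
#'
#' Cut-points mapping continuous environmental attributes onto the discrete
#' levels the rule engine branches on. Temperature above `temp_hot_c` is
#' "hot"; the closed band `[temp_moderate_lo_c, temp_hot_c]` is "moderate"
#' (so exactly 30 degrees C is moderate — "exceeds" read strictly); below is
#' "cool". Humidity is three-level (low / moderate / high); wind,
#' precipitation, UV and soil moisture are two-level with `>=` on the high
#' side. The UV default follows the WHO convention that an index of 6 or
#' more is high.
#'
#' @param temp_hot_c,temp_moderate_lo_c temperature cut-points, degrees C.
#' @param humidity_low_pct,humidity_high_pct relative-humidity cut-points, %.
#' @param wind_high_kmh wind threshold, km/h.
#' @param precip_high_mm_day precipitation threshold, mm/day.
#' @param uv_high UV-index threshold.
#' @param soil_high_vwc volumetric soil-moisture threshold, fraction.
#' @return a list of class `threshold_config`.
#' @export
threshold_config <- function(temp_hot_c = 30, temp_moderate_lo_c = 20,
                             humidity_low_pct = 40, humidity_high_pct = 70,
                             wind_high_kmh = 20, precip_high_mm_day = 10,
                             uv_high = 6, soil_high_vwc = 0.30) {
  stopifnot(temp_moderate_lo_c < temp_hot_c,
            humidity_low_pct < humidity_high_pct)
  structure(list(temp_hot_c = temp_hot_c,
                 temp_moderate_lo_c = temp_moderate_lo_c,
                 humidity_low_pct = humidity_low_pct,
                 humidity_high_pct = humidity_high_pct,
                 wind_high_kmh = wind_high_kmh,
                 precip_high_mm_day = precip_high_mm_day,
                 uv_high = uv_high, soil_high_vwc = soil_high_vwc),
            class = "threshold_config")
}

attr_columns <- c("location_name", "temperature_c", "humidity_pct",
                  "wind_kmh", "precip_mm_day", "uv_index",
                  "soil_moisture_vwc", "terrain")

validate_attributes <- function(df) {
  missing <- setdiff(attr_columns, names(df))
  if (length(missing)) {
    stop("attribute table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(ok, field) {
    if (any(!ok)) {
      stop(sprintf("invalid %s in row(s) %s", field,
                   paste(which(!ok), collapse = ", ")), call. = FALSE)
    }
  }
  bad_row(df$humidity_pct >= 0 & df$humidity_pct <= 100, "humidity_pct")
  bad_row(df$soil_moisture_vwc >= 0 & df$soil_moisture_vwc <= 1,
          "soil_moisture_vwc")
  bad_row(df$uv_index >= 0, "uv_index")
  bad_row(df$wind_kmh >= 0, "wind_kmh")
  bad_row(df$precip_mm_day >= 0, "precip_mm_day")
  bad_row(df$terrain %in% c("plain", "hilly"), "terrain")
  tibble::as_tibble(df[, attr_columns])
}

#' Load environmental attribute records
#'
#' Reads a JSON array of objects or a CSV file with columns
#' `location_name`, `temperature_c`, `humidity_pct`, `wind_kmh`,
#' `precip_mm_day`, `uv_index`, `soil_moisture_vwc`,
#' `terrain` (`"plain"` or `"hilly"`). Records violating the field
#' invariants (humidity outside 0-100, soil moisture outside 0-1, negative
#' UV/wind/precipitation, unknown terrain) are rejected with the offending
#' row index.
#'
#' @param path JSON or CSV file path.
#' @return a tibble, one row per location.
#' @export
load_attributes <- function(path) {
  if (!file.exists(path)) stop("no such attribute file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    jsonlite::fromJSON(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_attributes(as.data.frame(df))
}

#' Categorize attributes into rule-engine levels
#'
#' Maps each attribute row onto the discrete levels the crop rules branch
#' on. Total: every finite attribute vector gets exactly one level per
#' dimension, and raising an attribute never moves its level downward.
#'
#' @param attrs tibble of attribute records (see [load_attributes()]).
#' @param cfg a [threshold_config()].
#' @return the input tibble with added columns `temp_band`
#'   (hot/moderate/cool), `humidity_level` (low/moderate/high), `wind_level`,
#'   `precip_level`, `uv_level`, `soil_level` (low/high each).
#' @examples
#' categorize(tibble::tibble(location_name = "x", temperature_c = 32,
#'   humidity_pct = 35, wind_kmh = 5, precip_mm_day = 2, uv_index = 4,
#'   soil_moisture_vwc = 0.2, terrain = "plain"))
#' @export
categorize <- function(attrs, cfg = threshold_config()) {
  attrs <- validate_attributes(as.data.frame(attrs))
  dplyr::mutate(
    attrs,
    temp_band = dplyr::case_when(
      .data$temperature_c > cfg$temp_hot_c ~ "hot",
      .data$temperature_c >= cfg$temp_moderate_lo_c ~ "moderate",
      TRUE ~ "cool"
    ),
    humidity_level = dplyr::case_when(
      .data$humidity_pct >= cfg$humidity_high_pct ~ "high",
      .data$humidity_pct <= cfg$humidity_low_pct ~ "low",
      TRUE ~ "moderate"
    ),
    wind_level = ifelse(.data$wind_kmh >= cfg$wind_high_kmh, "high", "low"),
    precip_level = ifelse(.data$precip_mm_day >= cfg$precip_high_mm_day,
                          "high", "low"),
    uv_level = ifelse(.data$uv_index >= cfg$uv_high, "high", "low"),
    soil_level = ifelse(.data$soil_moisture_vwc >= cfg$soil_high_vwc,
                        "high", "low")
  )
}
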