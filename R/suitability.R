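#' Canonical crop order
#'
#' Fixed tie-break order for rankings: crops in order of first appearance in
#' the decision narrative the rulebase transcribes.
#'
#' @return character vector of crop names.
#' @export
crop_canon <- function() {
  c("Groundnut", "Sunflower", "Millets", "Cotton", "Rice", "Sugarcane",
    "Ragi", "Maize", "Pigeon pea", "Chickpea", "Tomato", "Brinjal", "Okra",
    "Mango", "Banana", "Guava", "Coffee", "Tea")
}

moderate_band_crops <- function() {
  c("Rice", "Ragi", "Maize", "Pigeon pea", "Chickpea", "Tomato", "Brinjal",
    "Okra", "Mango", "Banana", "Guava")
}

#' Built-in crop rulebase
#'
#' The decision narrative transcribed as data. Additive rules vote (weight 1
#' per fired rule) for their crops; restrictive rules (high wind, high UV)
#' multiply the scores of crops outside their tolerant set by a penalty
#' factor of 0.5. The wind-resistant and UV-tolerant memberships are
#' editorial defaults — the narrative names the properties, not the lists —
#' and can be edited via YAML ([write_rulebase()] / [read_rulebase()]).
#'
#' @return a tibble with columns `rule_id`, `stage`, `type`
#'   (additive/restrictive), `when` (list of level requirements), `crops`
#'   (list of crop names: voted-for if additive, tolerated if restrictive),
#'   `weight`, `penalty`.
#' @examples
#' builtin_rulebase()
#' @export
builtin_rulebase <- function() {
  rule <- function(rule_id, stage, type, when, crops, weight = 1,
                   penalty = NA_real_) {
    tibble::tibble(rule_id = rule_id, stage = stage, type = type,
                   when = list(when), crops = list(crops), weight = weight,
                   penalty = penalty)
  }
  dplyr::bind_rows(
    rule("hot_dry", "temperature_humidity", "additive",
         list(temp_band = "hot", humidity_level = "low"),
         c("Groundnut", "Sunflower", "Millets", "Cotton")),
    rule("hot_humid", "temperature_humidity", "additive",
         list(temp_band = "hot", humidity_level = "high"),
         c("Rice", "Sugarcane")),
    rule("moderate", "temperature_humidity", "additive",
         list(temp_band = "moderate"),
         moderate_band_crops()),
    rule("moderate_hilly", "temperature_humidity", "additive",
         list(temp_band = "moderate", terrain = "hilly"),
         c("Coffee", "Tea")),
    rule("wind_high", "wind", "restrictive",
         list(wind_level = "high"),
         c("Millets", "Ragi", "Sugarcane", "Groundnut"),
         penalty = 0.5),
    rule("precip_high", "precipitation", "additive",
         list(precip_level = "high"),
         c("Rice", "Sugarcane")),
    rule("precip_low", "precipitation", "additive",
         list(precip_level = "low"),
         c("Millets", "Groundnut", "Sunflower")),
    rule("uv_high", "uv", "restrictive",
         list(uv_level = "high"),
         c("Millets", "Groundnut", "Sunflower", "Cotton", "Sugarcane"),
         penalty = 0.5),
    rule("soil_high", "soil_moisture", "additive",
         list(soil_level = "high"),
         c("Rice", "Sugarcane", "Mango", "Guava", "Banana")),
    rule("soil_low", "soil_moisture", "additive",
         list(soil_level = "low"),
         c("Millets", "Groundnut", "Sunflower"))
  )
}

#' Write / read a rulebase as YAML
#'
#' Round-trippable serialization so the rules can be edited without code.
#'
#' @param rules a rulebase tibble (see [builtin_rulebase()]).
#' @param path YAML file path.
#' @return `read_rulebase()` returns the rulebase tibble; `write_rulebase()`
#'   returns `path` invisibly.
#' @export
write_rulebase <- function(rules, path) {
  lst <- purrr::pmap(rules, function(rule_id, stage, type, when, crops,
                                     weight, penalty) {
    out <- list(rule_id = rule_id, stage = stage, type = type, when = when,
                crops = as.list(crops), weight = weight)
    if (!is.na(penalty)) out$penalty <- penalty
    out
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_rulebase
#' @export
read_rulebase <- function(path) {
  lst <- yaml::read_yaml(path)
  dplyr::bind_rows(purrr::map(lst, function(r) {
    tibble::tibble(rule_id = r$rule_id, stage = r$stage, type = r$type,
                   when = list(r$when), crops = list(unlist(r$crops)),
                   weight = r$weight %||% 1,
                   penalty = r$penalty %||% NA_real_)
  }))
}

rule_matches <- function(when, cat_row) {
  all(purrr::imap_lgl(when, function(value, field) {
    identical(as.character(cat_row[[field]]), value)
  }))
}

rank_one <- function(cat_row, rules, k) {
  add <- rules[rules$type == "additive", ]
  fired <- purrr::map_lgl(add$when, rule_matches, cat_row = cat_row)
  scores <- stats::setNames(numeric(0), character(0))
  stages <- list()
  vote <- function(scores, crops, w) {
    for (cr in crops) {
      scores[cr] <- if (cr %in% names(scores)) scores[[cr]] + w else w
    }
    scores
  }
  for (i in which(fired)) {
    scores <- vote(scores, add$crops[[i]], add$weight[i])
    for (cr in add$crops[[i]]) {
      stages[[cr]] <- c(stages[[cr]], add$stage[i])
    }
  }
  if (!length(scores)) {
    # no additive branch covers this combination (e.g. cool temperatures):
    # fall back to the broad moderate-band list rather than returning nothing
    warning("no crop rule matched; falling back to the moderate-band list",
            call. = FALSE)
    scores <- vote(scores, moderate_band_crops(), 1)
    stages <- stats::setNames(as.list(rep("fallback",
                                          length(moderate_band_crops()))),
                              moderate_band_crops())
  }
  res <- rules[rules$type == "restrictive", ]
  for (i in seq_len(nrow(res))) {
    if (rule_matches(res$when[[i]], cat_row)) {
      outside <- setdiff(names(scores), res$crops[[i]])
      scores[outside] <- scores[outside] * res$penalty[i]
      for (cr in outside) {
        stages[[cr]] <- c(stages[[cr]], paste0(res$stage[i], "_penalty"))
      }
    }
  }
  canon <- match(names(scores), crop_canon())
  canon[is.na(canon)] <- length(crop_canon()) + seq_len(sum(is.na(canon)))
  ord <- order(-unlist(scores), canon)
  top <- utils::head(ord, k)
  tibble::tibble(
    crop = names(scores)[top],
    score = unname(unlist(scores))[top],
    rank = seq_along(top),
    stages = purrr::map_chr(names(scores)[top],
                            ~ paste(stages[[.x]], collapse = ";"))
  )
}

#' Rank crops for categorized attribute rows
#'
#' Runs the rule engine on each row of a categorized attribute table
#' (see [categorize()]). Deterministic: scores are the sum of fired additive
#' votes times restrictive penalties; ties break by the canonical crop
#' order.
#'
#' @param cat tibble with the categorical level columns (`temp_band`,
#'   `humidity_level`, `wind_level`, `precip_level`, `uv_level`,
#'   `soil_level`, `terrain`), e.g. the output of [categorize()].
#' @param rules rulebase tibble; defaults to [builtin_rulebase()].
#' @param k number of top crops to keep per row (>= 1).
#' @return a tibble with one row per (location, crop): `location_name` (if
#'   present in `cat`), `crop`, `score`, `rank`, `stages` (semicolon-joined
#'   provenance of the contributing rule stages).
#' @examples
#' cat <- tibble::tibble(temp_band = "hot", humidity_level = "low",
#'   wind_level = "low", precip_level = "low", uv_level = "low",
#'   soil_level = "low", terrain = "plain")
#' recommend(cat, k = 4)
#' @export
recommend <- function(cat, rules = builtin_rulebase(), k = 5) {
  stopifnot(nrow(rules) > 0)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  cat <- tibble::as_tibble(cat)
  need <- c("temp_band", "humidity_level", "wind_level", "precip_level",
            "uv_level", "soil_level", "terrain")
  missing <- setdiff(need, names(cat))
  if (length(missing)) {
    stop("categorized table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- purrr::map(seq_len(nrow(cat)), function(i) {
    r <- rank_one(cat[i, ], rules, k)
    if ("location_name" %in% names(cat)) {
      r <- dplyr::mutate(r, location_name = cat$location_name[i],
                         .before = 1)
    }
    r
  })
  dplyr::bind_rows(out)
}

#' Recommend crops for raw attribute records
#'
#' Composition of [categorize()] and [recommend()].
#'
#' @param attrs attribute tibble (see [load_attributes()]).
#' @param cfg a [threshold_config()].
#' @param rules rulebase tibble.
#' @param k top-k count.
#' @return ranked recommendation tibble (see [recommend()]).
#' @export
recommend_for_location <- function(attrs, cfg = threshold_config(),
                                   rules = builtin_rulebase(), k = 5) {
  recommend(categorize(attrs, cfg), rules = rules, k = k)
}
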