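rb <- builtin_rulebase()
rule_crops <- function(id) rb$crops[[which(rb$rule_id == id)]]

test_that("the built-in rules carry the narrative's crop sets verbatim", {
  expect_setequal(rule_crops("hot_dry"),
                  c("Groundnut", "Sunflower", "Millets", "Cotton"))
  expect_setequal(rule_crops("hot_humid"), c("Rice", "Sugarcane"))
  expect_setequal(rule_crops("moderate"),
                  c("Rice", "Ragi", "Maize", "Pigeon pea", "Chickpea",
                    "Tomato", "Brinjal", "Okra", "Mango", "Banana", "Guava"))
  expect_setequal(rule_crops("moderate_hilly"), c("Coffee", "Tea"))
  expect_setequal(rule_crops("precip_high"), c("Rice", "Sugarcane"))
  expect_setequal(rule_crops("precip_low"),
                  c("Millets", "Groundnut", "Sunflower"))
  expect_setequal(rule_crops("soil_high"),
                  c("Rice", "Sugarcane", "Mango", "Guava", "Banana"))
  expect_setequal(rule_crops("soil_low"),
                  c("Millets", "Groundnut", "Sunflower"))
  expect_true(all(rb$type[rb$rule_id %in% c("wind_high", "uv_high")] ==
                    "restrictive"))
})

test_that("hot-dry scoring matches the hand-summed votes", {
  r <- recommend(cat_row(temp_band = "hot", humidity_level = "low"), k = 10)
  # hot_dry + precip_low + soil_low: drought trio gets 3, Cotton 1
  expect_equal(r$score[r$crop %in% c("Groundnut", "Sunflower", "Millets")],
               rep(3, 3))
  expect_equal(r$score[r$crop == "Cotton"], 1)
  expect_equal(r$crop[1:3], c("Groundnut", "Sunflower", "Millets"))
  expect_true(which(r$crop == "Cotton") == 4)
})

test_that("hilly moderate regions bring Coffee and Tea into the list", {
  r <- recommend(cat_row(terrain = "hilly"), k = 20)
  expect_true(all(c("Coffee", "Tea") %in% r$crop))
  plains <- recommend(cat_row(terrain = "plain"), k = 20)
  expect_false(any(c("Coffee", "Tea") %in% plains$crop))
})

test_that("high soil moisture puts Rice first for a wet location", {
  attrs <- tibble::tibble(location_name = "wetland", temperature_c = 25,
                          humidity_pct = 75, wind_kmh = 5,
                          precip_mm_day = 20, uv_index = 3,
                          soil_moisture_vwc = 0.45, terrain = "plain")
  r <- recommend_for_location(attrs, k = 5)
  # Rice is voted by the moderate band, high precipitation and high soil
  expect_equal(r$crop[1], "Rice")
  expect_equal(r$score[1], 3)
})

test_that("uncovered conditions fall back to the moderate band with a warning", {
  # with the full rulebase the precipitation/soil stages vote on every
  # combination, so exercise the fallback with the temperature stage alone
  temp_only <- rb[rb$stage == "temperature_humidity", ]
  expect_warning(r <- recommend(cat_row(temp_band = "cool"),
                                rules = temp_only, k = 5),
                 "falling back")
  expect_gt(nrow(r), 0)
  expect_true(all(r$crop %in% c("Rice", "Ragi", "Maize", "Pigeon pea",
                                "Chickpea", "Tomato", "Brinjal", "Okra",
                                "Mango", "Banana", "Guava")))
})

test_that("all 288 category combinations yield valid deterministic rankings", {
  combos <- all_category_combos()
  expect_equal(nrow(combos), 288L)
  for (i in seq_len(nrow(combos))) {
    r1 <- suppressWarnings(recommend(combos[i, ], k = 25))
    r2 <- suppressWarnings(recommend(combos[i, ], k = 25))
    expect_identical(r1, r2)
    expect_gt(nrow(r1), 0)
    expect_equal(anyDuplicated(r1$crop), 0L)
    expect_true(all(diff(r1$score) <= 1e-12))
  }
})

test_that("restrictive wind rule never lets unresistant crops outrank", {
  r <- recommend(cat_row(temp_band = "hot", humidity_level = "low",
                         wind_level = "high"), k = 10)
  resistant <- c("Millets", "Ragi", "Sugarcane", "Groundnut")
  # Groundnut/Millets keep score 3; Sunflower and Cotton are halved
  expect_equal(r$crop[1:2], c("Groundnut", "Millets"))
  expect_equal(r$score[r$crop == "Sunflower"], 1.5)
  expect_equal(r$score[r$crop == "Cotton"], 0.5)
  expect_true(max(which(r$crop %in% resistant)) <
                min(which(!r$crop %in% resistant)))
})

test_that("scores equal a brute-force re-tally of fired rules", {
  combos <- all_category_combos()
  withr::with_seed(29, idx <- sample.int(nrow(combos), 40))
  for (i in idx) {
    row <- combos[i, ]
    r <- suppressWarnings(recommend(row, k = 25))
    matches_when <- function(when) {
      all(vapply(names(when), function(f)
        identical(as.character(row[[f]]), when[[f]]), logical(1)))
    }
    fired_add <- vapply(seq_len(nrow(rb)), function(j)
      rb$type[j] == "additive" && matches_when(rb$when[[j]]), logical(1))
    expected <- sapply(r$crop, function(cr) {
      base <- sum(vapply(which(fired_add), function(j)
        if (cr %in% rb$crops[[j]]) rb$weight[j] else 0, numeric(1)))
      if (base == 0) base <- 1   # fallback vote
      for (j in which(rb$type == "restrictive")) {
        if (matches_when(rb$when[[j]]) && !cr %in% rb$crops[[j]]) {
          base <- base * rb$penalty[j]
        }
      }
      base
    })
    expect_equal(r$score, unname(expected))
  }
})

test_that("the rulebase round-trips through YAML unchanged", {
  p <- withr::local_tempfile(fileext = ".yaml")
  write_rulebase(rb, p)
  expect_identical(read_rulebase(p), rb)
})

test_that("recommend validates its inputs", {
  expect_error(recommend(cat_row(), k = 0), "k must be")
  expect_error(recommend(tibble::tibble(temp_band = "hot")), "lacks column")
})
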