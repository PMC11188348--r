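test_that("the default tree satisfies its structural contract", {
  tree <- default_fis_tree()
  expect_s3_class(tree, "fis_tree")
  expect_setequal(names(tree$leaves), c("air", "water", "soil", "noise"))
  expect_setequal(names(tree$root$inputs),
                  vapply(tree$leaves, function(s) s$output$name, ""))
  for (s in c(tree$leaves, list(tree$root))) {
    expect_equal(s$output$universe, c(0, 1))
  }
  expect_setequal(names(tree$variables),
                  c("pm25", "no2", "pm10", "o3", "heavy_metal",
                    "dissolved_oxygen", "ph", "organic_matter", "n_p",
                    "noise_level"))
  # mismatched root raises a config error
  expect_error(new_fis_tree(tree$leaves["air"], tree$root),
               class = "config_error")
})

test_that("risk respects each variable's configured direction on a grid", {
  tree <- default_fis_tree()
  scan <- tree_monotonicity(tree, n_grid = 5)
  expect_true(all(scan$monotone))
  expect_equal(scan$direction[scan$variable == "dissolved_oxygen"],
               "decreasing")
  expect_equal(scan$direction[scan$variable == "ph"], "vshape")
})

test_that("the tree saturates sensibly and centres near mid-risk", {
  tree <- default_fis_tree()
  benign <- list(pm25 = 0, no2 = 0, pm10 = 0, o3 = 0, heavy_metal = 0,
                 dissolved_oxygen = 14, ph = 7.5, organic_matter = 0,
                 n_p = 0, noise_level = 40,
                 temperature = 22, wind_speed = 1, relative_humidity = 70,
                 site = "s", timestamp = "t")
  extreme <- list(pm25 = 100, no2 = 80, pm10 = 160, o3 = 200,
                  heavy_metal = 0.1, dissolved_oxygen = 0, ph = 0,
                  organic_matter = 8, n_p = 1500, noise_level = 90,
                  temperature = 35, wind_speed = 0, relative_humidity = 20,
                  site = "s", timestamp = "t")
  a_b <- assess_record(benign)
  a_e <- assess_record(extreme)
  expect_lt(a_b$risk, 0.2)
  expect_true(all(a_b$sub_scores < 0.2))
  expect_gt(a_e$risk, 0.8)
  # every-variable midpoint sits in the central risk band
  mids <- lapply(default_tree_config()$variables,
                 function(v) mean(v$universe))
  mid_risk <- urbanhealth:::assess_risk_values(default_fis_tree(), mids)
  expect_gte(mid_risk, 0.35)
  expect_lte(mid_risk, 0.65)
})

test_that("risk stays in [0, 1] for arbitrary valid records", {
  tree <- default_fis_tree()
  recs <- make_records(50, seed = 99)
  out <- assess_batch(recs, tree)
  expect_true(all(out$risk >= 0 & out$risk <= 1))
  expect_true(all(as.matrix(out[c("air", "water", "soil", "noise")]) >= 0))
  expect_true(all(as.matrix(out[c("air", "water", "soil", "noise")]) <= 1))
})

test_that("hierarchical and flat encodings agree at crisp saturation points", {
  # two single-variable leaves with near-step terms; at saturated inputs the
  # leaf outputs hit their consequent levels and the root reduces to the
  # same lookup a flat two-input grid encodes
  steep <- function(center, sign, base = 1) mf_sigmoid(center, sign * 400, base)
  leaf_var <- function(nm) fuzzy_variable(nm, c(0, 1),
    list(low = steep(0.5, -1), high = steep(0.5, 1)))
  out_var <- function(nm) fuzzy_variable(nm, c(0, 1),
    list(low = mf_gaussian(0.1, 0.15), high = mf_gaussian(0.9, 0.15)))
  leaf <- function(vn, on) fuzzy_system(list(leaf_var(vn)), out_var(on),
    list(fuzzy_rule(stats::setNames("low", vn), "low"),
         fuzzy_rule(stats::setNames("high", vn), "high")))
  score_var <- function(nm) fuzzy_variable(nm, c(0, 1),
    list(low = steep(0.5, -1), high = steep(0.5, 1)))
  levels <- c(ll = 0.1, lh = 0.4, hl = 0.6, hh = 0.9)
  root <- fuzzy_system(list(score_var("a"), score_var("b")),
                       out_var("risk"),
                       list(fuzzy_rule(c(a = "low", b = "low"), 0.1),
                            fuzzy_rule(c(a = "low", b = "high"), 0.4),
                            fuzzy_rule(c(a = "high", b = "low"), 0.6),
                            fuzzy_rule(c(a = "high", b = "high"), 0.9)))
  tree <- new_fis_tree(list(a = leaf("x1", "a"), b = leaf("x2", "b")), root)
  flat <- fuzzy_system(list(leaf_var("x1"), leaf_var("x2")),
                       out_var("risk"),
                       list(fuzzy_rule(c(x1 = "low", x2 = "low"), 0.1),
                            fuzzy_rule(c(x1 = "low", x2 = "high"), 0.4),
                            fuzzy_rule(c(x1 = "high", x2 = "low"), 0.6),
                            fuzzy_rule(c(x1 = "high", x2 = "high"), 0.9)))
  for (x1 in c(0.05, 0.95)) {
    for (x2 in c(0.05, 0.95)) {
      vals <- list(x1 = x1, x2 = x2)
      expect_equal(
        urbanhealth:::assess_risk_values(tree, vals),
        evaluate_fis(flat, vals)$output,
        tolerance = 1e-6)
    }
  }
})

test_that("trees survive a YAML round trip", {
  tree <- default_fis_tree()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fis_tree(tree, path)
  back <- read_fis_tree(path)
  recs <- make_records(10, seed = 5)
  a1 <- assess_batch(recs, tree)
  a2 <- assess_batch(recs, back)
  expect_equal(a2$risk, a1$risk, tolerance = 1e-12)
  expect_equal(names(back$leaves), names(tree$leaves))
})
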