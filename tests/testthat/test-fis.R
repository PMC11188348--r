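test_that("membership functions match their closed forms", {
  expect_equal(membership(mf_sigmoid(2, 1), 2), 0.5)
  expect_equal(membership(mf_sigmoid(0, 1), log(3)), 0.75,
               tolerance = 1e-12)
  # saturation stays inside the open unit interval
  expect_lt(membership(mf_sigmoid(0, 5), 1e6), 1)
  expect_gt(membership(mf_sigmoid(0, 5), 1e6), 1 - 1e-9)
  expect_gt(membership(mf_sigmoid(0, 5), -1e6), 0)
  # base rescales the axis, sign of steepness flips direction
  expect_equal(membership(mf_sigmoid(0, 2, base = 4), 1),
               membership(mf_sigmoid(0, 1, base = 2), 1))
  expect_equal(membership(mf_sigmoid(0, -1), 3),
               1 - membership(mf_sigmoid(0, 1), 3), tolerance = 1e-12)

  expect_equal(membership(mf_gaussian(5, 2), 5), 1.0)
  expect_equal(membership(mf_gaussian(5, 2), 7), exp(-0.5))
  expect_equal(membership(mf_gaussian(5, 2), 1), exp(-2))

  tri <- mf_triangular(0, 1, 3)
  expect_equal(membership(tri, c(-1, 0, 0.5, 1, 2, 3, 4)),
               c(0, 0, 0.5, 1, 0.5, 0, 0))
  expect_error(mf_triangular(1, 0, 3), class = "domain_error")
  expect_error(mf_gaussian(0, 0), class = "domain_error")
  expect_error(mf_sigmoid(0, 1, base = 0), class = "domain_error")
})

test_that("fuzzification returns per-term degrees and clamps excursions", {
  v <- fuzzy_variable("x", c(0, 10), list(
    low = mf_sigmoid(3, -2), high = mf_sigmoid(7, 2)))
  d <- fuzzify(3, v)
  expect_equal(unname(d["low"]), 0.5)
  # saturation far below all centers
  v3 <- fuzzy_variable("x", c(-100, 100), list(
    a = mf_sigmoid(0, 1), b = mf_sigmoid(10, 1), c = mf_sigmoid(20, 1)))
  d3 <- fuzzify(-100, v3)
  expect_true(all(d3 < 1e-9))
  # degrees equal direct per-term membership evaluation
  set.seed(11)
  for (x in runif(20, 0, 10)) {
    d <- fuzzify(x, v)
    expect_equal(unname(d),
                 c(oracle_membership(v$terms$low, x),
                   oracle_membership(v$terms$high, x)), tolerance = 1e-12)
  }
  expect_warning(fuzzify(12, v), class = "universe_clamp")
  expect_error(fuzzify(12, v, clamp = FALSE), class = "universe_error")
})

test_that("rule firing combines antecedents by the configured AND", {
  v1 <- fuzzy_variable("x1", c(0, 1), list(t = mf_gaussian(0.5, 1)))
  v2 <- fuzzy_variable("x2", c(0, 1), list(t = mf_gaussian(0.5, 1)))
  out <- fuzzy_variable("y", c(0, 1), list(t = mf_gaussian(0.5, 0.1)))
  deg <- list(x1 = c(t = 0.4), x2 = c(t = 0.9))
  mk <- function(op, w = 1) {
    fuzzy_system(list(v1, v2), out,
                 list(fuzzy_rule(c(x1 = "t", x2 = "t"), "t", weight = w)),
                 and_op = op)
  }
  expect_equal(fire_rules(mk("min"), deg)$strength, 0.4)
  expect_equal(fire_rules(mk("product"), deg)$strength, 0.36)
  expect_equal(fire_rules(mk("product", w = 0), deg)$strength, 0)
  single <- fuzzy_system(list(v1), out,
                         list(fuzzy_rule(c(x1 = "t"), "t")))
  expect_equal(fire_rules(single, list(x1 = c(t = 0.7)))$strength, 0.7)
  expect_error(fire_rules(mk("min"), list(x1 = c(t = 0.4))),
               class = "contract_error")
})

test_that("defuzzification is the strength-weighted consequent average", {
  expect_equal(defuzzify(0.3, 42), 42)
  expect_equal(defuzzify(c(0.2, 0.8), c(0, 1)), 0.8)
  expect_equal(defuzzify(c(1, 1, 1), c(10, 20, 30)), 20)
  expect_error(defuzzify(c(0, 0), c(1, 2)), class = "no_rule_fired")
})

test_that("system evaluation composes fuzzify, firing and defuzzification", {
  v <- fuzzy_variable("x", c(0, 1), list(
    low = mf_sigmoid(0.3, -20), high = mf_sigmoid(0.7, 20)))
  out <- fuzzy_variable("y", c(0, 1), list(
    low = mf_gaussian(0, 0.2), high = mf_gaussian(1, 0.2)))
  # constant-consequent system returns the constant for any input
  const <- fuzzy_system(list(v), out, list(
    fuzzy_rule(c(x = "low"), 0.7), fuzzy_rule(c(x = "high"), 0.7)))
  for (x in c(0, 0.33, 0.9, 1)) {
    expect_equal(evaluate_fis(const, c(x = x))$output, 0.7)
  }
  # monotone system saturates to its extreme consequents
  mono <- fuzzy_system(list(v), out, list(
    fuzzy_rule(c(x = "low"), "low"), fuzzy_rule(c(x = "high"), "high")))
  expect_lt(evaluate_fis(mono, c(x = 0))$output, 0.01)
  expect_gt(evaluate_fis(mono, c(x = 1))$output, 0.99)
  expect_error(evaluate_fis(mono, c(z = 1)), class = "contract_error")
})

test_that("scalar and batch evaluation agree with the straight-line oracle", {
  set.seed(101)
  for (i in 1:30) {
    sys <- random_fuzzy_system()
    vals <- random_system_values(sys)
    got <- evaluate_fis(sys, vals)$output
    expect_equal(got, oracle_evaluate_fis(sys, vals), tolerance = 1e-9)
    expect_equal(evaluate_fis_batch(sys, lapply(vals, rep, 2))[1], got,
                 tolerance = 1e-12)
  }
})

test_that("output is a convex combination and rule order is irrelevant", {
  set.seed(202)
  for (i in 1:20) {
    sys <- random_fuzzy_system()
    vals <- random_system_values(sys)
    res <- evaluate_fis(sys, vals)
    fired <- res$trace[res$trace$strength > 0, ]
    expect_gte(res$output, min(fired$consequent) - 1e-12)
    expect_lte(res$output, max(fired$consequent) + 1e-12)
    shuffled <- fuzzy_system(sys$inputs, sys$output,
                             sample(sys$rules), and_op = sys$and_op)
    expect_equal(evaluate_fis(shuffled, vals)$output, res$output,
                 tolerance = 1e-12)
  }
})

test_that("splitting a rule's weight in half leaves product-AND output unchanged", {
  set.seed(303)
  for (i in 1:10) {
    sys <- random_fuzzy_system()
    sys$and_op <- "product"
    r <- sys$rules[[1]]
    half1 <- fuzzy_rule(r$antecedent, r$consequent, r$weight / 2)
    split_sys <- fuzzy_system(sys$inputs, sys$output,
                              c(sys$rules[-1], list(half1, half1)),
                              and_op = "product")
    vals <- random_system_values(sys)
    expect_equal(evaluate_fis(split_sys, vals)$output,
                 evaluate_fis(sys, vals)$output, tolerance = 1e-12)
  }
})

test_that("with crisp memberships and one firing rule the system is a lookup table", {
  # near-step sigmoids make degrees effectively 0/1; away from the term
  # boundaries exactly one cell fires and the output is its consequent
  steep <- function(center, sign) mf_sigmoid(center, sign * 500)
  v1 <- fuzzy_variable("x1", c(0, 1), list(low = steep(0.5, -1),
                                           high = steep(0.5, 1)))
  v2 <- fuzzy_variable("x2", c(0, 1), list(low = steep(0.5, -1),
                                           high = steep(0.5, 1)))
  out <- fuzzy_variable("y", c(0, 100), list(k = mf_gaussian(50, 10)))
  lookup <- c(ll = 10, lh = 20, hl = 30, hh = 40)
  rules <- list(
    fuzzy_rule(c(x1 = "low", x2 = "low"), 10),
    fuzzy_rule(c(x1 = "low", x2 = "high"), 20),
    fuzzy_rule(c(x1 = "high", x2 = "low"), 30),
    fuzzy_rule(c(x1 = "high", x2 = "high"), 40))
  sys <- fuzzy_system(list(v1, v2), out, rules)
  cases <- list(c(0.1, 0.1, 10), c(0.1, 0.9, 20),
                c(0.9, 0.1, 30), c(0.9, 0.9, 40))
  for (cs in cases) {
    expect_equal(evaluate_fis(sys, c(x1 = cs[1], x2 = cs[2]))$output,
                 cs[3], tolerance = 1e-6)
  }
})
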