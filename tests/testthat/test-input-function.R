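test_that("input function obeys its interpolation contract", {
  ifn <- input_function(c(1, 2, 4), c(2, 4, 1))
  expect_equal(if_eval(ifn, 0.5), 0)           # zero before first sample
  expect_equal(if_eval(ifn, 1.5), 3)           # linear between samples
  # mono-exponential tail from the last two samples: rate log(4)/2
  r <- log(4) / 2
  expect_equal(if_eval(ifn, 6), exp(-2 * r), tolerance = 1e-12)
  # cumulative integral: exact trapezoid inside, analytic tail
  expect_equal(if_cumint(ifn, 2), 3)           # triangle 1-2 on [1,2]
  expect_equal(if_cumint(ifn, 4), 3 + 5)       # plus trapezoid [2,4]
  tail <- 1 * (1 - exp(-r * 2)) / r
  expect_equal(if_cumint(ifn, 6), 8 + tail, tolerance = 1e-12)
  expect_error(input_function(c(1, 1), c(2, 2)), "increasing")
})

test_that("blood merging scales the continuous segment and estimates the ratio", {
  cont <- data.frame(time = seq(0, 3, 0.1), value = 10)
  disc <- data.frame(time = c(2, 4, 10), value = c(8, 6, 3),
                     parent_fraction = NA)
  bd <- blood_data(cont, disc)
  m <- merge_blood_curves(bd, plasma_to_wb_ratio = 0.8)
  expect_equal(m$value[m$time <= 3], rep(8, 31))
  # estimated ratio from the earliest overlapping sample (2 min): 8/10
  m2 <- merge_blood_curves(bd)
  expect_equal(attr(m2, "plasma_to_wb_ratio"), 0.8)
  # discrete samples after the continuous span are appended
  expect_equal(m2$value[m2$time == 10], 3)
  expect_error(merge_blood_curves(blood_data(cont[0, ], disc)), "empty")
})

test_that("merging warns on a junction discontinuity", {
  cont <- data.frame(time = seq(0, 3, 0.1), value = 10)
  disc <- data.frame(time = c(2, 4), value = c(8, 6), parent_fraction = NA)
  bd <- blood_data(cont, disc)
  expect_warning(merge_blood_curves(bd, plasma_to_wb_ratio = 1.0),
                 "disagree")
  expect_silent(merge_blood_curves(bd, plasma_to_wb_ratio = 0.8))
})

test_that("parent-fraction fit recovers noiseless Hill parameters", {
  tt <- c(2, 4, 6, 10, 15, 20, 25, 30)
  truth <- hill_pf_params(floor = 0.03, t50 = 9, h = 1.8)
  pf <- simulate_parent_fraction(truth, tt)
  fit <- fit_parent_fraction(tt, pf)
  expect_equal(unname(fit$params["floor"]), 0.03, tolerance = 1e-6)
  expect_equal(unname(fit$params["t50"]), 9, tolerance = 1e-6)
  expect_equal(unname(fit$params["h"]), 1.8, tolerance = 1e-6)
  # predictions bounded and monotone non-increasing
  g <- predict(fit, seq(0, 40, 0.5))
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(diff(g) <= 1e-12))
})

test_that("parent-fraction fit handles degenerate inputs", {
  expect_error(fit_parent_fraction(c(2, 4), c(0.9, 0.8)), "at least 3")
  expect_error(fit_parent_fraction(rep(5, 4), c(0.9, 0.8, 0.7, 0.6)),
               "identical")
  const <- fit_parent_fraction(c(2, 10, 20, 30), rep(1, 4))
  expect_equal(predict(const, c(0, 15, 30)), rep(1, 3))
})

test_that("a study-like declining parent fraction fit stays below 10% at 30 min", {
  tt <- c(2, 4, 10, 20, 30)
  pf <- c(0.95, 0.83, 0.44, 0.17, 0.09)
  fit <- fit_parent_fraction(tt, pf)
  expect_lt(predict(fit, 30), 0.10)
})

test_that("metabolite correction multiplies pointwise and never raises activity", {
  plasma <- data.frame(time = c(0, 1, 5, 10, 30), value = c(0, 10, 4, 2, 1))
  ident <- metabolite_correct(plasma, 1.0)
  expect_equal(if_eval(ident, plasma$time), plasma$value)
  half <- metabolite_correct(plasma, 0.5)
  expect_equal(if_eval(half, plasma$time), plasma$value / 2)
  fit <- fit_parent_fraction(c(2, 4, 10, 20, 30),
                             simulate_parent_fraction(hill_pf_params(),
                                                      c(2, 4, 10, 20, 30)))
  flat <- data.frame(time = seq(0, 30, 0.5), value = 10)
  cp <- metabolite_correct(flat, fit)
  expect_lt(if_eval(cp, 30) / if_eval(cp, 0.01), 0.10)
  expect_true(all(if_eval(cp, flat$time) <= 10 + 1e-12))
  expect_error(metabolite_correct(data.frame(time = -1, value = 2), fit),
               "before injection")
})

test_that("plasma free fraction follows the corrected ultrafiltration ratio", {
  r <- plasma_free_fraction(139, 1000, 500, 500)
  expect_equal(r$fp, 0.139)
  expect_equal(r$protein_binding_pct, 86.1)
  r2 <- plasma_free_fraction(100, 1000, 720, 1000)
  expect_equal(r2$fp, 0.10 / 0.72, tolerance = 1e-12)
  # plasma ratio equal to control ratio: fully free
  r3 <- plasma_free_fraction(60, 100, 120, 200)
  expect_equal(r3$fp, 1.0)
  # scale invariance under common rescaling of all counts
  r4 <- plasma_free_fraction(100 * 7, 1000 * 7, 720 * 7, 1000 * 7)
  expect_equal(r4$fp, r2$fp)
  # duplicates averaged before the ratio
  r5 <- plasma_free_fraction(c(90, 110), c(990, 1010), c(700, 740), c(990, 1010))
  expect_equal(r5$fp, r2$fp)
  expect_error(plasma_free_fraction(1, 1, 0, 1), "positive")
})
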