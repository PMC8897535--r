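test_that("simulated input function has one peak near the delay and scales with pretreatment", {
  g <- seq(0, 63, by = 0.01)
  base <- simulate_input_function(feng_params(), g)
  peaks <- which(diff(sign(diff(base$cp))) == -2)
  expect_equal(length(peaks), 1)
  t_peak <- g[peaks + 1]
  expect_gte(t_peak - 0.5, 0.25)   # delay is 0.5 min
  expect_lte(t_peak - 0.5, 2)
  expect_true(all(base$cp >= 0))
  expect_equal(base$cp[g <= 0.5], rep(0, sum(g <= 0.5)))
  pre <- simulate_input_function(feng_params(peak_scale = 1.8), g)
  expect_equal(max(pre$cp), 1.8 * max(base$cp), tolerance = 1e-12)
  zero <- simulate_input_function(feng_params(A1 = 0, A2 = 0, A3 = 0), g)
  expect_true(all(zero$cp == 0))
  expect_error(simulate_input_function(feng_params(), c(1, 0.5)), "increasing")
})

test_that("simulated parent fraction starts at 1, declines monotonically, drops below 10% by 30 min", {
  tt <- seq(0, 60, 0.5)
  pf <- simulate_parent_fraction(hill_pf_params(), tt)
  expect_equal(pf[1], 1)
  expect_true(all(diff(pf) <= 0))
  expect_lt(pf[tt == 30], 0.10)
  expect_equal(simulate_parent_fraction(hill_pf_params(floor = 1), tt),
               rep(1, length(tt)))
  expect_error(simulate_parent_fraction(hill_pf_params(), -1), ">= 0")
})

test_that("tissue simulation is deterministic under a seed and zero for K1 = 0", {
  ifn <- make_test_if()
  sch <- frame_schedule("brain63")
  a <- simulate_tissue_tac(c(0.8, 0.6, 0.7), ifn, sch, noise_level = 0.05,
                           seed = 42)
  b <- simulate_tissue_tac(c(0.8, 0.6, 0.7), ifn, sch, noise_level = 0.05,
                           seed = 42)
  expect_identical(a$activity, b$activity)
  z <- simulate_tissue_tac(c(0, 0.6, 0.7), ifn, sch)
  expect_true(all(z$activity == 0))
  expect_error(simulate_tissue_tac(c(0.8, 0.6, 0.7), ifn, sch,
                                   noise_level = -1), ">= 0")
})

test_that("frame noise variance grows with the square of the noise level", {
  ifn <- make_test_if()
  sch <- frame_schedule("brain63")
  kp <- c(0.849, 0.645, 0.750)
  frame <- 20
  draws <- function(nl) {
    vapply(1:200, function(i) {
      simulate_tissue_tac(kp, ifn, sch, noise_level = nl,
                          seed = 5000 * nl + i)$activity[frame]
    }, numeric(1))
  }
  v1 <- stats::var(draws(0.05))
  v2 <- stats::var(draws(0.10))
  expect_gt(v2 / v1, 4 * 0.6)
  expect_lt(v2 / v1, 4 * 1.7)
})

test_that("study simulation honours occupancy limits and truth bookkeeping", {
  sc0 <- study_scenario(occupancies = 0)
  st0 <- simulate_study(sc0)
  # occupancy 0: pretreatment tissue identical to baseline kinetics would
  # give equal TACs if the input function were unchanged; compare Ki truth
  expect_equal(st0$truth$occupancies, 0)
  sc1 <- study_scenario(occupancies = 1)
  st1 <- simulate_study(sc1)
  # full blocking: pretreatment Patlak slope ~ 0
  ifn <- st1$pretreatment[[1]]$cp_true
  tac <- region_tac(st1$pretreatment[[1]]$tacs, "cerebellum")
  expect_lt(patlak(tac, ifn)$slope, 1e-6)
  expect_error(study_scenario(occupancies = 1.2), "\\[0, 1\\]")
})

test_that("study simulation is reproducible byte-for-byte under a seed", {
  sc <- study_scenario(occupancies = c(0.5), noise_level = 0.05, seed = 9)
  a <- simulate_study(sc)
  b <- simulate_study(sc)
  expect_identical(serialize(a$baseline$tacs$activity, NULL),
                   serialize(b$baseline$tacs$activity, NULL))
  expect_identical(serialize(a$pretreatment[[1]]$tacs$activity, NULL),
                   serialize(b$pretreatment[[1]]$tacs$activity, NULL))
})

test_that("drug concentration series reproduce the target Cave on the Emax curve", {
  sc <- study_scenario(occupancies = c(0.25, 0.5, 0.75, 0.95), ec50 = 5)
  st <- simulate_study(sc)
  for (j in seq_along(st$pretreatment)) {
    cv <- cave(st$pretreatment[[j]]$conc)
    expect_equal(as.numeric(cv), st$truth$caves[j], tolerance = 1e-9)
    occ_pred <- 100 * as.numeric(cv) / (5 + as.numeric(cv))
    expect_equal(occ_pred, 100 * st$truth$occupancies[j], tolerance = 1e-9)
  }
  # fitting the truth pairs recovers the scenario EC50 essentially exactly
  fit <- fit_emax(st$truth$caves, 100 * st$truth$occupancies)
  expect_equal(fit$ec50, 5, tolerance = 1e-6)
})

test_that("whole-body simulation conserves activity and ranks organs as specified", {
  wb <- simulate_wholebody()
  total <- tapply(wb$pct_id, wb$time, sum)
  expect_true(all(total <= 100 + 1e-9))
  peaks <- tapply(wb$pct_id, wb$organ, max)
  top4 <- names(sort(peaks, decreasing = TRUE))[1:4]
  expect_setequal(top4, c("liver", "small intestine", "kidney", "brain"))
  expect_equal(unname(peaks["brain"]), 7, tolerance = 0.01)
  # single organ, full uptake, no clearance: constant 100 %ID
  one <- simulate_wholebody(data.frame(organ = "whole body", fraction = 1,
                                       uptake_rate = Inf, clearance_rate = 0))
  expect_equal(one$pct_id, rep(100, nrow(one)))
  # two organs without clearance stay at their fractions
  two <- simulate_wholebody(data.frame(organ = c("a", "b"),
                                       fraction = c(0.4, 0.6),
                                       uptake_rate = Inf,
                                       clearance_rate = 0))
  expect_equal(as.numeric(tapply(two$pct_id, two$organ, unique)), c(40, 60))
  expect_error(simulate_wholebody(data.frame(organ = c("a", "b"),
                                             fraction = c(0.7, 0.6),
                                             uptake_rate = Inf,
                                             clearance_rate = 0)),
               "at most 1")
})

test_that("whole-body pass times span about 100 minutes", {
  pt <- wholebody_pass_times()
  expect_equal(length(pt), 15)
  expect_gt(max(pt), 90)
  expect_lt(max(pt), 105)
  expect_true(all(diff(pt) > 0))
})
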