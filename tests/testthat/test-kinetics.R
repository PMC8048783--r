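test_that("a linear decay gives slope/p450 for any window", {
  tc <- tibble::tibble(time_min = seq(0, 300, 30),
                       substrate_uM = 2000 - 6 * seq(0, 300, 30))
  res <- ton_from_timecourse(tc, p450_total = 3, window_min = 120)
  expect_equal(res$ton, 2.0, tolerance = 1e-10)
  expect_false(res$no_consumption)
  res2 <- ton_from_timecourse(tc, p450_total = 3, window_min = 60)
  expect_equal(res2$ton, 2.0, tolerance = 1e-10)
})

test_that("the steepest window is found in a flat-steep-flat course", {
  t <- seq(0, 360, 15)
  s <- 2000 - pmin(pmax(t - 60, 0), 120) * 9
  tc <- tibble::tibble(time_min = t, substrate_uM = s)
  res <- ton_from_timecourse(tc, p450_total = 3, window_min = 120)
  expect_equal(res$ton, 3.0, tolerance = 1e-10)
  expect_equal(unname(res$window), c(60, 180))
})

test_that("an increasing trace clamps to zero with a flag", {
  tc <- tibble::tibble(time_min = seq(0, 240, 30),
                       substrate_uM = seq(100, 500, length.out = 9))
  res <- ton_from_timecourse(tc, p450_total = 3)
  expect_equal(res$ton, 0)
  expect_true(res$no_consumption)
  expect_true(glance(res)$no_consumption)
})

test_that("TON is invariant to substrate offset and time translation", {
  gen <- gen_timecourse(ton_true = 4.47, seed = 61)
  tc <- gen$timecourse
  base <- ton_from_timecourse(tc, p450_total = 3)$ton
  shifted <- dplyr::mutate(tc, substrate_uM = substrate_uM + 500)
  expect_equal(ton_from_timecourse(shifted, 3)$ton, base, tolerance = 1e-12)
  lagged <- dplyr::mutate(tc, time_min = time_min + 37)
  expect_equal(ton_from_timecourse(lagged, 3)$ton, base, tolerance = 1e-12)
})

test_that("time-course validation catches degenerate inputs", {
  expect_error(ton_from_timecourse(
    tibble::tibble(time_min = c(0, 10), substrate_uM = c(1, 2)), 3),
    "insufficient")
  expect_error(ton_from_timecourse(
    tibble::tibble(time_min = c(0, 10, 5), substrate_uM = c(1, 2, 3)), 3),
    "increasing")
  expect_error(ton_from_timecourse(
    tibble::tibble(time_min = c(0, 10, 20), substrate_uM = 1:3), 0),
    "p450")
})

test_that("coupling efficiency is plain stoichiometric arithmetic", {
  expect_equal(as.numeric(coupling_efficiency(200, 200)), 100)
  expect_equal(as.numeric(coupling_efficiency(0, 200)), 0)
  expect_equal(as.numeric(coupling_efficiency(84, 200)), 42)
  over <- coupling_efficiency(250, 200)
  expect_true(attr(over, "implausible"))
  expect_error(coupling_efficiency(10, 0), "domain")
  # exact arithmetic round trip
  ce <- as.numeric(coupling_efficiency(84, 200))
  expect_equal(ce * 200 / 100, 84)
})

test_that("Beer-Lambert converters match hand arithmetic", {
  expect_equal(nadh_consumed_from_abs(1.444, 0.2), 200, tolerance = 1e-9)
  expect_equal(nadh_consumed_from_abs(1, 1), 0)
  expect_equal(nadh_consumed_from_abs(0.822, 0.2, path_cm = 0.5), 200,
               tolerance = 1e-9)
  expect_warning(nadh_consumed_from_abs(0.1, 0.2), "negative")

  expect_equal(etc_activity(0, 1, 1), 0)
  expect_equal(etc_activity(0.0191, 1, 1), 0.001)
  withr::with_seed(62, {
    for (i in 1:10) {
      sl <- runif(1, 0, 0.5); vr <- runif(1, 0.5, 2); vs <- runif(1, 0.01, 0.2)
      want <- sl / 19.1 * vr / vs
      expect_equal(etc_activity(sl, vr, vs), want)
    }
  })
  expect_error(etc_activity(-1, 1, 1), "domain")
  expect_error(etc_activity(1, 0, 1), "domain")

  expect_equal(p450_conc_from_co_difference(0.091), 1.0)
  expect_equal(p450_conc_from_co_difference(0), 0)
  expect_equal(p450_conc_from_co_difference(0.091, path_cm = 2), 0.5)
  expect_warning(p450_conc_from_co_difference(-0.01), "negative")
})

test_that("generated time courses return their planted TON and coupling", {
  gen <- gen_timecourse(ton_true = 4.47, p450_total = 3, window = c(0, 120),
                        times = seq(0, 360, 15), noise = 0, seed = 63)
  res <- ton_from_timecourse(gen$timecourse, 3, window_min = 120)
  expect_equal(res$ton, 4.47, tolerance = 1e-9)

  # endpoint analysis of the NADH record plus the measured conversion
  # reproduces the planted coupling ratio
  tc <- gen$timecourse
  nadh_used <- nadh_consumed_from_abs(tc$A340[1], tc$A340[nrow(tc)])
  expect_equal(nadh_used, gen$truth$nadh_consumed, tolerance = 1e-9)
  expect_equal(
    as.numeric(coupling_efficiency(gen$truth$substrate_converted, nadh_used)),
    68, tolerance = 1e-9)

  flat <- gen_timecourse(ton_true = 0, seed = 64)
  expect_equal(ton_from_timecourse(flat$timecourse, 3)$ton, 0)
})

test_that("windowed-max TON recovery respects the discretisation bound", {
  for (seed in 65:74) {
    gen <- gen_timecourse(ton_true = 3.0, p450_total = 3,
                          window = c(60, 180), times = seq(0, 360, 15),
                          noise = 1, seed = seed)
    res <- ton_from_timecourse(gen$timecourse, 3, window_min = 120)
    expect_lt(abs(res$ton - 3.0), 3.0 * (15 / 120) + 0.15)
  }
})
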