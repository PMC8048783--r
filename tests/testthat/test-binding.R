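test_that("difference signal interpolates the probe wavelengths", {
  sp <- tibble::tibble(wavelength_nm = seq(300, 500, 2),
                       absorbance = 0.25)
  expect_equal(difference_signal(sp), 0)

  sp$absorbance <- ifelse(sp$wavelength_nm == 386, 0.30,
                          ifelse(sp$wavelength_nm == 420, 0.10, 0.2))
  expect_equal(difference_signal(sp), 0.20)

  # off-grid probe against a hand two-point interpolation
  sp2 <- tibble::tibble(wavelength_nm = c(385, 387, 419, 421),
                        absorbance = c(0.10, 0.30, 0.05, 0.09))
  hand <- (0.10 + (386 - 385) / (387 - 385) * 0.20) -
    (0.05 + (420 - 419) / (421 - 419) * 0.04)
  expect_equal(difference_signal(sp2), hand)

  expect_error(difference_signal(sp2, peak_nm = 250), "outside")
})

test_that("tight-binding model honours its limits", {
  E <- 3
  expect_equal(tight_binding_model(0, E, 0.5, 0.1), 0)
  # K_D = 0: exact stoichiometric piecewise form
  L <- c(0, 0.5, 1, 2.9, 3, 3.1, 10, 150)
  expect_equal(tight_binding_model(L, E, 0, 0.1), 0.1 * pmin(L, E) / E)
  # weak-binding limit approaches the Langmuir isotherm
  KD <- 3000
  L2 <- seq(10, 150, 10)
  langmuir <- 0.1 * L2 / (L2 + KD)
  expect_equal(tight_binding_model(L2, E, KD, 0.1), langmuir,
               tolerance = 5e-3)
  # monotone non-decreasing in L, non-increasing in K_D
  g <- tight_binding_model(seq(0, 150, 1), E, 0.2, 0.1)
  expect_true(all(diff(g) >= -1e-12))
  kds <- c(0.01, 0.1, 1, 10, 100)
  at50 <- vapply(kds, function(k) tight_binding_model(50, E, k, 0.1),
                 numeric(1))
  expect_true(all(diff(at50) <= 1e-12))
  expect_error(tight_binding_model(-1, E, 1, 0.1), "domain")
})

test_that("a noiseless series recovers its K_D within 1 %", {
  gen <- gen_titration(titration_spec(kd_nM = 209, noise_sigma = 0,
                                      replicates = 1, seed = 51))
  fit <- fit_tight_binding(gen$series)
  expect_equal(fit$status, "ok")
  expect_equal(fit$kd_nM, 209, tolerance = 0.01)
  expect_equal(fit$delta_A_max, 0.1, tolerance = 0.01)
})

test_that("an all-zero series reports no shift", {
  ser <- tibble::tibble(ligand_uM = rep(c(0, 10, 50, 100, 150), each = 2),
                        deltaA = 0)
  expect_equal(fit_tight_binding(ser)$status, "no_shift")
})

test_that("K_D far below the enzyme concentration is flagged as an upper bound", {
  gen <- gen_titration(titration_spec(kd_nM = 1, noise_sigma = 0,
                                      replicates = 1, seed = 52))
  fit <- fit_tight_binding(gen$series)
  expect_equal(fit$status, "upper_bound_only")
  expect_true(is.finite(fit$kd_upper_nM))
  g <- glance(fit)
  expect_equal(g$status, "upper_bound_only")
})

test_that("fitted K_D is invariant to rescaling the signal", {
  gen <- gen_titration(titration_spec(kd_nM = 500, noise_sigma = 0.01,
                                      seed = 53))
  f1 <- fit_tight_binding(gen$series)
  ser2 <- dplyr::mutate(gen$series, deltaA = deltaA * 5)
  f2 <- fit_tight_binding(ser2)
  expect_equal(f2$kd_nM, f1$kd_nM, tolerance = 1e-3)
  expect_equal(f2$delta_A_max, 5 * f1$delta_A_max, tolerance = 1e-3)
})

test_that("parameter recovery holds across the K_D range of interest", {
  errs <- list()
  for (kd in c(50, 200, 1000, 5000)) {
    rel <- vapply(1:40, function(s) {
      gen <- gen_titration(titration_spec(kd_nM = kd, noise_sigma = 0.01,
                                          seed = 1000 + s))
      fit <- fit_tight_binding(gen$series)
      abs(fit$kd_nM - kd) / kd
    }, numeric(1))
    errs[[as.character(kd)]] <- stats::median(rel)
  }
  expect_true(all(unlist(errs) <= 0.25))
})

test_that("insufficient titration points are rejected", {
  ser <- tibble::tibble(ligand_uM = c(0, 10, 50), deltaA = c(0, 0.05, 0.09))
  expect_error(fit_tight_binding(ser), "insufficient")
})

test_that("high-spin fraction unmixing recovers planted mixtures", {
  wl <- seq(300, 500, 1)
  ls <- tibble::tibble(wavelength_nm = wl,
                       absorbance = exp(-(wl - 420)^2 / 400))
  hs <- tibble::tibble(wavelength_nm = wl,
                       absorbance = exp(-(wl - 390)^2 / 500))
  expect_equal(highspin_fraction(hs, ls, hs), 1.0, tolerance = 1e-9)

  mix <- tibble::tibble(wavelength_nm = wl,
                        absorbance = 0.5 * ls$absorbance +
                          0.5 * hs$absorbance)
  expect_equal(highspin_fraction(mix, ls, hs), 0.5, tolerance = 1e-9)

  withr::with_seed(54, {
    fr <- vapply(1:100, function(i) {
      noisy <- tibble::tibble(
        wavelength_nm = wl,
        absorbance = 0.3 * hs$absorbance + 0.7 * ls$absorbance +
          rnorm(length(wl), sd = 0.01 * max(hs$absorbance)))
      highspin_fraction(noisy, ls, hs)
    }, numeric(1))
    expect_equal(mean(fr), 0.30, tolerance = 0.03)
  })

  expect_error(highspin_fraction(mix, ls, ls), "degenerate")
})
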