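#' Type-I difference signal from an absorbance spectrum
#'
#' The titration signal of a type-I spin shift: absorbance at the high-spin
#' peak minus absorbance at the low-spin trough, each linearly interpolated
#' between the bracketing samples of the wavelength grid.  Defaults probe
#' 386 nm minus 420 nm.
#'
#' @param spectrum Data frame with columns `wavelength_nm` (strictly
#'   increasing) and `absorbance`.
#' @param peak_nm High-spin probe wavelength (default 386).
#' @param trough_nm Low-spin probe wavelength (default 420).
#' @return Difference signal in AU.
#' @export
difference_signal <- function(spectrum, peak_nm = 386, trough_nm = 420) {
  spectrum <- tibble::as_tibble(spectrum)
  if (!all(c("wavelength_nm", "absorbance") %in% names(spectrum))) {
    stop("spectrum needs columns wavelength_nm and absorbance", call. = FALSE)
  }
  wl <- spectrum$wavelength_nm
  if (any(diff(wl) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  for (p in c(peak_nm, trough_nm)) {
    if (p < min(wl) || p > max(wl)) {
      stop(sprintf("probe wavelength %g nm outside spectrum range [%g, %g]",
                   p, min(wl), max(wl)), call. = FALSE)
    }
  }
  a <- stats::approx(wl, spectrum$absorbance, xout = c(peak_nm, trough_nm))$y
  a[1] - a[2]
}

#' Quadratic tight-binding (Morrison) model
#'
#' Expected difference signal at total ligand `L` for enzyme total `E`:
#' `dA = dA_max * ((E + L + K_D) - sqrt((E + L + K_D)^2 - 4*E*L)) / (2*E)`.
#' This is the exact single-site solution without the free-ligand
#' approximation, required when `K_D` is comparable to or below the enzyme
#' concentration.
#'
#' @param L Total ligand concentration(s), uM (vectorised).
#' @param E Total enzyme concentration, uM (> 0).
#' @param K_D Dissociation constant, uM (>= 0).
#' @param delta_A_max Signal at saturation, AU.
#' @return Expected signal(s), AU, in `[0, delta_A_max]`.
#' @export
tight_binding_model <- function(L, E, K_D, delta_A_max) {
  if (any(L < 0) || E <= 0 || K_D < 0 || delta_A_max < 0) {
    stop("domain error: concentrations and K_D must be non-negative, E > 0",
         call. = FALSE)
  }
  s <- E + L + K_D
  disc <- pmax(s^2 - 4 * E * L, 0)
  delta_A_max * (s - sqrt(disc)) / (2 * E)
}

#' Fit a titration series with the tight-binding equation
#'
#' Weighted least squares over `(K_D, delta_A_max)`, both constrained
#' non-negative, on a series of total-ligand vs difference-signal points.
#' Replicate measurements at the same ligand concentration are averaged and
#' their spread feeds the weights.  Two special regimes are flagged:
#'
#' * `no_shift`: the largest signal never clears the noise floor (no
#'   spectral transition; K_D is not reported);
#' * `upper_bound_only`: the profile-likelihood lower confidence limit of
#'   K_D reaches 0, i.e. binding is too tight to resolve at this enzyme
#'   concentration.  Only the 95% profile upper limit is meaningful, as in
#'   "K_D < X nM" reporting.
#'
#' @param series Data frame with columns `ligand_uM` (including a 0 point)
#'   and `deltaA`.
#' @param enzyme_total Total enzyme concentration, uM (default 3).
#' @param noise_floor Signal magnitude below which a series counts as
#'   showing no shift, AU.  Default: 3x the standard deviation of replicate
#'   signals at `ligand_uM == 0` when replicates exist, otherwise 3e-3 AU.
#' @param conf_level Confidence level for the profile limits (default 0.95).
#' @return A `binding_fit`: `kd_nM`, `kd_se_nM`, `delta_A_max`,
#'   `delta_A_max_se`, `status` (`ok` / `upper_bound_only` / `no_shift`),
#'   `kd_upper_nM` (95% profile upper limit, reported for
#'   `upper_bound_only`), plus the averaged data and the underlying fit.
#'   Use [tidy()] / [glance()] or [autoplot.binding_fit()] on it.
#' @examples
#' gen <- gen_titration(titration_spec(kd_nM = 209, noise_sigma = 0, seed = 1))
#' fit <- fit_tight_binding(gen$series)
#' glance(fit)
#' @export
fit_tight_binding <- function(series, enzyme_total = 3, noise_floor = NULL,
                              conf_level = 0.95) {
  series <- tibble::as_tibble(series)
  if (!all(c("ligand_uM", "deltaA") %in% names(series))) {
    stop("series needs columns ligand_uM and deltaA", call. = FALSE)
  }
  if (enzyme_total <= 0) stop("enzyme_total must be > 0", call. = FALSE)

  if (is.null(noise_floor)) {
    z <- series$deltaA[series$ligand_uM == 0]
    noise_floor <- if (length(z) >= 2 && stats::sd(z) > 0) {
      3 * stats::sd(z)
    } else {
      3e-3
    }
  }

  # average replicates; spread feeds weights when available
  avg <- dplyr::summarise(dplyr::group_by(series, .data$ligand_uM),
                          deltaA = mean(.data$deltaA),
                          .sd = stats::sd(.data$deltaA),
                          .n = dplyr::n(), .groups = "drop")
  avg <- dplyr::arrange(avg, .data$ligand_uM)
  if (nrow(avg) < 4) {
    stop("insufficient data: need >= 4 distinct ligand concentrations",
         call. = FALSE)
  }
  if (all(avg$.n >= 2) && all(!is.na(avg$.sd)) && any(avg$.sd > 0)) {
    s2 <- pmax(avg$.sd^2, max(avg$.sd^2) * 1e-4)  # avoid infinite weights
    w <- (1 / s2) / mean(1 / s2)
  } else {
    w <- rep(1, nrow(avg))
  }

  mk_fit <- function(status, kd = NA_real_, kd_se = NA_real_,
                     amax = NA_real_, amax_se = NA_real_,
                     kd_upper = NA_real_, fit = NULL, rss = NA_real_) {
    structure(list(kd_nM = kd, kd_se_nM = kd_se, delta_A_max = amax,
                   delta_A_max_se = amax_se, status = status,
                   kd_upper_nM = kd_upper, enzyme_total_uM = enzyme_total,
                   noise_floor = noise_floor, conf_level = conf_level,
                   data = avg[, c("ligand_uM", "deltaA")], weights = w,
                   rss = rss, fit = fit),
              class = "binding_fit")
  }

  if (max(abs(avg$deltaA)) < noise_floor) {
    return(mk_fit("no_shift"))
  }

  L <- avg$ligand_uM
  y <- avg$deltaA
  amax0 <- max(y)
  half <- amax0 / 2
  above <- which(y >= half)
  kd0 <- if (length(above) > 0) max(L[min(above)] - enzyme_total / 2, 0.01)
         else stats::median(L[L > 0])

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ tight_binding_model(L, enzyme_total, KD, Amax),
      # keep K_D off the exact zero boundary: the model gradient is singular
      # there (the discriminant kinks at L = E); 1e-6 uM is 0.001 nM
      start = list(KD = max(kd0, 1e-5), Amax = amax0),
      lower = c(1e-6, 0), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("fit failure: ", conditionMessage(e), call. = FALSE)
    }
  )
  cf <- summary(fit)$coefficients
  kd_uM <- cf["KD", "Estimate"]
  rss_min <- sum(w * stats::residuals(fit)^2)

  # profile RSS over K_D (delta_A_max solved analytically at each K_D);
  # residual-variance floor keeps the F-test meaningful on noiseless series
  n <- length(y)
  prof_rss <- function(kd) {
    m <- tight_binding_model(L, enzyme_total, kd, 1)
    a <- sum(w * y * m) / sum(w * m^2)
    sum(w * (y - max(a, 0) * m)^2)
  }
  sigma2 <- max(rss_min / (n - 2), 1e-8)
  thresh <- rss_min + sigma2 * stats::qf(conf_level, 1, n - 2)

  status <- "ok"
  kd_upper <- NA_real_
  if (prof_rss(0) <= thresh) {
    status <- "upper_bound_only"
    # smallest K_D whose profile RSS exceeds the threshold = upper limit
    hi <- max(kd_uM * 4, enzyme_total, 1)
    while (prof_rss(hi) <= thresh && hi < 1e6) hi <- hi * 4
    kd_upper <- if (prof_rss(hi) > thresh) {
      1000 * stats::uniroot(function(k) prof_rss(k) - thresh,
                            lower = 0, upper = hi)$root
    } else {
      NA_real_
    }
  }

  mk_fit(status,
         kd = 1000 * kd_uM,
         kd_se = 1000 * cf["KD", "Std. Error"],
         amax = cf["Amax", "Estimate"],
         amax_se = cf["Amax", "Std. Error"],
         kd_upper = kd_upper, fit = fit, rss = rss_min)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit> status:", x$status, "\n")
  if (x$status == "ok") {
    cat(sprintf("  K_D = %.1f +/- %.1f nM, dA_max = %.4g AU\n",
                x$kd_nM, x$kd_se_nM, x$delta_A_max))
  } else if (x$status == "upper_bound_only") {
    cat(sprintf("  K_D < %.2f nM (%.0f%% profile upper limit)\n",
                x$kd_upper_nM, 100 * x$conf_level))
  } else {
    cat("  no spectral shift above the noise floor\n")
  }
  invisible(x)
}

#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd_nM", "delta_A_max"),
    estimate = c(x$kd_nM, x$delta_A_max),
    std.error = c(x$kd_se_nM, x$delta_A_max_se)
  )
}

#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(kd_nM = x$kd_nM, kd_se_nM = x$kd_se_nM,
                 delta_A_max = x$delta_A_max, status = x$status,
                 kd_upper_nM = x$kd_upper_nM,
                 enzyme_total_uM = x$enzyme_total_uM,
                 rss = x$rss, n = nrow(x$data))
}

#' High-spin fraction by linear unmixing
#'
#' Decomposes a spectrum as a non-negative combination of a low-spin and a
#' high-spin basis spectrum (interpolated onto the sample grid) and returns
#' the high-spin coefficient fraction `a_HS / (a_LS + a_HS)`.
#'
#' @param sample,low_spin_basis,high_spin_basis Data frames with columns
#'   `wavelength_nm` and `absorbance`; bases must cover the sample grid.
#' @return High-spin fraction in `[0, 1]`.
#' @export
highspin_fraction <- function(sample, low_spin_basis, high_spin_basis) {
  sample <- tibble::as_tibble(sample)
  wl <- sample$wavelength_nm
  y <- sample$absorbance
  interp <- function(b) {
    b <- tibble::as_tibble(b)
    if (min(b$wavelength_nm) > min(wl) || max(b$wavelength_nm) < max(wl)) {
      stop("basis spectrum does not cover the sample grid", call. = FALSE)
    }
    stats::approx(b$wavelength_nm, b$absorbance, xout = wl)$y
  }
  B <- cbind(ls = interp(low_spin_basis), hs = interp(high_spin_basis))
  if (kappa(crossprod(B)) > 1e12) {
    stop("degenerate basis: spectra are linearly dependent on this grid",
         call. = FALSE)
  }
  # 2-variable non-negative least squares: unconstrained solve, then the
  # better of the two boundary solutions if a coefficient goes negative
  a <- solve(crossprod(B), crossprod(B, y))
  if (any(a < 0)) {
    a1 <- c(max(sum(B[, 1] * y) / sum(B[, 1]^2), 0), 0)
    a2 <- c(0, max(sum(B[, 2] * y) / sum(B[, 2]^2), 0))
    rss <- function(ab) sum((y - B %*% ab)^2)
    a <- if (rss(a1) <= rss(a2)) a1 else a2
  }
  tot <- sum(a)
  if (tot <= 0) {
    stop("degenerate basis: sample has no projection on the bases",
         call. = FALSE)
  }
  as.numeric(a[2] / tot)
}
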