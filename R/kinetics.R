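#' Turnover number from a substrate time course
#'
#' The turnover number (TON, umol substrate consumed per umol P450 per
#' minute) is evaluated over the contiguous window of highest substrate
#' consumption rate: every window of samples spanning at least `window_min`
#' minutes gets a least-squares line through (time, substrate), and the
#' steepest negative slope wins.  A best slope that is still non-negative
#' clamps the TON to 0 with a `no_consumption` flag.
#'
#' @param tc Data frame with columns `time_min` (strictly increasing) and
#'   `substrate_uM`; at least 3 rows.
#' @param p450_total Total P450 concentration, uM (> 0).
#' @param window_min Minimum window span in minutes (default 120,
#'   consumption is typically fastest within the first 2-3 h); must cover
#'   at least 2 samples.
#' @return A `kinetics_result`: `ton`, `window` (start/end, min), `slope`
#'   (uM/min), `no_consumption` flag.  Use [glance()] for a one-row tibble.
#' @examples
#' tc <- tibble::tibble(time_min = seq(0, 300, 30),
#'                      substrate_uM = 2000 - 6 * seq(0, 300, 30))
#' glance(ton_from_timecourse(tc, p450_total = 3))
#' @export
ton_from_timecourse <- function(tc, p450_total, window_min = 120) {
  tc <- tibble::as_tibble(tc)
  if (!all(c("time_min", "substrate_uM") %in% names(tc))) {
    stop("time course needs columns time_min and substrate_uM", call. = FALSE)
  }
  if (nrow(tc) < 3) {
    stop("insufficient data: need >= 3 time points", call. = FALSE)
  }
  if (p450_total <= 0) stop("p450_total must be > 0", call. = FALSE)
  if (any(diff(tc$time_min) <= 0)) {
    stop("time_min must be strictly increasing", call. = FALSE)
  }
  t <- tc$time_min
  s <- tc$substrate_uM
  n <- length(t)
  best <- list(slope = Inf, i = NA, j = NA)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (t[j] - t[i] < window_min) next
      tt <- t[i:j]; ss <- s[i:j]
      sl <- sum((tt - mean(tt)) * (ss - mean(ss))) / sum((tt - mean(tt))^2)
      if (sl < best$slope) best <- list(slope = sl, i = i, j = j)
    }
  }
  if (!is.finite(best$slope)) {
    stop("insufficient data: no window spans ", window_min, " min",
         call. = FALSE)
  }
  no_cons <- best$slope >= 0
  structure(list(
    ton = max(0, -best$slope) / p450_total,
    window = c(t_start = t[best$i], t_end = t[best$j]),
    slope = best$slope,
    p450_total = p450_total,
    window_min = window_min,
    no_consumption = no_cons
  ), class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("<kinetics_result> TON = %.3f /min over (%g, %g) min%s\n",
              x$ton, x$window[1], x$window[2],
              if (x$no_consumption) " [no consumption]" else ""))
  invisible(x)
}

#' @method glance kinetics_result
#' @export
glance.kinetics_result <- function(x, ...) {
  tibble::tibble(ton = x$ton, t_start = x$window[[1]],
                 t_end = x$window[[2]], slope_uM_per_min = x$slope,
                 p450_total_uM = x$p450_total,
                 no_consumption = x$no_consumption)
}

#' Coupling efficiency
#'
#' Percentage of consumed NADH reducing equivalents ending up in converted
#' substrate: `100 * substrate_converted / nadh_consumed`.  Values above
#' 100% are allowed but flagged as stoichiometrically implausible (attribute
#' `implausible`).
#'
#' @param substrate_converted Substrate converted, uM (>= 0).
#' @param nadh_consumed NADH consumed, uM (> 0).
#' @return Coupling efficiency in percent (vectorised).
#' @export
coupling_efficiency <- function(substrate_converted, nadh_consumed) {
  if (any(nadh_consumed <= 0)) {
    stop("domain error: nadh_consumed must be > 0", call. = FALSE)
  }
  if (any(substrate_converted < 0)) {
    stop("domain error: substrate_converted must be >= 0", call. = FALSE)
  }
  out <- 100 * substrate_converted / nadh_consumed
  attr(out, "implausible") <- out > 100
  out
}

#' NADH consumed from the 340 nm absorbance drop
#'
#' Beer-Lambert conversion with the NADH extinction coefficient at 340 nm,
#' 6.22 mM^-1 cm^-1.
#'
#' @param a0 Absorbance at 340 nm before, AU.
#' @param a1 Absorbance at 340 nm after, AU.
#' @param path_cm Optical path length, cm (default 1).
#' @param epsilon_mM Extinction coefficient, mM^-1 cm^-1 (default 6.22).
#' @return NADH consumed, uM.  `a1 > a0` yields a negative value with a
#'   warning (flagged apparent negative consumption).
#' @export
nadh_consumed_from_abs <- function(a0, a1, path_cm = 1, epsilon_mM = 6.22) {
  if (path_cm <= 0 || epsilon_mM <= 0) {
    stop("domain error: path and epsilon must be > 0", call. = FALSE)
  }
  out <- (a0 - a1) / (epsilon_mM * 1e-3 * path_cm)
  if (any(out < 0)) {
    warning("negative NADH consumption (a1 > a0) flagged", call. = FALSE)
  }
  out
}

#' Electron-transfer-chain activity from a cytochrome c reduction slope
#'
#' Converts the rate of absorbance increase at 550 nm of reduced cytochrome
#' c (epsilon 19.1 mM^-1 cm^-1) into volumetric activity of the sample,
#' U/mL = umol min^-1 per mL of sample, scaling by the reaction-to-sample
#' volume ratio.
#'
#' @param slope_A550_per_min Absorbance slope, AU/min (>= 0).
#' @param reaction_volume_mL Assay mixture volume, mL.
#' @param sample_volume_mL Volume of sample added to the mixture, mL.
#' @param epsilon_mM Extinction coefficient, mM^-1 cm^-1 (default 19.1).
#' @param path_cm Optical path, cm (default 1).
#' @return Activity, U/mL of sample.
#' @export
etc_activity <- function(slope_A550_per_min, reaction_volume_mL,
                         sample_volume_mL, epsilon_mM = 19.1, path_cm = 1) {
  if (any(slope_A550_per_min < 0)) {
    stop("domain error: slope must be >= 0", call. = FALSE)
  }
  if (reaction_volume_mL <= 0 || sample_volume_mL <= 0) {
    stop("domain error: volumes must be > 0", call. = FALSE)
  }
  rate_mM_per_min <- slope_A550_per_min / (epsilon_mM * path_cm)
  rate_mM_per_min * reaction_volume_mL / sample_volume_mL
}

#' P450 concentration from a CO-difference spectrum
#'
#' Beer-Lambert conversion of the 450-490 nm difference absorbance of the
#' reduced CO complex.  The default extinction coefficient 91 mM^-1 cm^-1 is
#' the classic Omura-Sato literature value; it is configurable.
#'
#' @param delta_A_450_490 Difference absorbance, AU.
#' @param path_cm Optical path, cm (default 1).
#' @param epsilon_mM Extinction coefficient, mM^-1 cm^-1 (default 91).
#' @return P450 concentration, uM.  Negative deltas are returned with a
#'   warning.
#' @export
p450_conc_from_co_difference <- function(delta_A_450_490, path_cm = 1,
                                         epsilon_mM = 91) {
  if (path_cm <= 0 || epsilon_mM <= 0) {
    stop("domain error: path and epsilon must be > 0", call. = FALSE)
  }
  if (any(delta_A_450_490 < 0)) {
    warning("negative CO-difference absorbance flagged", call. = FALSE)
  }
  delta_A_450_490 / (epsilon_mM * 1e-3 * path_cm)
}
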