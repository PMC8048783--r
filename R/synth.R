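#' Specification for a synthetic reactive trajectory
#'
#' Describes a trajectory with planted near-attack conformations: for each
#' site, the requested fraction of frames carries one equivalent hydrogen
#' strictly inside the NAC criterion (by at least `margin`), while all other
#' hydrogens -- and all hydrogens in the remaining frames -- violate both
#' the distance and angle conditions by at least `margin`.  The margin band
#' makes planted labels robust to floating-point noise.  Waters are parked
#' at `water_park` Angstrom from the ferryl oxygen except during scheduled
#' approaches.
#'
#' @param n_frames Number of frames (>= 1).
#' @param sites List of site requests, each `list(label, n_H, fraction)`:
#'   label string, number of equivalent hydrogens, target NAC fraction in
#'   `[0, 1]`.
#' @param jitter_sigma Isotropic positional jitter applied to the parked
#'   scaffold atoms, Angstrom (default 0.05).
#' @param water_schedule List of approaches, each
#'   `list(water = k, frames = c(from, to), distance = d)`; waters outside
#'   their schedule sit at `water_park`.
#' @param n_waters Number of water molecules (default: enough for the
#'   schedule, at least 1).
#' @param water_park Parked water O...ferryl O distance, Angstrom
#'   (default 7).
#' @param d_max,theta_ref,theta_tol NAC criterion the plant is built
#'   against (defaults as in [nac_criterion()]).
#' @param margin Relative keep-away band around the thresholds, in (0, 1)
#'   (default 0.1).
#' @param seed Integer seed; identical specs generate identical output.
#' @return A `reactive_trajectory_spec`.
#' @export
reactive_trajectory_spec <- function(n_frames, sites, jitter_sigma = 0.05,
                                     water_schedule = list(),
                                     n_waters = NULL, water_park = 7,
                                     d_max = 2.72, theta_ref = 180,
                                     theta_tol = 20, margin = 0.1,
                                     seed = 1) {
  if (n_frames < 1) stop("spec error: n_frames must be >= 1", call. = FALSE)
  if (margin <= 0 || margin >= 1) {
    stop("spec error: margin must be in (0, 1)", call. = FALSE)
  }
  sites <- lapply(sites, function(s) {
    s <- unname(s)
    out <- list(label = as.character(s[[1]]), n_H = as.integer(s[[2]]),
                fraction = as.numeric(s[[3]]))
    if (out$n_H < 1) stop("spec error: n_H must be >= 1", call. = FALSE)
    if (out$fraction < 0 || out$fraction > 1) {
      stop("spec error: fraction must be in [0, 1]", call. = FALSE)
    }
    out
  })
  if (d_max * (1 - margin) <= 1.8) {
    stop("spec error: margin leaves no room inside d_max above 1.8 A",
         call. = FALSE)
  }
  if (is.null(n_waters)) {
    n_waters <- max(1, vapply(water_schedule,
                              function(w) as.numeric(w$water), numeric(1)))
  }
  structure(list(n_frames = as.integer(n_frames), sites = sites,
                 jitter_sigma = jitter_sigma,
                 water_schedule = water_schedule,
                 n_waters = as.integer(n_waters), water_park = water_park,
                 d_max = d_max, theta_ref = theta_ref,
                 theta_tol = theta_tol, margin = margin,
                 seed = as.integer(seed)),
            class = "reactive_trajectory_spec")
}

# random unit row-vectors, n x 3
runit <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# unit vectors perpendicular to the rows of u
rperp <- function(u) {
  v <- runit(nrow(u))
  p <- v - rowSums(v * u) * u
  n <- sqrt(rowSums(p^2))
  bad <- n < 1e-8
  while (any(bad)) {
    v2 <- runit(sum(bad))
    p[bad, ] <- v2 - rowSums(v2 * u[bad, , drop = FALSE]) * u[bad, , drop = FALSE]
    n[bad] <- sqrt(rowSums(p[bad, , drop = FALSE]^2))
    bad <- n < 1e-8
  }
  p / n
}

# place hydrogens on a 1.09 A sphere around their carbon so that BOTH the
# distance and the angle criterion are violated by at least the margin;
# C, acc: n x 3. Rejection sampling (the margin bands leave most of the
# sphere available).
reject_place_h <- function(C, acc, d_max, theta_ref, theta_tol, margin,
                           max_tries = 500) {
  n <- nrow(C)
  H <- matrix(NA_real_, n, 3)
  todo <- rep(TRUE, n)
  b <- 1.09
  for (try in seq_len(max_tries)) {
    m <- sum(todo)
    if (m == 0) break
    cand <- C[todo, , drop = FALSE] + b * runit(m)
    u <- acc[todo, , drop = FALSE] - cand          # H -> O
    du <- sqrt(rowSums(u^2))
    v <- C[todo, , drop = FALSE] - cand            # H -> C
    cosang <- rowSums(u * v) / (du * b)
    cosang <- pmin(1, pmax(-1, cosang))
    th <- acos(cosang) * 180 / pi
    ok <- du >= d_max * (1 + margin) &
      abs(th - theta_ref) >= theta_tol * (1 + margin)
    idx <- which(todo)[ok]
    H[idx, ] <- cand[ok, , drop = FALSE]
    todo[idx] <- FALSE
  }
  if (any(todo)) {
    stop("spec error: infeasible geometry request (rejection sampling failed)",
         call. = FALSE)
  }
  H
}

#' Generate a trajectory with planted near-attack conformations
#'
#' Builds a deterministic (seeded) trajectory around a ferryl oxygen at the
#' origin.  For each site, an exact count `round(fraction * n_frames)` of
#' frames is sampled without replacement and planted as NAC: one equivalent
#' hydrogen is placed with `d` uniform in `[1.8, d_max*(1-margin)]` and
#' C-H...O angle within `theta_tol*(1-margin)` of `theta_ref`; every other
#' hydrogen (and every hydrogen of unplanted frames) violates both criteria
#' by at least the margin.  Waters follow the schedule, parked at the park
#' distance otherwise, each with two hydrogens (one pointing at the
#' acceptor, so a close approach also hydrogen-bonds).
#'
#' @param spec A [reactive_trajectory_spec()].
#' @return List with `trajectory` ([trajectory()]), `labels` (tibble
#'   `frame`, `site`, `nac` -- the planted ground truth), `criterion` (the
#'   matching [nac_criterion()]) and `water_oxygens` (roster indices).
#' @export
gen_reactive_trajectory <- function(spec) {
  stopifnot(inherits(spec, "reactive_trajectory_spec"))
  withr::with_seed(spec$seed, {
    nf <- spec$n_frames
    ns <- length(spec$sites)

    # roster: ferryl O, then per site C + hydrogens, then waters (O,H1,H2)
    ros <- list(tibble::tibble(serial = 1L, name = "OFE", element = "O",
                               resname = "CPI", resnum = 500L, chain = "X"))
    serial <- 1L
    site_rows <- list()
    for (k in seq_len(ns)) {
      s <- spec$sites[[k]]
      rows <- list(carbon = serial + 1L,
                   hydrogens = serial + 1L + seq_len(s$n_H))
      ros[[length(ros) + 1]] <- tibble::tibble(
        serial = serial + c(1L, 1L + seq_len(s$n_H)),
        name = c(paste0("C", s$label), paste0("H", s$label, seq_len(s$n_H))),
        element = c("C", rep("H", s$n_H)),
        resname = "STR", resnum = 400L, chain = "X")
      serial <- serial + 1L + s$n_H
      site_rows[[k]] <- rows
    }
    water_rows <- integer(spec$n_waters)
    for (k in seq_len(spec$n_waters)) {
      ros[[length(ros) + 1]] <- tibble::tibble(
        serial = serial + 1:3,
        name = c("O", "H1", "H2"), element = c("O", "H", "H"),
        resname = "HOH", resnum = 600L + k, chain = "W")
      water_rows[k] <- serial + 1L
      serial <- serial + 3L
    }
    roster <- dplyr::bind_rows(ros)
    na_ <- nrow(roster)
    coords <- array(0, c(na_, 3, nf))

    labels <- list()
    acc <- matrix(0, nf, 3)            # ferryl O at the origin, all frames

    for (k in seq_len(ns)) {
      s <- spec$sites[[k]]
      rows <- site_rows[[k]]
      n_nac <- round(s$fraction * nf)
      nac_frames <- sort(sample.int(nf, n_nac))
      is_nac <- rep(FALSE, nf)
      is_nac[nac_frames] <- TRUE

      C <- matrix(NA_real_, nf, 3)
      H <- array(NA_real_, c(nf, 3, s$n_H))

      if (n_nac > 0) {
        d <- stats::runif(n_nac, 1.8, spec$d_max * (1 - spec$margin))
        u <- runit(n_nac)
        h1 <- d * u
        off <- stats::runif(n_nac, 0, spec$theta_tol * (1 - spec$margin)) *
          sample(c(-1, 1), n_nac, replace = TRUE)
        th <- spec$theta_ref + off
        th[th > 180] <- spec$theta_ref - abs(off[th > 180])
        th[th <= 0] <- spec$theta_ref + abs(off[th <= 0])
        thr <- th * pi / 180
        p <- rperp(u)
        # vertex at H: arm to O is -u; carbon set to realise the angle
        C[nac_frames, ] <- h1 + 1.09 * (cos(thr) * (-u) + sin(thr) * p)
        H[nac_frames, , 1] <- h1
        if (s$n_H > 1) {
          for (j in 2:s$n_H) {
            H[nac_frames, , j] <- reject_place_h(
              C[nac_frames, , drop = FALSE], acc[nac_frames, , drop = FALSE],
              spec$d_max, spec$theta_ref, spec$theta_tol, spec$margin)
          }
        }
      }
      rest <- which(!is_nac)
      if (length(rest) > 0) {
        dc <- stats::runif(length(rest), 4, 6)
        C[rest, ] <- dc * runit(length(rest))
        for (j in seq_len(s$n_H)) {
          H[rest, , j] <- reject_place_h(
            C[rest, , drop = FALSE], acc[rest, , drop = FALSE],
            spec$d_max, spec$theta_ref, spec$theta_tol, spec$margin)
        }
      }
      coords[rows$carbon, , ] <- t(C)
      for (j in seq_len(s$n_H)) {
        coords[rows$hydrogens[j], , ] <- t(H[, , j])
      }
      labels[[k]] <- tibble::tibble(frame = seq_len(nf), site = s$label,
                                    nac = is_nac)
    }

    # waters: fixed random direction per water; distance per schedule
    for (k in seq_len(spec$n_waters)) {
      dirw <- runit(1)
      dk <- rep(spec$water_park, nf)
      for (w in spec$water_schedule) {
        if (w$water == k) {
          rng <- seq(w$frames[1], w$frames[2])
          dk[rng] <- w$distance
        }
      }
      ow <- outer(dk, as.numeric(dirw))                 # nf x 3
      h1 <- ow - 0.96 * matrix(dirw, nf, 3, byrow = TRUE)  # toward acceptor
      perp <- as.numeric(rperp(dirw))
      h2 <- ow + 0.96 * matrix(perp, nf, 3, byrow = TRUE)
      coords[water_rows[k], , ] <- t(ow)
      coords[water_rows[k] + 1L, , ] <- t(h1)
      coords[water_rows[k] + 2L, , ] <- t(h2)
    }

    # park-position jitter would break the margin guarantees for site atoms,
    # so it only shakes the water hydrogens' off-axis partner
    if (spec$jitter_sigma > 0 && spec$n_waters > 0) {
      for (k in seq_len(spec$n_waters)) {
        j <- water_rows[k] + 2L
        coords[j, , ] <- coords[j, , ] +
          matrix(stats::rnorm(3 * nf, sd = spec$jitter_sigma), 3, nf)
      }
    }

    traj <- trajectory(roster, coords, times = seq_len(nf) * 50)
    sites <- lapply(seq_len(ns), function(k) {
      site_definition(spec$sites[[k]]$label,
                      hydrogens = site_rows[[k]]$hydrogens,
                      carbon = site_rows[[k]]$carbon)
    })
    crit <- nac_criterion(acceptor = 1L, sites = sites, d_max = spec$d_max,
                          theta_ref = spec$theta_ref,
                          theta_tol = spec$theta_tol)
    list(trajectory = traj, labels = dplyr::bind_rows(labels),
         criterion = crit, water_oxygens = water_rows)
  })
}

#' Specification for a synthetic titration series
#'
#' Defaults emulate the binding-study design: 3 uM enzyme, 12 ligand
#' concentrations from 0 to 150 uM, duplicate measurements, 1% multiplicative
#' noise.
#'
#' @param kd_nM True dissociation constant, nM.
#' @param delta_A_max True saturation signal, AU (default 0.1).
#' @param enzyme_total Enzyme concentration, uM (default 3).
#' @param ligand_uM Ligand grid, uM, must include 0 (default 12 points,
#'   0 to 150).
#' @param noise_sigma Relative (multiplicative) noise sd (default 0.01).
#' @param replicates Replicates per concentration (default 2).
#' @param seed Integer seed.
#' @return A `titration_spec`.
#' @export
titration_spec <- function(kd_nM, delta_A_max = 0.1, enzyme_total = 3,
                           ligand_uM = c(0, 1, 2, 5, 10, 20, 30, 50, 75,
                                         100, 125, 150),
                           noise_sigma = 0.01, replicates = 2, seed = 1) {
  if (!0 %in% ligand_uM) stop("spec error: grid must include 0", call. = FALSE)
  if (noise_sigma < 0) stop("spec error: noise must be >= 0", call. = FALSE)
  structure(list(kd_nM = kd_nM, delta_A_max = delta_A_max,
                 enzyme_total = enzyme_total, ligand_uM = ligand_uM,
                 noise_sigma = noise_sigma,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "titration_spec")
}

#' Generate a synthetic titration series
#'
#' `deltaA = tight_binding_model(L, E, K_D, dA_max) * (1 + eps)` with
#' `eps ~ N(0, noise_sigma)`, seeded.
#'
#' @param spec A [titration_spec()].
#' @return List with `series` (tibble `ligand_uM`, `replicate`, `deltaA`)
#'   and `truth` (the spec parameters).
#' @export
gen_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  withr::with_seed(spec$seed, {
    L <- rep(spec$ligand_uM, each = spec$replicates)
    mu <- tight_binding_model(L, spec$enzyme_total, spec$kd_nM / 1000,
                              spec$delta_A_max)
    eps <- stats::rnorm(length(L), sd = spec$noise_sigma)
    tibble::tibble(
      ligand_uM = L,
      replicate = rep(seq_len(spec$replicates), times = length(spec$ligand_uM)),
      deltaA = mu * (1 + eps)
    ) -> series
    list(series = series,
         truth = list(kd_nM = spec$kd_nM, delta_A_max = spec$delta_A_max,
                      enzyme_total = spec$enzyme_total))
  })
}

#' Generate a synthetic substrate/NADH time course
#'
#' Substrate is flat outside the planted window and decays at
#' `-ton_true * p450_total` uM/min inside it.  The NADH record emulates the
#' separate coupling assay: the cofactor pool `nadh0` is completely consumed
#' over the window (tracked as 340 nm absorbance), and the truth list carries
#' the endpoint conversion consistent with the planted coupling ratio,
#' `substrate_converted = coupling_true/100 * nadh0` -- the quantity an
#' endpoint chromatographic analysis would measure.
#'
#' @param ton_true Planted maximal turnover number, per minute.
#' @param p450_total P450 concentration, uM (default 3).
#' @param s0 Initial substrate, uM (default 2000, i.e. 2 mM).
#' @param window Planted steep-phase window `c(t_a, t_b)`, minutes
#'   (default `c(60, 180)`).
#' @param times Sampling times, minutes (default 0-360 by 15).
#' @param nadh0 Initial NADH, uM (default 200).
#' @param coupling_true Planted coupling efficiency, percent (default 68).
#' @param noise Additive noise sd on the substrate trace, uM (default 0).
#' @param seed Integer seed.
#' @return List with `timecourse` (tibble `time_min`, `substrate_uM`,
#'   `nadh_uM`, `A340`) and `truth`.
#' @export
gen_timecourse <- function(ton_true, p450_total = 3, s0 = 2000,
                           window = c(60, 180),
                           times = seq(0, 360, by = 15), nadh0 = 200,
                           coupling_true = 68, noise = 0, seed = 1) {
  if (ton_true < 0 || p450_total <= 0 || nadh0 <= 0) {
    stop("spec error: rates and concentrations must be non-negative",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    rate <- ton_true * p450_total
    drop <- pmin(pmax(times - window[1], 0), window[2] - window[1]) * rate
    substrate <- s0 - drop
    if (any(substrate < 0)) {
      stop("spec error: substrate would go negative; raise s0", call. = FALSE)
    }
    total_drop <- rate * (window[2] - window[1])
    nadh_used <- nadh0                  # coupling assay runs to completion
    frac <- pmin(pmax(times - window[1], 0), window[2] - window[1]) /
      (window[2] - window[1])
    nadh <- nadh0 - nadh_used * frac
    if (noise > 0) {
      substrate <- substrate + stats::rnorm(length(times), sd = noise)
    }
    substrate_converted <- nadh_used * coupling_true / 100
    list(
      timecourse = tibble::tibble(time_min = times, substrate_uM = substrate,
                                  nadh_uM = nadh, A340 = nadh * 6.22e-3),
      truth = list(ton = ton_true, window = window,
                   coupling = coupling_true, nadh_consumed = nadh_used,
                   substrate_converted = substrate_converted,
                   p450_total = p450_total)
    )
  })
}

#' Generate a pair of synthetic complex structures
#'
#' Builds a random CA scaffold (3.8 Angstrom consecutive steps), then a
#' partner whose coordinates are perturbed so the minimized C-alpha RMSD
#' equals `rmsd_target` within a small calibration tolerance, plus a random
#' rigid motion.  A ligand atom is placed in each structure such that, after
#' superposing the partner onto the reference, the named pair sits at the
#' requested offset.
#'
#' @param rmsd_target Target minimized CA RMSD, Angstrom (>= 0).
#' @param n_residues Number of CA atoms (default 100).
#' @param ligand_offset Post-alignment distance between the two ligand
#'   atoms, Angstrom (default 0.8).
#' @param ligand_names Atom names of the ligand atoms in the reference and
#'   partner (default `c("C15", "C16")`).
#' @param seed Integer seed.
#' @return List with `a`, `b` (`complex_structure`s) and `truth`.
#' @export
gen_complex_pair <- function(rmsd_target, n_residues = 100,
                             ligand_offset = 0.8,
                             ligand_names = c("C15", "C16"), seed = 1) {
  if (rmsd_target < 0) stop("spec error: rmsd_target >= 0", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    steps <- 3.8 * runit(n_residues)
    ca <- apply(steps, 2, cumsum)
    lig_a <- colMeans(ca)

    if (rmsd_target > 0) {
      pert <- matrix(stats::rnorm(3 * n_residues), n_residues, 3)
      cb <- ca + pert * rmsd_target / sqrt(mean(rowSums(pert^2)))
      for (it in 1:6) {                       # calibrate to the minimized RMSD
        cur <- kabsch(cb, ca)$rmsd
        cb <- ca + (cb - ca) * (rmsd_target / cur)
      }
    } else {
      cb <- ca
    }
    v <- runit(1)
    lig_b_pre <- lig_a + ligand_offset * as.numeric(v)

    # random proper rotation + translation applied to the partner
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- quat_to_rot(q)
    tr <- stats::rnorm(3, sd = 10)
    cb_m <- cb %*% R + matrix(tr, n_residues, 3, byrow = TRUE)
    lig_b <- as.numeric(lig_b_pre %*% R + tr)

    mk <- function(ca_xyz, lig_xyz, lig_name, id) {
      atoms <- tibble::tibble(
        serial = seq_len(n_residues + 1L),
        name = c(rep("CA", n_residues), lig_name),
        element = c(rep("C", n_residues), "C"),
        resname = c(rep("ALA", n_residues), "STR"),
        resnum = c(seq_len(n_residues), 900L),
        chain = "A",
        x = c(ca_xyz[, 1], lig_xyz[1]),
        y = c(ca_xyz[, 2], lig_xyz[2]),
        z = c(ca_xyz[, 3], lig_xyz[3])
      )
      complex_structure(atoms, id, ligand_resnames = "STR")
    }
    list(a = mk(ca, lig_a, ligand_names[1], "SYNTH_A"),
         b = mk(cb_m, lig_b, ligand_names[2], "SYNTH_B"),
         truth = list(rmsd = rmsd_target, ligand_offset = ligand_offset))
  })
}

# rotation matrix from a unit quaternion (row-vector convention)
quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
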