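#' Define an abstractable-hydrogen site
#'
#' A site is a set of chemically equivalent substrate hydrogens (e.g. the
#' three C21 methyl hydrogens) plus their common bonded carbon.  A frame
#' scores as a near-attack conformation (NAC) for the site if ANY equivalent
#' hydrogen meets the geometric criterion.
#'
#' @param label Site label, e.g. `"16a"` or `"21"`; unique within a
#'   criterion.
#' @param hydrogens Roster indices of the equivalent hydrogens (>= 1).
#' @param carbon Roster index of the bonded carbon.
#' @return A `site_definition`.
#' @export
site_definition <- function(label, hydrogens, carbon) {
  hydrogens <- as.integer(hydrogens)
  carbon <- as.integer(carbon)
  if (length(hydrogens) < 1) stop("a site needs >= 1 hydrogen", call. = FALSE)
  if (carbon %in% hydrogens) {
    stop("site carbon must be distinct from its hydrogens", call. = FALSE)
  }
  structure(list(label = as.character(label), hydrogens = hydrogens,
                 carbon = carbon), class = "site_definition")
}

#' Near-attack-conformation criterion
#'
#' A hydrogen is in a NAC when its distance to the compound I ferryl oxygen
#' is below the van der Waals contact distance and the C-H...O angle (the
#' three reacting atoms) lies within a tolerance of the transition-state
#' reference angle.
#'
#' @param acceptor Roster index of the ferryl (compound I) oxygen.
#' @param sites List of [site_definition()]s with unique labels.
#' @param d_max H...O contact distance threshold in Angstrom.  Default 2.72
#'   = Bondi vdW radii r(O) 1.52 + r(H) 1.20.
#' @param theta_ref Reference C-H...O angle in degrees; default 180
#'   (near-linear hydrogen abstraction).
#' @param theta_tol Angle tolerance in degrees; default 20.
#' @return A `nac_criterion`.
#' @export
nac_criterion <- function(acceptor, sites, d_max = 2.72, theta_ref = 180,
                          theta_tol = 20) {
  if (inherits(sites, "site_definition")) sites <- list(sites)
  if (length(sites) == 0) {
    stop("configuration error: criterion needs >= 1 site", call. = FALSE)
  }
  labs <- vapply(sites, function(s) s$label, character(1))
  if (anyDuplicated(labs)) {
    stop("configuration error: duplicate site labels", call. = FALSE)
  }
  if (d_max <= 0) stop("d_max must be > 0", call. = FALSE)
  if (theta_ref <= 0 || theta_ref > 180) {
    stop("theta_ref must be in (0, 180]", call. = FALSE)
  }
  if (theta_tol <= 0) stop("theta_tol must be > 0", call. = FALSE)
  acceptor <- as.integer(acceptor)
  for (s in sites) {
    if (acceptor %in% s$hydrogens || acceptor == s$carbon) {
      stop("configuration error: acceptor oxygen coincides with site atoms",
           call. = FALSE)
    }
  }
  structure(list(acceptor = acceptor, sites = sites, d_max = d_max,
                 theta_ref = theta_ref, theta_tol = theta_tol),
            class = "nac_criterion")
}

# distances (n_h x n_frames) and C-H...O angles for one site, vectorised
site_geometry <- function(traj, site, acceptor) {
  nf <- n_frames(traj)
  nh <- length(site$hydrogens)
  acc <- traj$coords[acceptor, , , drop = FALSE]
  dim(acc) <- c(3, nf)
  cc <- traj$coords[site$carbon, , , drop = FALSE]
  dim(cc) <- c(3, nf)
  D <- matrix(NA_real_, nh, nf)
  TH <- matrix(NA_real_, nh, nf)
  for (k in seq_len(nh)) {
    h <- traj$coords[site$hydrogens[k], , , drop = FALSE]
    dim(h) <- c(3, nf)
    u <- acc - h                      # H -> O
    v <- cc - h                       # H -> C
    du <- sqrt(colSums(u^2))
    dv <- sqrt(colSums(v^2))
    D[k, ] <- du
    cosang <- colSums(u * v) / (du * dv)
    cosang[cosang > 1] <- 1
    cosang[cosang < -1] <- -1
    TH[k, ] <- acos(cosang) * 180 / pi
  }
  list(D = D, TH = TH)
}

#' Frame-by-frame NAC classification
#'
#' Classifies every frame against every site of a criterion.  A site is NAC
#' in a frame iff any of its equivalent hydrogens has `d(H...O) < d_max` and
#' `|theta(C-H...O) - theta_ref| <= theta_tol`.  The reported geometry is
#' that of the hydrogen with the smallest distance (ties broken by lowest
#' roster index).
#'
#' @param x A [trajectory()].
#' @param criterion A [nac_criterion()].
#' @return Tibble with one row per frame per site: `frame`, `site`, `nac`,
#'   `hydrogen` (roster index of the closest hydrogen), `distance`
#'   (Angstrom), `angle` (degrees) and `time_ps` when available.
#' @export
classify_frames <- function(x, criterion) {
  stopifnot(inherits(x, "trajectory"), inherits(criterion, "nac_criterion"))
  for (s in criterion$sites) {
    idx <- c(s$hydrogens, s$carbon, criterion$acceptor)
    if (any(idx < 1 | idx > n_atoms(x))) {
      stop("configuration error: site indices outside roster", call. = FALSE)
    }
  }
  nf <- n_frames(x)
  res <- purrr::map(criterion$sites, function(s) {
    g <- site_geometry(x, s, criterion$acceptor)
    ok <- (g$D < criterion$d_max) &
      (abs(g$TH - criterion$theta_ref) <= criterion$theta_tol)
    nac <- apply(ok, 2, any)
    # hydrogens are ordered by roster index, so which.min's first-match
    # tie-break picks the lowest index
    hsort <- order(s$hydrogens)
    Ds <- g$D[hsort, , drop = FALSE]
    best <- apply(Ds, 2, which.min)
    pick <- cbind(best, seq_len(nf))
    tibble::tibble(
      frame = seq_len(nf),
      site = s$label,
      nac = nac,
      hydrogen = s$hydrogens[hsort][best],
      distance = Ds[pick],
      angle = g$TH[hsort, , drop = FALSE][pick]
    )
  })
  out <- dplyr::bind_rows(res)
  if (!is.null(x$times)) {
    out$time_ps <- x$times[out$frame]
  }
  dplyr::arrange(out, .data$frame, .data$site)
}

#' Per-site NAC percentages over a trajectory
#'
#' The headline reactivity statistic: for each site, the percentage of
#' frames classified as near-attack conformations.
#'
#' @inheritParams classify_frames
#' @return Tibble with `site`, `nac_frames`, `total_frames`, `nac_percent`.
#' @examples
#' gen <- gen_reactive_trajectory(reactive_trajectory_spec(
#'   n_frames = 50, sites = list(list("21", 3, 0.4)), seed = 7))
#' nac_percentages(gen$trajectory, gen$criterion)
#' @export
nac_percentages <- function(x, criterion) {
  cls <- classify_frames(x, criterion)
  out <- dplyr::summarise(
    dplyr::group_by(cls, .data$site),
    nac_frames = sum(.data$nac),
    total_frames = dplyr::n(),
    .groups = "drop"
  )
  out$nac_percent <- 100 * out$nac_frames / out$total_frames
  # preserve the criterion's site order
  labs <- vapply(criterion$sites, function(s) s$label, character(1))
  out[match(labs, out$site), ]
}

#' Shortest-distance trace for a site
#'
#' Per frame, the minimum H...O distance over a site's equivalent hydrogens
#' (with several identical hydrogens, only the shortest distance is
#' reported at each time point).
#'
#' @param x A [trajectory()].
#' @param site A [site_definition()].
#' @param acceptor Roster index of the ferryl oxygen.
#' @return Tibble with `frame`, `distance` (Angstrom) and `time_ps` when
#'   available.
#' @export
min_distance_trace <- function(x, site, acceptor) {
  stopifnot(inherits(x, "trajectory"), inherits(site, "site_definition"))
  idx <- c(site$hydrogens, site$carbon, acceptor)
  if (any(idx < 1 | idx > n_atoms(x))) {
    stop("configuration error: indices outside roster", call. = FALSE)
  }
  g <- site_geometry(x, site, as.integer(acceptor))
  out <- tibble::tibble(frame = seq_len(n_frames(x)),
                        site = site$label,
                        distance = apply(g$D, 2, min))
  if (!is.null(x$times)) out$time_ps <- x$times[out$frame]
  out
}
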