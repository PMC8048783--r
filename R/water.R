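#' Nearest-water distance trace with hydrogen-bond flags
#'
#' For each frame, finds the water oxygen closest to the compound I ferryl
#' oxygen.  The frame is flagged as hydrogen-bonded when the O...O distance
#' is at most `hbond_d_max` and, whenever the winning water's hydrogens are
#' present in the roster, at least one O-H...O angle (vertex at the water
#' hydrogen) is at least `hbond_angle_min`.  Waters parked far from the
#' active site never flag; an intruding water that approaches the ferryl
#' oxygen does.
#'
#' @param x A [trajectory()].
#' @param acceptor Roster index of the ferryl oxygen.
#' @param water_oxygens Roster indices of candidate water oxygens (>= 1).
#' @param hbond_d_max O...O hydrogen-bond distance cutoff, Angstrom
#'   (default 3.5).
#' @param hbond_angle_min Minimum O-H...O angle in degrees (default 120).
#' @return Tibble with `frame`, `distance` (Angstrom), `water_index`
#'   (roster index of the nearest water oxygen), `hbond` (logical) and
#'   `time_ps` when available.  The hbond thresholds are recorded as
#'   attributes `hbond_d_max` / `hbond_angle_min`.
#' @export
nearest_water_trace <- function(x, acceptor, water_oxygens,
                                hbond_d_max = 3.5, hbond_angle_min = 120) {
  stopifnot(inherits(x, "trajectory"))
  water_oxygens <- as.integer(water_oxygens)
  if (length(water_oxygens) < 1) {
    stop("configuration error: empty water oxygen set", call. = FALSE)
  }
  idx <- c(acceptor, water_oxygens)
  if (any(idx < 1 | idx > n_atoms(x))) {
    stop("configuration error: indices outside roster", call. = FALSE)
  }
  nf <- n_frames(x)
  acc <- x$coords[acceptor, , , drop = FALSE]
  dim(acc) <- c(3, nf)
  D <- matrix(NA_real_, length(water_oxygens), nf)
  for (k in seq_along(water_oxygens)) {
    w <- x$coords[water_oxygens[k], , , drop = FALSE]
    dim(w) <- c(3, nf)
    D[k, ] <- sqrt(colSums((w - acc)^2))
  }
  best <- apply(D, 2, which.min)
  dist <- D[cbind(best, seq_len(nf))]
  win <- water_oxygens[best]

  # map each water oxygen to its hydrogens by shared residue identity
  ros <- x$roster
  hyd_of <- lapply(water_oxygens, function(o) {
    which(ros$element == "H" & ros$resname == ros$resname[o] &
            ros$resnum == ros$resnum[o] & ros$chain == ros$chain[o])
  })
  names(hyd_of) <- as.character(water_oxygens)

  hbond <- dist <= hbond_d_max
  for (f in which(hbond)) {
    hs <- hyd_of[[as.character(win[f])]]
    if (length(hs) == 0) next          # distance-only criterion
    ang <- vapply(hs, function(h) {
      vec_angle(x$coords[win[f], , f], x$coords[h, , f],
                x$coords[acceptor, , f])
    }, numeric(1))
    hbond[f] <- any(ang >= hbond_angle_min)
  }

  out <- tibble::tibble(frame = seq_len(nf), distance = dist,
                        water_index = win, hbond = hbond)
  if (!is.null(x$times)) out$time_ps <- x$times[out$frame]
  attr(out, "hbond_d_max") <- hbond_d_max
  attr(out, "hbond_angle_min") <- hbond_angle_min
  out
}
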