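#' Multi-frame structure container
#'
#' A `trajectory` couples a constant atom roster with per-frame Cartesian
#' coordinates (Angstrom, right-handed, as in PDB files).  The roster is a
#' tibble with one row per atom; coordinates live in a `n_atoms x 3 x
#' n_frames` array so frame-wise geometry stays vectorised.
#'
#' @param roster Tibble with columns `serial` (integer, unique), `name`,
#'   `element` (non-empty), `resname`, `resnum` (integer), `chain`.
#' @param coords Numeric array of dimension `c(nrow(roster), 3, n_frames)`,
#'   or a single `n x 3` matrix for a one-frame trajectory.  All values must
#'   be finite.
#' @param times Optional numeric vector of frame times in ps, strictly
#'   increasing, one per frame.
#' @return An object of class `trajectory`.
#' @examples
#' ros <- tibble::tibble(serial = 1:2, name = c("O", "H"),
#'                       element = c("O", "H"), resname = "LIG",
#'                       resnum = 1L, chain = "A")
#' xyz <- array(0, c(2, 3, 1)); xyz[2, 1, 1] <- 1
#' trajectory(ros, xyz)
#' @export
trajectory <- function(roster, coords, times = NULL) {
  roster <- tibble::as_tibble(roster)
  need <- c("serial", "name", "element", "resname", "resnum", "chain")
  miss <- setdiff(need, names(roster))
  if (length(miss) > 0) {
    stop("roster is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  roster$serial <- as.integer(roster$serial)
  roster$resnum <- as.integer(roster$resnum)
  if (anyDuplicated(roster$serial)) {
    stop("roster serial numbers must be unique within a frame", call. = FALSE)
  }
  if (any(is.na(roster$element) | !nzchar(roster$element))) {
    stop("every roster atom needs a non-empty element symbol", call. = FALSE)
  }
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3, 1))
  d <- dim(coords)
  if (length(d) != 3 || d[1] != nrow(roster) || d[2] != 3 || d[3] < 1) {
    stop("coords must be an n_atoms x 3 x n_frames array matching the roster",
         call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (!is.null(times)) {
    if (length(times) != d[3]) {
      stop("frame_times length must equal the number of frames", call. = FALSE)
    }
    if (any(diff(times) <= 0)) {
      stop("frame_times must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(roster = roster, coords = coords, times = times),
            class = "trajectory")
}

#' Number of frames / atoms in a trajectory
#' @param x A `trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "trajectory"))
  dim(x$coords)[3]
}

#' @rdname n_frames
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "trajectory"))
  dim(x$coords)[1]
}

#' Coordinates of one frame
#' @param x A `trajectory`.
#' @param i Frame index (1-based).
#' @return `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(x, i) {
  stopifnot(inherits(x, "trajectory"))
  if (i < 1 || i > n_frames(x)) stop("frame index out of range", call. = FALSE)
  m <- x$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms%s\n", n_frames(x), n_atoms(x),
              if (!is.null(x$times)) {
                sprintf(" (%.0f-%.0f ps)", min(x$times), max(x$times))
              } else ""))
  invisible(x)
}

#' Long (tidy) view of a trajectory
#'
#' One row per atom per frame, suitable for dplyr/ggplot2 pipelines.
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return Tibble with `frame`, roster columns, `x`, `y`, `z` and, when the
#'   trajectory carries times, `time_ps`.
#' @method as_tibble trajectory
#' @export
as_tibble.trajectory <- function(x, ...) {
  nf <- n_frames(x)
  na <- n_atoms(x)
  out <- x$roster[rep(seq_len(na), nf), ]
  out <- tibble::add_column(out, frame = rep(seq_len(nf), each = na),
                            .before = 1)
  out$x <- as.vector(x$coords[, 1, ])
  out$y <- as.vector(x$coords[, 2, ])
  out$z <- as.vector(x$coords[, 3, ])
  if (!is.null(x$times)) out$time_ps <- rep(x$times, each = na)
  out
}
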