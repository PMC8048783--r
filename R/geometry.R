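#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors (Angstrom), or matrices of row-points of
#'   equal dimension, in which case distances are computed row-wise.
#' @return Distance(s) in Angstrom.
#' @export
vec_distance <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- rbind(a); b <- rbind(b)
    return(sqrt(rowSums((a - b)^2)))
  }
  sqrt(sum((a - b)^2))
}

#' Angle at a vertex, in degrees
#'
#' The angle between the arms `vertex -> a` and `vertex -> c`, reported in
#' degrees in `[0, 180]`.
#'
#' @param a,vertex,c Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @export
vec_angle <- function(a, vertex, c) {
  u <- a - vertex
  v <- c - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("degenerate geometry: zero-length angle arm", call. = FALSE)
  }
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired point sets, via SVD of the cross-covariance with a determinant
#' guard so a reflection is never returned.  The fitted transform maps a
#' row-point `p` of `mobile` to `p %*% rotation + translation`.
#'
#' @param mobile,reference `n x 3` matrices of paired points, `n >= 3`.
#' @return A `superposition` object: list with `rotation` (3x3, det +1),
#'   `translation` (3-vector), `rmsd` (Angstrom) and `n_atoms`.
#' @export
kabsch <- function(mobile, reference) {
  mobile <- rbind(mobile); reference <- rbind(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("point sets must be paired (equal length)", call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3) stop("insufficient points: superposition needs n >= 3",
                  call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm)
  R0 <- sweep(reference, 2, cr)
  C <- crossprod(M, R0)                       # 3x3 cross-covariance
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- M %*% rot
  rmsd <- sqrt(sum((fitted - R0)^2) / n)
  structure(list(rotation = rot,
                 translation = as.numeric(cr - cm %*% rot),
                 rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' Apply a fitted superposition to coordinates
#' @param sp A `superposition` from [kabsch()].
#' @param coords `n x 3` matrix (or 3-vector).
#' @return Transformed coordinates, same shape.
#' @export
apply_superposition <- function(sp, coords) {
  stopifnot(inherits(sp, "superposition"))
  v <- is.null(dim(coords))
  out <- sweep(rbind(coords) %*% sp$rotation, 2, -sp$translation)
  if (v) as.numeric(out) else out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> n = %d atoms, rmsd = %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy superposition
#' @export
tidy.superposition <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("rotation[", rep(1:3, 3), ",", rep(1:3, each = 3), "]"),
             paste0("translation[", 1:3, "]")),
    estimate = c(as.vector(x$rotation), x$translation)
  )
}

#' @method glance superposition
#' @export
glance.superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
                 det_rotation = det(x$rotation))
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF of each target atom about its trajectory-mean position,
#' `sqrt(mean_f |r_i(f) - <r_i>|^2)`.  When `fit_atoms` is given, every frame
#' is first rigid-body superposed onto frame 1 over those atoms (removing
#' global tumbling/translation) before fluctuations are measured.
#'
#' @param x A [trajectory()] with at least 2 frames.
#' @param target_atoms Roster indices to profile (default: all atoms).
#' @param fit_atoms Optional roster indices (>= 3) used for the frame-wise
#'   alignment; `NULL` analyses raw coordinates.
#' @return Tibble with `index`, `name`, `resname`, `resnum`, `rmsf`
#'   (Angstrom) and a `fit_reference` attribute describing the alignment.
#' @export
rmsf <- function(x, target_atoms = NULL, fit_atoms = NULL) {
  stopifnot(inherits(x, "trajectory"))
  if (n_frames(x) < 2) stop("RMSF needs at least 2 frames", call. = FALSE)
  if (is.null(target_atoms)) target_atoms <- seq_len(n_atoms(x))
  coords <- x$coords
  fit_desc <- "none (raw coordinates)"
  if (!is.null(fit_atoms)) {
    if (length(fit_atoms) < 3) {
      stop("insufficient points: fit_atoms needs n >= 3", call. = FALSE)
    }
    ref <- coords[fit_atoms, , 1, drop = FALSE]
    dim(ref) <- c(length(fit_atoms), 3)
    for (f in seq_len(n_frames(x))) {
      fr <- coords[, , f]
      sp <- kabsch(fr[fit_atoms, , drop = FALSE], ref)
      coords[, , f] <- apply_superposition(sp, fr)
    }
    fit_desc <- sprintf("kabsch onto frame 1 over %d atoms",
                        length(fit_atoms))
  }
  sub <- coords[target_atoms, , , drop = FALSE]
  mean_pos <- apply(sub, c(1, 2), mean)
  dev2 <- (sub - as.vector(mean_pos))^2   # recycles over frames
  msd <- apply(dev2, 1, sum) / dim(sub)[3]
  out <- tibble::tibble(
    index = target_atoms,
    name = x$roster$name[target_atoms],
    resname = x$roster$resname[target_atoms],
    resnum = x$roster$resnum[target_atoms],
    rmsf = sqrt(msd)
  )
  attr(out, "fit_reference") <- fit_desc
  out
}
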